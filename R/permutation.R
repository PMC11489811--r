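#' Nonparametric cluster-permutation test for one ANOVA effect
#'
#' Computes the pointwise F map of the requested effect, forms
#' spatiotemporal clusters at `p < point_alpha`, and calibrates the cluster
#' masses against a permutation null distribution of the maximal cluster
#' mass. Cluster p-values use the unbiased estimator
#' `p = (1 + #\{null >= observed\}) / (1 + n_perm)`.
#'
#' Permutation schemes:
#' \itemize{
#'   \item effects involving the between factor (`group`, `task:group`,
#'     `picture:group`, `task:picture:group`): group labels are permuted
#'     across subjects — exact, since the statistic reduces to a
#'     between-group comparison of per-subject contrast scores;
#'   \item within main effects (`task`, `picture`): the factor's levels are
#'     permuted independently within every subject;
#'   \item `task:picture`: cell labels of the per-subject residualised data
#'     (subject task and picture margins removed) are permuted within every
#'     subject.
#' }
#' Inside the permutation loop the cluster-forming threshold uses the
#' uncorrected parametric pointwise p (a fixed F quantile), applied
#' identically to the observed and permuted statistics.
#'
#' @param activity Array `subjects x tasks x pictures x sites x time`.
#' @param group Two-level factor over subjects.
#' @param effect One of `"group"`, `"task"`, `"picture"`, `"task:group"`,
#'   `"picture:group"`, `"task:picture"`, `"task:picture:group"`.
#' @param adjacency Spatial adjacency list from [site_adjacency()].
#' @param n_perm Number of permutations (>= 100; default 1000).
#' @param point_alpha Pointwise cluster-forming criterion.
#' @param cluster_stat Cluster score: `"mass"` (sum of F, the default) or
#'   `"max"` (maximum F within the cluster).
#' @param seed Integer RNG seed (mandatory for reproducibility).
#' @return List of class `bse_cluster_test`: `clusters` (with permutation
#'   p-values), `F` (observed map), `f_crit`, `df`, `null_max` (the
#'   permutation distribution), `effect`, `n_perm`.
#' @export
permutation_null <- function(activity, group, effect, adjacency,
                             n_perm = 1000, point_alpha = 0.05,
                             cluster_stat = c("mass", "max"), seed = 1L) {
  stopifnot(n_perm >= 100)
  cluster_stat <- match.arg(cluster_stat)
  d <- dim(activity)
  stopifnot(length(d) == 5)
  S <- d[4]; Tn <- d[5]
  Y <- array(activity, c(d[1], d[2], d[3], S * Tn))
  group <- droplevels(as.factor(group))
  stopifnot(nlevels(group) == 2)
  N <- d[1]; a <- d[2]; b <- d[3]
  M <- rm_contrasts(a, b)
  effects_grp <- c("group", "task:group", "picture:group", "task:picture:group")
  effects_wth <- c("task", "picture", "task:picture")
  if (!effect %in% c(effects_grp, effects_wth))
    stop("unknown effect '", effect, "'", call. = FALSE)
  withr_seed(seed)

  contrast_of <- c(group = "int", task = "task", picture = "picture",
                   "task:group" = "task", "picture:group" = "picture",
                   "task:picture" = "task_picture",
                   "task:picture:group" = "task_picture")
  side <- if (effect %in% effects_grp) "F_grp" else "F_int"

  stat_map <- function(Z, g) score_tests(Z, g)[[side]]

  if (effect %in% effects_grp) {
    Z <- rm_scores(Y, M[[contrast_of[effect]]])
    tst <- score_tests(Z, group)
    Fobs <- tst[[side]]
    df1 <- tst$df1; df2 <- tst$df2
    draw <- function() stat_map(Z, sample(group))
  } else if (effect %in% c("task", "picture")) {
    tst <- score_tests(rm_scores(Y, M[[contrast_of[effect]]]), group)
    Fobs <- tst[[side]]
    df1 <- tst$df1; df2 <- tst$df2
    k <- if (effect == "task") a else b
    draw <- function() {
      Yp <- Y
      for (n in seq_len(N)) {
        pi_n <- sample.int(k)
        if (effect == "task") Yp[n, , , ] <- Y[n, pi_n, , ]
        else Yp[n, , , ] <- Y[n, , pi_n, ]
      }
      stat_map(rm_scores(Yp, M[[contrast_of[effect]]]), group)
    }
  } else {  # task:picture — permute residualised cell labels within subject
    tst <- score_tests(rm_scores(Y, M$task_picture), group)
    Fobs <- tst[[side]]
    df1 <- tst$df1; df2 <- tst$df2
    mt <- apply(Y, c(1, 2, 4), mean)  # N x a x P task margins
    mp <- apply(Y, c(1, 3, 4), mean)  # N x b x P picture margins
    ms <- apply(Y, c(1, 4), mean)     # N x P subject means
    W <- Y
    for (t in seq_len(a)) for (p in seq_len(b))
      W[, t, p, ] <- Y[, t, p, ] - mt[, t, ] - mp[, p, ] + ms
    Wc <- array(W, c(N, a * b, S * Tn))
    draw <- function() {
      Wp <- Wc
      for (n in seq_len(N)) Wp[n, , ] <- Wc[n, sample.int(a * b), ]
      stat_map(rm_scores(array(Wp, c(N, a, b, S * Tn)), M$task_picture), group)
    }
  }

  f_crit <- stats::qf(1 - point_alpha, df1, df2)
  score <- function(cl, Fm)
    if (cluster_stat == "mass") cl$mass else max(Fm[cl$points])
  Fmat <- matrix(Fobs, S, Tn)
  clusters <- cluster_from_mask(Fmat, Fmat > f_crit, adjacency, effect)
  for (i in seq_along(clusters))
    clusters[[i]]$stat <- score(clusters[[i]], Fmat)
  null_max <- numeric(n_perm)
  for (bp in seq_len(n_perm)) {
    Fp <- matrix(draw(), S, Tn)
    cl <- cluster_from_mask(Fp, Fp > f_crit, adjacency, effect)
    null_max[bp] <- if (length(cl))
      max(vapply(cl, score, numeric(1), Fm = Fp)) else 0
  }
  for (i in seq_along(clusters))
    clusters[[i]]$p <- (1 + sum(null_max >= clusters[[i]]$stat)) / (1 + n_perm)
  structure(list(clusters = clusters, F = Fmat, f_crit = f_crit,
                 df = c(df1, df2), null_max = null_max, effect = effect,
                 n_perm = n_perm, point_alpha = point_alpha,
                 cluster_stat = cluster_stat),
            class = "bse_cluster_test")
}

#' @export
print.bse_cluster_test <- function(x, ...) {
  cat(sprintf("<cluster test: effect %s, %d clusters, n_perm = %d>\n",
              x$effect, length(x$clusters), x$n_perm))
  if (length(x$clusters)) print(cluster_table(x$clusters))
  invisible(x)
}

#' Cluster-permutation analysis over several effects
#'
#' Runs [permutation_null()] for each requested effect, merges adjacent
#' same-effect clusters, and collects a tidy cluster table.
#'
#' @inheritParams permutation_null
#' @param effects Character vector of effect names.
#' @param cluster_alpha Cluster-level significance criterion (reported, not
#'   used for selection).
#' @param time_ms Optional time axis for the report.
#' @return List of class `bse_cluster_anova` with per-effect test objects,
#'   a combined `table`, and the analysis parameters.
#' @export
cluster_anova <- function(activity, group, effects = c("task", "picture",
                                                       "picture:group"),
                          adjacency, n_perm = 1000, point_alpha = 0.05,
                          cluster_alpha = 0.05, time_ms = NULL, seed = 1L) {
  tests <- list()
  for (i in seq_along(effects)) {
    eff <- effects[i]
    tst <- permutation_null(activity, group, eff, adjacency,
                            n_perm = n_perm, point_alpha = point_alpha,
                            seed = as.integer(seed) + i)
    tst$clusters <- merge_clusters(tst$clusters, adjacency,
                                   n_sites = nrow(tst$F))
    tests[[eff]] <- tst
  }
  tab <- do.call(rbind, lapply(tests, function(t)
    cluster_table(t$clusters, time_ms)))
  rownames(tab) <- NULL
  structure(list(tests = tests, table = tab, cluster_alpha = cluster_alpha,
                 point_alpha = point_alpha, n_perm = n_perm),
            class = "bse_cluster_anova")
}
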