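# Orthonormal within-subject contrast sets for an a (task) x b (picture)
# within design. Cell ordering: picture fastest within task,
# cell = (t - 1) * b + p.
rm_contrasts <- function(a, b) {
  ja <- rep(1 / sqrt(a), a)
  jb <- rep(1 / sqrt(b), b)
  CT <- stats::contr.poly(a)
  CP <- stats::contr.poly(b)
  list(
    int = kronecker(matrix(ja, ncol = 1), matrix(jb, ncol = 1)),
    task = kronecker(CT, matrix(jb, ncol = 1)),
    picture = kronecker(matrix(ja, ncol = 1), CP),
    task_picture = kronecker(CT, CP)
  )
}

# Z scores for a contrast set: returns array (q, N, P) from Y (N, a, b, P).
rm_scores <- function(Y, M) {
  d <- dim(Y)  # N, a, b, P
  Ym <- matrix(aperm(Y, c(3, 2, 1, 4)), d[2] * d[3], d[1] * d[4])
  Z <- crossprod(M, Ym)  # q x (N * P)
  array(Z, c(ncol(M), d[1], d[4]))
}

# Averaged-univariate-F tests on score arrays (Type III / unweighted means).
# Z: (q, N, P) array; g: 2-level factor. Returns F vectors over P for the
# within-effect ("intercept") and its interaction with group ("group"),
# plus sums of squares for effect sizes.
score_tests <- function(Z, g, zero_tol = 0) {
  q <- dim(Z)[1]; N <- dim(Z)[2]; P <- dim(Z)[3]
  gi <- as.integer(g)
  n1 <- sum(gi == 1L); n2 <- sum(gi == 2L)
  Zm <- matrix(aperm(Z, c(2, 1, 3)), N, q * P)
  gm <- rowsum(Zm, gi) / c(n1, n2)          # 2 x (q*P) group means
  ssq <- colSums(Zm^2)                       # per (v,p)
  sse_vp <- ssq - n1 * gm[1, ]^2 - n2 * gm[2, ]^2
  mbar <- (gm[1, ] + gm[2, ]) / 2
  h <- 4 / (1 / n1 + 1 / n2)
  ss_int_vp <- h * mbar^2
  ss_grp_vp <- (gm[1, ] - gm[2, ])^2 / (1 / n1 + 1 / n2)
  collapse <- function(v) .colSums(matrix(v, q, P), q, P)
  sse <- pmax(collapse(sse_vp), 0)  # cancellation can leave -1e-16
  ss_int <- collapse(ss_int_vp)
  ss_grp <- collapse(ss_grp_vp)
  df2 <- q * (N - 2)
  # an effect whose sum of squares is at numerical zero (relative to the
  # data scale) is reported as F = 0 rather than 0/0
  fvec <- function(ss) ifelse(ss <= zero_tol, 0, (ss / q) / (sse / df2))
  list(F_int = fvec(ss_int), F_grp = fvec(ss_grp),
       ss_int = ss_int, ss_grp = ss_grp, sse = sse,
       df1 = q, df2 = df2, n = c(n1, n2))
}

# Greenhouse-Geisser epsilon per point from score arrays (pooled
# within-group covariance of the orthonormal contrast variables).
score_gg_epsilon <- function(Z, g) {
  q <- dim(Z)[1]; N <- dim(Z)[2]; P <- dim(Z)[3]
  if (q == 1) return(rep(1, P))
  gi <- as.integer(g)
  n_j <- tabulate(gi)
  Zm <- matrix(aperm(Z, c(2, 1, 3)), N, q * P)
  gm <- rowsum(Zm, gi) / n_j
  Zc <- Zm - gm[gi, ]
  Zc <- array(Zc, c(N, q, P))
  tr <- rep(0, P); frob <- rep(0, P)
  for (u in seq_len(q)) {
    suu <- .colSums(Zc[, u, ]^2, N, P) / (N - 2)
    tr <- tr + suu
    frob <- frob + suu^2
    if (u < q) for (v in (u + 1):q) {
      suv <- .colSums(Zc[, u, ] * Zc[, v, ], N, P) / (N - 2)
      frob <- frob + 2 * suv^2
    }
  }
  eps <- tr^2 / (q * frob)
  eps[!is.finite(eps)] <- 1 / q  # singular covariance: lower bound
  pmin(pmax(eps, 1 / q), 1)
}

#' Greenhouse-Geisser epsilon from a within-level covariance matrix
#'
#' Box/Greenhouse-Geisser sphericity index for `k` repeated measures:
#' `eps = tr(C S C')^2 / ((k - 1) * tr((C S C')^2))` with `C` an
#' orthonormal contrast basis. Bounded in `[1/(k-1), 1]`; equals 1 under
#' compound symmetry, and is always 1 for `k = 2`.
#'
#' @param S k x k covariance matrix of the within-condition measures.
#' @return Epsilon in `[1/(k-1), 1]`.
#' @export
gg_epsilon <- function(S) {
  S <- as.matrix(S)
  k <- nrow(S)
  stopifnot(k >= 2, ncol(S) == k)
  C <- t(stats::contr.poly(k))  # (k-1) x k orthonormal rows
  E <- C %*% S %*% t(C)
  tr <- sum(diag(E)); frob <- sum(E^2)
  if (frob <= 0) {
    warning("gg_epsilon: singular covariance; returning lower bound")
    return(1 / (k - 1))
  }
  min(max(tr^2 / ((k - 1) * frob), 1 / (k - 1)), 1)
}

#' Pointwise mixed-design repeated-measures ANOVA
#'
#' At every (site, time) point, computes the univariate split-plot F for
#' each effect of the task x picture (within) x group (between, 2 levels)
#' design: the three main effects, the three two-way interactions and the
#' three-way interaction. Implementation follows the
#' orthonormal-contrast-score (averaged univariate F) formulation, which for
#' unbalanced groups yields the unweighted-means (Type III) solution.
#' Greenhouse-Geisser epsilon is estimated per point for every within
#' effect and the correction is applied to the reported p-values where
#' `epsilon < gg_threshold` (0.75).
#'
#' @param activity Numeric array `subjects x tasks x pictures x sites x
#'   time` (or `subjects x tasks x pictures x points`).
#' @param group Two-level factor over subjects.
#' @param gg_threshold Epsilon below which the GG correction is applied.
#' @return List of class `bse_fmap_set`; one element per effect with `F`,
#'   `p` (corrected where applicable), `p_uncorrected`, `df1`, `df2`,
#'   `epsilon`, `gg_applied`, `eta_p2`, each a sites x time matrix (or
#'   vector), plus a `dims` attribute.
#' @export
pointwise_rm_anova <- function(activity, group, gg_threshold = 0.75) {
  d <- dim(activity)
  if (length(d) == 5) {
    out_dim <- d[4:5]
    Y <- array(activity, c(d[1], d[2], d[3], d[4] * d[5]))
  } else if (length(d) == 4) {
    out_dim <- d[4]
    Y <- activity
  } else stop("activity must be a 4- or 5-d array", call. = FALSE)
  group <- droplevels(as.factor(group))
  stopifnot(nlevels(group) == 2, length(group) == d[1])
  if (any(tabulate(group) < 2))
    stop("need >= 2 subjects per group", call. = FALSE)
  M <- rm_contrasts(d[2], d[3])
  zero_tol <- 1e-14 * (.colSums(matrix(Y^2, prod(d[1:3]), prod(out_dim)),
                                prod(d[1:3]), prod(out_dim)) + 1e-300)
  shape <- function(v) if (length(out_dim) == 2) matrix(v, out_dim[1], out_dim[2]) else v

  res <- list()
  add <- function(name, Fv, ss, sse, df1, df2, eps = NULL) {
    p_unc <- stats::pf(Fv, df1, df2, lower.tail = FALSE)
    if (!is.null(eps)) {
      apply_gg <- eps < gg_threshold
      p <- ifelse(apply_gg,
                  stats::pf(Fv, df1 * eps, df2 * eps, lower.tail = FALSE),
                  p_unc)
    } else {
      apply_gg <- rep(FALSE, length(Fv))
      p <- p_unc
    }
    res[[name]] <<- list(effect = name, F = shape(Fv), p = shape(p),
                         p_uncorrected = shape(p_unc),
                         df1 = df1, df2 = df2,
                         epsilon = if (is.null(eps)) NULL else shape(eps),
                         gg_applied = shape(apply_gg),
                         eta_p2 = shape(ss / (ss + sse)))
  }

  Zg <- rm_scores(Y, M$int)
  tg <- score_tests(Zg, group, zero_tol)
  add("group", tg$F_grp, tg$ss_grp, tg$sse, tg$df1, tg$df2)

  for (nm in c("task", "picture", "task_picture")) {
    Z <- rm_scores(Y, M[[nm]])
    tt <- score_tests(Z, group, zero_tol)
    eps <- score_gg_epsilon(Z, group)
    lab <- sub("_", ":", nm)
    add(lab, tt$F_int, tt$ss_int, tt$sse, tt$df1, tt$df2, eps)
    add(paste0(lab, ":group"), tt$F_grp, tt$ss_grp, tt$sse, tt$df1, tt$df2, eps)
  }
  structure(res, dims = out_dim, class = "bse_fmap_set")
}

#' @export
print.bse_fmap_set <- function(x, ...) {
  for (e in x)
    cat(sprintf("%-20s F(%g,%g): max = %.2f, min p = %.3g\n",
                e$effect, e$df1, e$df2, max(e$F), min(e$p)))
  invisible(x)
}
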