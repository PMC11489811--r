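test_that("pointwise mixed ANOVA agrees with aov at random points", {
  set.seed(31)
  N <- 10; a <- 3; b <- 6; P <- 7
  Y <- array(rnorm(N * a * b * P), c(N, a, b, P))
  Y[1:5, , , ] <- Y[1:5, , , ] + 0.4          # group shift
  Y[, 3, , ] <- Y[, 3, , ] + 0.5              # task shift
  g <- factor(rep(c("AN", "HC"), each = 5))
  fm <- pointwise_rm_anova(Y, g)
  effmap <- c(group = "grp", task = "task", picture = "pic",
              "task:group" = "task:grp", "picture:group" = "pic:grp",
              "task:picture" = "task:pic", "task:picture:group" = "task:pic:grp")
  for (pt in c(1, 4, 7)) {
    df <- expand.grid(subj = 1:N, task = factor(1:a), pic = factor(1:b))
    df$y <- Y[cbind(df$subj, as.integer(df$task), as.integer(df$pic), pt)]
    df$grp <- g[df$subj]; df$subj <- factor(df$subj)
    fit <- summary(aov(y ~ task * pic * grp + Error(subj / (task * pic)),
                       data = df))
    strata <- do.call(rbind, lapply(fit, function(s) {
      tab <- s[[1]]
      data.frame(term = trimws(rownames(tab)), F = tab$`F value`)
    }))
    for (eff in names(effmap)) {
      ref <- strata$F[strata$term == effmap[eff]]
      expect_equal(fm[[eff]]$F[pt], ref, tolerance = 1e-6,
                   label = paste("effect", eff, "point", pt))
    }
  }
})

test_that("ANOVA degenerate and invariance properties hold", {
  N <- 8
  Y <- array(5, c(N, 3, 6, 4))
  g <- factor(rep(c("AN", "HC"), each = 4))
  fm <- pointwise_rm_anova(Y, g)
  for (e in fm) expect_true(all(e$F == 0))
  # permuting subjects (within groups preserved as labels move with rows)
  set.seed(32)
  Y2 <- array(rnorm(N * 3 * 6 * 4), c(N, 3, 6, 4))
  perm <- sample(N)
  f1 <- pointwise_rm_anova(Y2, g)
  f2 <- pointwise_rm_anova(Y2[perm, , , ], g[perm])
  expect_equal(f1$task$F, f2$task$F, tolerance = 1e-10)
  expect_equal(f1$group$F, f2$group$F, tolerance = 1e-10)
})

test_that("Greenhouse-Geisser epsilon matches the Box formula", {
  # compound symmetry gives epsilon 1
  S_cs <- matrix(0.3, 4, 4); diag(S_cs) <- 1
  expect_equal(gg_epsilon(S_cs), 1, tolerance = 1e-12)
  # k = 2 always gives 1
  expect_equal(gg_epsilon(matrix(c(1, 0.1, 0.1, 2), 2, 2)), 1)
  # random covariance against an independent elementwise implementation
  set.seed(33)
  for (i in 1:10) {
    X <- matrix(rnorm(40), 10, 4)
    S <- cov(X)
    k <- 4
    sbar <- mean(S)
    rowm <- rowMeans(S)
    num <- (k * (mean(diag(S)) - sbar))^2
    den <- (k - 1) * (sum(S^2) - 2 * k * sum(rowm^2) + k^2 * sbar^2)
    expect_equal(gg_epsilon(S), max(min(num / den, 1), 1 / (k - 1)),
                 tolerance = 1e-10)
  }
  expect_warning(gg_epsilon(matrix(0, 3, 3)), "singular")
})

test_that("cluster formation matches a naive flood fill", {
  set.seed(34)
  src <- build_source_shell(n_sites = 25)
  adj <- site_adjacency(src, 4)
  Fmat <- matrix(rexp(25 * 12), 25, 12)
  fmap <- list(effect = "task", F = Fmat,
               p = matrix(runif(25 * 12), 25, 12))
  cl <- form_clusters(fmap, point_alpha = 0.3, adjacency = adj)
  mask <- fmap$p < 0.3
  lab <- naive_flood_fill(mask, adj)
  expect_equal(length(cl), max(lab))
  # memberships coincide
  for (c1 in cl) {
    ids <- unique(lab[c1$members])
    expect_length(ids, 1)
    expect_equal(nrow(c1$members), sum(lab == ids))
    expect_equal(c1$mass, sum(Fmat[lab == ids]), tolerance = 1e-12)
  }
  # no suprathreshold points -> empty list
  fmap0 <- list(effect = "task", F = Fmat, p = matrix(1, 25, 12))
  expect_length(form_clusters(fmap0, 0.05, adj), 0)
  # one isolated point forms a singleton cluster with mass = F
  p1 <- matrix(1, 25, 12); p1[7, 5] <- 0.001
  cl1 <- form_clusters(list(effect = "x", F = Fmat, p = p1), 0.05, adj)
  expect_length(cl1, 1)
  expect_equal(cl1[[1]]$mass, Fmat[7, 5])
})

test_that("cluster mass is invariant to site relabelling", {
  set.seed(35)
  src <- build_source_shell(n_sites = 20)
  adj <- site_adjacency(src, 4)
  Fmat <- matrix(rexp(20 * 8, rate = 0.5), 20, 8)
  pmat <- matrix(runif(20 * 8), 20, 8)
  perm <- sample(20)
  adj_p <- vector("list", 20)
  for (i in 1:20) adj_p[[perm[i]]] <- sort(perm[adj[[i]]])
  cl <- form_clusters(list(effect = "e", F = Fmat, p = pmat), 0.3, adj)
  # relabelling: site i of the original becomes site perm[i]
  Fm2 <- Fmat; pm2 <- pmat
  Fm2[perm, ] <- Fmat; pm2[perm, ] <- pmat
  cl2 <- form_clusters(list(effect = "e", F = Fm2, p = pm2), 0.3, adj_p)
  expect_setequal(round(sapply(cl2, `[[`, "mass"), 8),
                  round(sapply(cl, `[[`, "mass"), 8))
})

test_that("cluster merging unions adjacent clusters and is idempotent", {
  src <- build_source_shell(n_sites = 12)
  adj <- site_adjacency(src, 3)
  Fmat <- matrix(1, 12, 10)
  mk <- function(times, site = 1) {
    pts <- (times - 1L) * 12L + site
    list(effect = "task", members = cbind(site = rep(site, length(times)),
                                          time = times),
         points = pts, sites = site, time_range = range(times),
         mass = length(times), p = 0.01)
  }
  # temporally abutting clusters on the same site merge; distant ones do not
  far <- list(mk(1:2), mk(3:4), mk(8:9))
  merged <- merge_clusters(far, adj, 12)
  expect_length(merged, 2)
  masses <- sort(sapply(merged, `[[`, "mass"))
  expect_equal(masses, c(2, 4))
  # idempotent and order-independent
  again <- merge_clusters(merged, adj, 12)
  expect_equal(sort(sapply(again, `[[`, "mass")), masses)
  merged_rev <- merge_clusters(rev(far), adj, 12)
  expect_equal(sort(sapply(merged_rev, `[[`, "mass")), masses)
  # different effects refuse to merge
  mixed <- list(mk(1:2), modifyList(mk(3:4), list(effect = "picture")))
  expect_error(merge_clusters(mixed, adj, 12), "one effect")
})

test_that("cluster means equal the naive double loop", {
  set.seed(36)
  act <- array(rnorm(6 * 3 * 6 * 10 * 8), c(6, 3, 6, 10, 8))
  cl <- list(effect = "task",
             members = cbind(site = c(2, 2, 5), time = c(3, 4, 3)),
             points = c((3 - 1) * 10 + 2, (4 - 1) * 10 + 2, (3 - 1) * 10 + 5),
             sites = c(2, 5), time_range = c(3, 4), mass = 1, p = NA)
  cm <- extract_cluster_mean(act, cl)
  ref <- array(0, c(6, 3, 6))
  for (i in 1:6) for (t in 1:3) for (p in 1:6)
    ref[i, t, p] <- mean(c(act[i, t, p, 2, 3], act[i, t, p, 2, 4],
                           act[i, t, p, 5, 3]))
  expect_equal(cm, ref, tolerance = 1e-12)
  # single point and uniform data
  cl1 <- modifyList(cl, list(members = cbind(site = 4, time = 2),
                             points = (2 - 1) * 10 + 4))
  expect_equal(extract_cluster_mean(act, cl1)[3, 2, 5], act[3, 2, 5, 4, 2])
  actu <- act; actu[] <- 7
  expect_true(all(extract_cluster_mean(actu, cl) == 7))
})

test_that("permutation p-values behave per the Monte Carlo formula", {
  set.seed(37)
  src <- build_source_shell(n_sites = 15)
  adj <- site_adjacency(src, 4)
  # a very strong injected group x picture interaction
  Y <- array(rnorm(12 * 3 * 6 * 15 * 6, sd = 0.1), c(12, 3, 6, 15, 6))
  lin <- seq(-1, 1, length.out = 6)
  for (p in 1:6) Y[1:6, , p, , ] <- Y[1:6, , p, , ] + lin[p] * 2
  g <- factor(rep(c("AN", "HC"), each = 6))
  pt <- permutation_null(Y, g, "picture:group", adj, n_perm = 199, seed = 5)
  ps <- sapply(pt$clusters, `[[`, "p")
  expect_equal(min(ps), 1 / 200)  # observed exceeds every permutation
  # seeded determinism
  pt2 <- permutation_null(Y, g, "picture:group", adj, n_perm = 199, seed = 5)
  expect_identical(sapply(pt$clusters, `[[`, "p"),
                   sapply(pt2$clusters, `[[`, "p"))
  expect_identical(pt$null_max, pt2$null_max)
  expect_error(permutation_null(Y, g, "nonsense", adj, n_perm = 100),
               "unknown effect")
  expect_error(permutation_null(Y, g, "task", adj, n_perm = 10), "n_perm")
})

test_that("within-subject permutation schemes run and stay calibrated", {
  set.seed(38)
  src <- build_source_shell(n_sites = 10)
  adj <- site_adjacency(src, 3)
  Y <- array(rnorm(8 * 3 * 6 * 10 * 5), c(8, 3, 6, 10, 5))
  g <- factor(rep(c("AN", "HC"), each = 4))
  for (eff in c("task", "picture", "task:picture")) {
    pt <- permutation_null(Y, g, eff, adj, n_perm = 120, seed = 6)
    expect_true(all(pt$null_max >= 0))
    ps <- sapply(pt$clusters, `[[`, "p")
    if (length(ps)) expect_true(all(ps > 0 & ps <= 1))
  }
})

test_that("polynomial contrasts reproduce hand-computed statistics", {
  w_lin <- poly_weights(6, 1)
  w_quad <- poly_weights(6, 2)
  expect_equal(w_lin, c(-5, -3, -1, 1, 3, 5))
  expect_equal(w_quad, c(5, -1, -4, -4, -1, 5))
  expect_equal(sum(w_lin * w_quad), 0)
  expect_equal(sum(w_lin), 0)
  # perfectly linear means: quadratic F = 0
  cm <- outer(seq(0.5, 2, length.out = 7), seq(2, 12, by = 2))
  res <- polynomial_contrast(cm)
  expect_equal(res$F[res$trend == "quadratic" & res$test == "mean"], 0)
  # fixture against a hand t
  set.seed(39)
  cm2 <- matrix(rnorm(5 * 6), 5, 6)
  sc <- cm2 %*% w_lin
  t_hand <- mean(sc) / (sd(sc) / sqrt(5))
  res2 <- polynomial_contrast(cm2)
  expect_equal(res2$F[res2$trend == "linear" & res2$test == "mean"],
               t_hand^2, tolerance = 1e-10)
  # group trend difference equals the two-sample t squared
  gset <- factor(c("AN", "AN", "HC", "HC", "HC"))
  tg <- t.test(sc ~ gset, var.equal = TRUE)
  res3 <- polynomial_contrast(cm2, gset)
  expect_equal(res3$F[res3$trend == "linear" & res3$test == "group"],
               unname(tg$statistic)^2, tolerance = 1e-10)
  expect_error(polynomial_contrast(matrix(1, 4, 2)), ">= 3")
})

test_that("post-hoc t-tests match textbook formulas and symmetries", {
  set.seed(40)
  v <- cbind(a = rnorm(9), b = rnorm(9, 0.5), c = rnorm(9, 1))
  res <- posthoc_ttests(v)
  d <- v[, "a"] - v[, "b"]
  t_hand <- mean(d) / (sd(d) / sqrt(9))
  row <- res[res$comparison == "a vs b", ]
  expect_equal(row$t, t_hand, tolerance = 1e-10)
  expect_equal(row$df, 8)
  expect_equal(row$d, mean(d) / sd(d), tolerance = 1e-10)
  # identical vectors: t = 0; swapped order flips the sign
  expect_equal(posthoc_ttests(cbind(x = v[, 1], y = v[, 1]))$t, 0)
  rev_row <- posthoc_ttests(v[, c("b", "a", "c")])
  expect_equal(rev_row$t[rev_row$comparison == "b vs a"], -t_hand,
               tolerance = 1e-10)
  # group tests are appended per condition
  g <- factor(rep(c("AN", "HC"), c(4, 5)))
  res_g <- posthoc_ttests(v, group = g)
  expect_equal(sum(grepl("independent", res_g$type)), 3)
})

test_that("the maximum-statistic cluster score is a valid alternative", {
  set.seed(41)
  src <- build_source_shell(n_sites = 12)
  adj <- site_adjacency(src, 3)
  Y <- array(rnorm(10 * 3 * 6 * 12 * 5, sd = 0.1), c(10, 3, 6, 12, 5))
  lin <- seq(-1, 1, length.out = 6)
  for (p in 1:6) Y[1:5, , p, , ] <- Y[1:5, , p, , ] + lin[p] * 2
  g <- factor(rep(c("AN", "HC"), each = 5))
  pm <- permutation_null(Y, g, "picture:group", adj, n_perm = 119,
                         cluster_stat = "max", seed = 9)
  expect_equal(pm$cluster_stat, "max")
  ps <- sapply(pm$clusters, `[[`, "p")
  # the injected effect is detected (single suprathreshold noise points can
  # carry large F under the max statistic, so the minimal p need not be
  # the Monte Carlo floor)
  expect_lt(min(ps), 0.05)
  # cluster score equals the maximal member F
  big <- pm$clusters[[which.min(ps)]]
  expect_equal(big$stat, max(pm$F[big$points]), tolerance = 1e-12)
})
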