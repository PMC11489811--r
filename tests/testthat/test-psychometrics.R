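test_that("weibull_cdf matches its closed form", {
  expect_equal(weibull_cdf(0, 0.05, 3), 0)
  expect_equal(weibull_cdf(20, 0.05, 3), -expm1(-1), tolerance = 1e-12)
  expect_equal(weibull_cdf(40, 0.05, 1), -expm1(-2), tolerance = 1e-12)
  x <- seq(0, 60, by = 0.5)
  expect_true(all(diff(weibull_cdf(x, 0.05, 6)) >= 0))
  expect_true(all(weibull_cdf(x, 0.05, 6) <= 1))
  expect_lt(weibull_cdf(25, 0.05, 6), 1)
  expect_error(weibull_cdf(10, -0.1, 3), "positive")
  expect_error(weibull_cdf(-1, 0.1, 3), "non-negative")
})

test_that("fitted_bmi inverts the psychometric function", {
  fit <- list(a = 0.05, beta = 3, converged = TRUE)
  # closed form checked against a numeric root finder
  target <- uniroot(function(x) weibull_cdf(x, 0.05, 3) - 0.5, c(1, 100),
                    tol = 1e-10)$root
  expect_equal(fitted_bmi(fit, 0.5), target, tolerance = 1e-6)
  expect_equal(fitted_bmi(fit, 0.5), log(2)^(1 / 3) / 0.05, tolerance = 1e-12)
  # criterion 1 - e^-1 gives exactly 1/a; beta = 1 gives ln 2 / a
  expect_equal(fitted_bmi(fit, -expm1(-1)), 1 / 0.05, tolerance = 1e-12)
  expect_equal(fitted_bmi(list(a = 0.04, beta = 1, converged = TRUE), 0.5),
               log(2) / 0.04, tolerance = 1e-12)
  expect_error(fitted_bmi(list(a = 1, beta = 1, converged = FALSE)),
               "converge")
  # strictly decreasing in a at fixed beta and criterion
  a_grid <- seq(0.02, 0.2, by = 0.01)
  pse <- sapply(a_grid, function(a)
    fitted_bmi(list(a = a, beta = 4, converged = TRUE)))
  expect_true(all(diff(pse) < 0))
})

test_that("fit_weibull recovers known observers", {
  # noiseless responses thresholded at f = 0.5 on a dense BMI grid: the
  # recovered PSE is pinned between the neighbouring stimulus values
  dense <- data.frame(bmi = rep(seq(10, 40, by = 0.2), 2))
  dense$response <- as.integer(weibull_cdf(dense$bmi, 0.051, 6) > 0.5)
  ft <- fit_weibull(dense)
  expect_true(ft$converged)
  true_pse <- log(2)^(1 / 6) / 0.051
  expect_lt(abs(fitted_bmi(ft) - true_pse) / true_pse, 0.02)
  # stochastic responses at the design's trial count
  st <- make_stimulus_set(seed = 5)
  ts <- make_trial_sequence(st, seed = 5)
  set.seed(11)
  resp2 <- data.frame(bmi = ts$bmi,
                      response = rbinom(nrow(ts), 1,
                                        weibull_cdf(ts$bmi, 0.051, 6)))
  ft2 <- fit_weibull(resp2)
  expect_lt(abs(fitted_bmi(ft2) - true_pse), 1)
})

test_that("fit_weibull is invariant to data duplication and start grids", {
  st <- make_stimulus_set(seed = 6)
  ts <- make_trial_sequence(st, seed = 6)
  set.seed(3)
  resp <- data.frame(bmi = ts$bmi,
                     response = rbinom(nrow(ts), 1,
                                       weibull_cdf(ts$bmi, 0.06, 5)))
  f1 <- fit_weibull(resp)
  f2 <- fit_weibull(rbind(resp, resp))
  expect_equal(f1$a, f2$a, tolerance = 1e-5)
  expect_equal(f1$beta, f2$beta, tolerance = 1e-5)
  # dispersed starts reach the same optimum
  f3 <- fit_weibull(resp, beta_grid = c(0.5, 2, 8, 20))
  expect_equal(f1$a, f3$a, tolerance = 1e-4)
  expect_equal(f1$beta, f3$beta, tolerance = 1e-4)
})

test_that("degenerate and inverted response patterns are flagged", {
  resp <- data.frame(bmi = c(15, 20, 25, 30), response = c(1, 1, 1, 1))
  ft <- fit_weibull(resp)
  expect_false(ft$converged)
  expect_match(ft$note, "degenerate")
  expect_error(fit_weibull(data.frame(bmi = rep(20, 4),
                                      response = c(0, 1, 0, 1))), "distinct")
  # reversed coding is auto-detected
  st <- make_stimulus_set(seed = 2)
  ts <- make_trial_sequence(st, seed = 2)
  set.seed(4)
  y <- rbinom(nrow(ts), 1, weibull_cdf(ts$bmi, 0.05, 6))
  finv <- fit_weibull(data.frame(bmi = ts$bmi, response = 1 - y))
  expect_true(finv$inverted)
  expect_equal(fitted_bmi(finv),
               fitted_bmi(fit_weibull(data.frame(bmi = ts$bmi, response = y))),
               tolerance = 1e-6)
})

test_that("BPI arithmetic and invariances hold", {
  expect_equal(compute_bpi(20, 20), 100)
  expect_equal(compute_bpi(25, 20), 125)
  expect_equal(compute_bpi(19.61, 19.61), 100)
  expect_error(compute_bpi(10, 0), "positive")
  # scale invariance
  set.seed(8)
  v <- runif(20, 10, 40); r <- runif(20, 10, 40); c0 <- runif(20, 0.1, 10)
  expect_equal(compute_bpi(v, r), compute_bpi(v * c0, r * c0),
               tolerance = 1e-12)
  expect_equal(metric_bpi(c(65, 25, 45), c(65, 25, 45)), 100)
})

test_that("median split labels AN subgroups per the tie rule", {
  ms <- median_split(c(120, 130))
  expect_equal(ms$median, 125)
  expect_equal(as.character(sort(ms$labels$label)), c("AN1", "AN2"))
  expect_warning(ms2 <- median_split(c(110, 110, 110)), "degenerate")
  expect_true(all(ms2$labels$label == "AN1"))
  expect_error(median_split(100), ">= 2")
  # odd n with distinct values: sizes differ by exactly 1 (brute force)
  set.seed(13)
  for (i in 1:20) {
    n <- sample(c(3, 5, 7, 9), 1)
    v <- sample(seq(100, 160, by = 2), n)
    tab <- table(median_split(v)$labels$label)
    expect_equal(abs(tab[["AN1"]] - tab[["AN2"]]), 1)
  }
})

test_that("behavioural statistics match direct oracles", {
  # identical groups: t = 0, d = 0
  x <- c(1, 2, 3, 4, 1, 2, 3, 4)
  g <- factor(rep(c("AN", "HC"), each = 4))
  gt <- group_ttest(x, g)
  expect_equal(gt$t, 0)
  expect_equal(gt$d, 0)
  # balanced 2x2 fixture against an aov multistratum oracle
  set.seed(21)
  n <- 8
  subj <- rep(sprintf("S%02d", 1:(2 * n)), each = 2)
  grp <- rep(rep(c("AN", "HC"), each = n), each = 2)
  task <- rep(c("body", "bar"), 2 * n)
  y <- rnorm(4 * n) + (grp == "AN") * (task == "body") * 2
  ours <- mixed_anova_2x2(y, task, grp, subj)
  df <- data.frame(y = y, task = factor(task), grp = factor(grp),
                   subj = factor(subj))
  fit <- summary(aov(y ~ task * grp + Error(subj / task), data = df))
  pick <- function(stratum, term) {
    tab <- fit[[stratum]][[1]]
    tab$`F value`[trimws(rownames(tab)) == term]
  }
  f_grp <- pick("Error: subj", "grp")
  f_task <- pick("Error: subj:task", "task")
  f_int <- pick("Error: subj:task", "task:grp")
  expect_equal(ours$F[ours$effect == "group"], f_grp, tolerance = 1e-8)
  expect_equal(ours$F[ours$effect == "task"], f_task, tolerance = 1e-8)
  expect_equal(ours$F[ours$effect == "task:group"], f_int, tolerance = 1e-8)
  # Cohen's d converges to delta/sigma for large samples
  set.seed(22)
  xx <- c(rnorm(4000, 0, 2), rnorm(4000, 1, 2))
  gg <- factor(rep(c("a", "b"), each = 4000))
  expect_equal(abs(group_ttest(xx, gg)$d), 0.5, tolerance = 0.1)
})

test_that("the full behavioural pipeline produces group differences", {
  co <- make_cohort(n_an = 8, n_hc = 8, seed = 31)
  st <- make_stimulus_set(seed = 31)
  resp <- simulate_cohort_responses(co, st, seed = 31)
  bpi <- fit_bpi_table(resp, setNames(co$actual_bmi, co$subject_id))
  expect_true(all(bpi$converged))
  met <- simulate_metric_task(co, seed = 31)
  met_rows <- do.call(rbind, lapply(split(met, met$subject_id), function(sl)
    data.frame(subject_id = sl$subject_id[1], group = sl$group[1],
               kind = "metric", bpi = metric_bpi(sl$estimated_cm, sl$measured_cm))))
  stats <- behavioural_stats(rbind(bpi[, c("subject_id", "group", "kind", "bpi")],
                                   met_rows))
  # AN overestimates in the self-referential tasks by construction
  expect_gt(stats$metric$t, 0)
  expect_gt(mean(bpi$bpi[bpi$kind == "body" & bpi$group == "AN"]),
            mean(bpi$bpi[bpi$kind == "body" & bpi$group == "HC"]))
  expect_s3_class(stats$depictive_anova, "data.frame")
  expect_equal(nrow(stats$median_split$labels), 8)
})

test_that("least-squares and likelihood fits agree on clean data", {
  st <- make_stimulus_set(seed = 12)
  ts <- make_trial_sequence(st, n_repeats = 6, seed = 12)
  set.seed(12)
  resp <- data.frame(bmi = ts$bmi,
                     response = rbinom(nrow(ts), 1,
                                       weibull_cdf(ts$bmi, 0.055, 5)))
  ml <- fit_weibull(resp)
  ls <- fit_weibull_ls(resp)
  expect_true(ls$converged)
  expect_lt(abs(fitted_bmi(ls) - fitted_bmi(ml)), 0.5)
  # degenerate proportions flagged, not estimated
  flat <- data.frame(bmi = c(15, 20, 25), response = c(1, 1, 1))
  expect_false(fit_weibull_ls(flat)$converged)
})
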