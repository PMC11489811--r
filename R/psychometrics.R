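#' Weibull psychometric function
#'
#' `f(x) = 1 - exp(-(a x)^beta)`, the cumulative Weibull used as the
#' psychometric function mapping stimulus BMI to the probability of a
#' "wider" judgment.
#'
#' @param x Stimulus magnitude (BMI, kg/m^2), `x >= 0`.
#' @param a Scale parameter, 1/(kg/m^2), `a > 0`.
#' @param beta Slope parameter (dimensionless), `beta > 0`.
#' @return Probability in `[0, 1)`.
#' @export
weibull_cdf <- function(x, a, beta) {
  if (any(a <= 0) || any(beta <= 0))
    stop("weibull_cdf: 'a' and 'beta' must be positive", call. = FALSE)
  if (any(x < 0)) stop("weibull_cdf: 'x' must be non-negative", call. = FALSE)
  -expm1(-(a * x)^beta)
}

#' Fit a Weibull psychometric function by maximum likelihood
#'
#' Maximises the Bernoulli likelihood of trial-level binary responses under
#' `P(wider | bmi) = weibull_cdf(bmi, a, beta)`. Parameters are optimised on
#' the log scale (enforcing positivity) with a fixed multi-start grid:
#' candidate PSEs at quantiles of the stimulus range crossed with slopes
#' `beta in {1, 3, 6, 12}`; the best optimum is returned, making the fit
#' deterministic given the data.
#'
#' If responses decrease with BMI the fit is performed on the flipped
#' responses and flagged via `inverted = TRUE` (the direction coding of
#' "narrower"/"wider" is auto-detected). Degenerate data (a single response
#' category) yield a non-converged record with boundary diagnostics rather
#' than a silent estimate.
#'
#' @param responses ResponseTable slice for one subject and task: a data
#'   frame with numeric `bmi` and binary `response` columns.
#' @param beta_grid Multi-start slope values.
#' @return Object of class `bse_psychometric_fit`: list with `a`, `beta`,
#'   `n_trials`, `converged`, `inverted`, `neg_log_likelihood`, `note`.
#' @export
fit_weibull <- function(responses, beta_grid = c(1, 3, 6, 12)) {
  stopifnot(is.data.frame(responses),
            all(c("bmi", "response") %in% names(responses)))
  x <- responses$bmi
  y <- responses$response
  stopifnot(all(y %in% c(0, 1)))
  if (length(unique(x)) < 2)
    stop("fit_weibull: need >= 2 distinct stimulus BMIs", call. = FALSE)

  out <- list(a = NA_real_, beta = NA_real_, n_trials = length(y),
              converged = FALSE, inverted = FALSE,
              neg_log_likelihood = NA_real_, note = "")
  class(out) <- "bse_psychometric_fit"

  if (length(unique(y)) < 2) {
    out$note <- sprintf(
      "degenerate data: all responses are %d; likelihood maximised at a %s boundary",
      y[1], if (y[1] == 1) "steep/low-PSE" else "flat/high-PSE")
    return(out)
  }

  # auto-detect slope direction: "wider" should become more likely with BMI
  if (stats::cor(x, y) < 0) {
    y <- 1 - y
    out$inverted <- TRUE
  }

  nll <- function(par) {
    a <- exp(par[1]); b <- exp(par[2])
    eta <- (a * x)^b
    # log p and log(1-p) computed stably: p = 1 - exp(-eta)
    lp <- log(-expm1(-pmin(eta, 700)))
    lq <- -eta
    -sum(ifelse(y == 1, lp, lq))
  }

  pse_grid <- stats::quantile(x, c(0.15, 0.35, 0.5, 0.65, 0.85), names = FALSE)
  best <- NULL
  for (b0 in beta_grid) {
    for (pse0 in pse_grid) {
      a0 <- log(2)^(1 / b0) / pse0
      fit <- try(stats::optim(c(log(a0), log(b0)), nll, method = "L-BFGS-B",
                              lower = c(log(1e-4), log(0.05)),
                              upper = c(log(10), log(60))), silent = TRUE)
      if (inherits(fit, "try-error")) next
      if (is.null(best) || fit$value < best$value - 1e-12) best <- fit
    }
  }
  if (is.null(best)) {
    out$note <- "all optimisation starts failed"
    return(out)
  }
  out$a <- exp(best$par[1])
  out$beta <- exp(best$par[2])
  out$neg_log_likelihood <- best$value
  out$converged <- best$convergence == 0
  out
}

#' Fit a Weibull psychometric function by least squares on proportions
#'
#' Comparison method to the maximum-likelihood fit: responses are pooled
#' into per-stimulus "wider" proportions and the Weibull CDF is fitted by
#' unweighted least squares. Kept for methodological comparison; the
#' likelihood fit is the default analysis because binary trial data are
#' Bernoulli, not homoscedastic.
#'
#' @inheritParams fit_weibull
#' @return A `bse_psychometric_fit` object (`neg_log_likelihood` slot holds
#'   the residual sum of squares instead).
#' @export
fit_weibull_ls <- function(responses, beta_grid = c(1, 3, 6, 12)) {
  stopifnot(all(c("bmi", "response") %in% names(responses)))
  agg <- stats::aggregate(response ~ bmi, data = responses, FUN = mean)
  x <- agg$bmi; pr <- agg$response
  out <- list(a = NA_real_, beta = NA_real_, n_trials = nrow(responses),
              converged = FALSE, inverted = FALSE,
              neg_log_likelihood = NA_real_, note = "least-squares fit")
  class(out) <- "bse_psychometric_fit"
  if (length(x) < 2) stop("fit_weibull_ls: need >= 2 distinct stimulus BMIs",
                          call. = FALSE)
  if (stats::sd(pr) == 0) {
    out$note <- "degenerate data: constant response proportion"
    return(out)
  }
  if (stats::cor(x, pr) < 0) { pr <- 1 - pr; out$inverted <- TRUE }
  rss <- function(par)
    sum((pr - weibull_cdf(x, exp(par[1]), exp(par[2])))^2)
  pse_grid <- stats::quantile(x, c(0.15, 0.35, 0.5, 0.65, 0.85), names = FALSE)
  best <- NULL
  for (b0 in beta_grid) for (pse0 in pse_grid) {
    fit <- try(stats::optim(c(log(log(2)^(1 / b0) / pse0), log(b0)), rss,
                            method = "L-BFGS-B",
                            lower = c(log(1e-4), log(0.05)),
                            upper = c(log(10), log(60))), silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) || fit$value < best$value - 1e-12) best <- fit
  }
  if (is.null(best)) { out$note <- "all starts failed"; return(out) }
  out$a <- exp(best$par[1]); out$beta <- exp(best$par[2])
  out$neg_log_likelihood <- best$value
  out$converged <- best$convergence == 0
  out
}

#' @export
print.bse_psychometric_fit <- function(x, ...) {
  if (x$converged)
    cat(sprintf(
      "<Weibull fit: a = %.4f, beta = %.2f, PSE = %.2f, nLL = %.2f, n = %d%s>\n",
      x$a, x$beta, fitted_bmi(x), x$neg_log_likelihood, x$n_trials,
      if (x$inverted) ", inverted" else ""))
  else cat(sprintf("<Weibull fit: NOT converged (%s)>\n", x$note))
  invisible(x)
}

#' Fitted BMI (point of subjective equality) of a psychometric fit
#'
#' Inverts the fitted Weibull at a response criterion, by default
#' `P(wider) = 0.5`: `x = (-log(1 - criterion))^(1/beta) / a`. The 0.5
#' criterion is the standard point of subjective equality and defines the
#' "fitted BMI" used for the body perception indices.
#'
#' @param fit A converged [fit_weibull()] object (or any list with `a`,
#'   `beta`, `converged`).
#' @param criterion Response probability in (0, 1).
#' @return Fitted BMI in kg/m^2.
#' @export
fitted_bmi <- function(fit, criterion = 0.5) {
  stopifnot(criterion > 0, criterion < 1)
  if (!isTRUE(fit$converged))
    stop("fitted_bmi: fit did not converge", call. = FALSE)
  (-log1p(-criterion))^(1 / fit$beta) / fit$a
}

#' Body perception index
#'
#' `BPI = value / reference x 100`; values above 100 indicate
#' overestimation. For the depictive tasks `value` is the fitted BMI and
#' `reference` the subject's actual BMI (body task) or the BMI of the
#' picture matching the comparison bar (bar task, 19.61). For the metric
#' task use [metric_bpi()], which averages per-part indices.
#'
#' @param value Estimated magnitude (> 0 expected).
#' @param reference Reference magnitude (> 0).
#' @return BPI in percent.
#' @export
compute_bpi <- function(value, reference) {
  if (any(reference <= 0))
    stop("compute_bpi: reference must be positive", call. = FALSE)
  value / reference * 100
}

#' Metric-task body perception index
#'
#' Per body part (waist, upper arm, thigh) a BPI is computed as
#' estimated/measured x 100; their mean is the total metric BPI.
#'
#' @param estimated,measured Numeric vectors of circumferences (same length,
#'   same units).
#' @return Total metric BPI in percent.
#' @export
metric_bpi <- function(estimated, measured) {
  stopifnot(length(estimated) == length(measured))
  mean(compute_bpi(estimated, measured))
}

#' Median split of patients by body-task BPI
#'
#' Splits the AN group into AN1 (slight overestimation, `bpi <= median`) and
#' AN2 (distinct overestimation, `bpi > median`). With an odd number of
#' distinct values the subgroup sizes differ by exactly one. If all values
#' are equal the split is degenerate: everyone is labelled AN1 and a warning
#' is raised.
#'
#' @param bpi Numeric body-task BPI values of the AN subjects.
#' @param subject_id Optional subject identifiers (defaults to indices).
#' @return List with `median`, and `labels`: data frame of `subject_id`,
#'   `bpi`, `label` (factor AN1/AN2).
#' @export
median_split <- function(bpi, subject_id = NULL) {
  if (length(bpi) < 2) stop("median_split: need >= 2 subjects", call. = FALSE)
  if (is.null(subject_id)) subject_id <- seq_along(bpi)
  med <- stats::median(bpi)
  lab <- factor(ifelse(bpi <= med, "AN1", "AN2"), levels = c("AN1", "AN2"))
  if (all(lab == "AN1"))
    warning("median_split: degenerate split (all values <= median)")
  list(median = med,
       labels = data.frame(subject_id = subject_id, bpi = bpi, label = lab,
                           stringsAsFactors = FALSE))
}

#' Fit psychometric functions and tabulate BPIs for a whole ResponseTable
#'
#' Convenience wrapper: for each subject x task slice, fit the Weibull,
#' derive the fitted BMI and the task's BPI (body: reference = subject's
#' actual BMI; bar: reference = `bar_reference_bmi`).
#'
#' @param responses Full ResponseTable (see [simulate_cohort_responses()]).
#' @param actual_bmi Named vector mapping subject_id to actual BMI (needed
#'   for body-task BPIs).
#' @param criterion PSE criterion passed to [fitted_bmi()].
#' @param bar_reference_bmi Reference BMI for the bar task (default 19.61).
#' @return Data frame: `subject_id`, `group`, `kind` (body/bar), `fitted`
#'   (kg/m^2), `reference`, `bpi`, `converged`.
#' @export
fit_bpi_table <- function(responses, actual_bmi, criterion = 0.5,
                          bar_reference_bmi = 19.61) {
  keys <- unique(responses[, c("subject_id", "group", "task")])
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    sl <- responses[responses$subject_id == keys$subject_id[i] &
                      responses$task == keys$task[i], ]
    ft <- fit_weibull(sl)
    fb <- if (ft$converged) fitted_bmi(ft, criterion) else NA_real_
    ref <- if (keys$task[i] == "bar") bar_reference_bmi
           else unname(actual_bmi[keys$subject_id[i]])
    data.frame(subject_id = keys$subject_id[i], group = keys$group[i],
               kind = keys$task[i], fitted = fb, reference = ref,
               bpi = if (is.na(fb)) NA_real_ else compute_bpi(fb, ref),
               converged = ft$converged, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
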