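#' Integer orthogonal polynomial contrast weights
#'
#' Classical tables for equally spaced levels: for `k = 6`, linear
#' `(-5, -3, -1, 1, 3, 5)` and quadratic `(5, -1, -4, -4, -1, 5)`. For
#' other `k` the weights are `stats::contr.poly(k)` columns rescaled to the
#' smallest integer pattern. Weights always sum to zero, and linear and
#' quadratic weights are mutually orthogonal; the resulting F statistics
#' are invariant to the scaling.
#'
#' @param k Number of ordered levels.
#' @param degree 1 (linear) or 2 (quadratic).
#' @return Numeric weight vector of length `k`.
#' @export
poly_weights <- function(k, degree) {
  stopifnot(degree %in% 1:2, k >= degree + 1)
  w <- stats::contr.poly(k)[, degree]
  w <- w / min(abs(w[abs(w) > 1e-12]))
  round(w, 10)
}

#' Planned polynomial (trend) contrasts over ordered condition means
#'
#' For every subject, the linear and quadratic contrast scores over the
#' `k` ordered levels (body-picture categories) are computed; each trend is
#' tested against zero with a one-sample t (reported as `F = t^2`), and, if
#' a group factor is supplied, between groups with an independent-samples t
#' (the trend x group interaction).
#'
#' @param cell_means Subjects x levels matrix of condition means (levels in
#'   increasing BMI order).
#' @param group Optional two-level factor for between-group trend
#'   differences.
#' @return Data frame of class `bse_contrast_result`: one row per trend
#'   (and per trend x group test), with `F`, `df1`, `df2`, `p`, `eta_p2`.
#' @export
polynomial_contrast <- function(cell_means, group = NULL) {
  cell_means <- as.matrix(cell_means)
  k <- ncol(cell_means); N <- nrow(cell_means)
  if (k < 3) stop("quadratic contrast needs >= 3 levels", call. = FALSE)
  rows <- list()
  scale_tol <- 1e-12 * (1 + max(abs(cell_means)))
  safe_t1 <- function(sc) {
    if (stats::sd(sc) <= scale_tol) {
      if (abs(mean(sc)) <= scale_tol) return(list(t = 0, p = 1))
      return(list(t = Inf, p = 0))
    }
    tt <- stats::t.test(sc)
    list(t = unname(tt$statistic), p = tt$p.value)
  }
  for (degree in 1:2) {
    w <- poly_weights(k, degree)
    sc <- as.numeric(cell_means %*% w)
    tt <- safe_t1(sc)
    Fv <- tt$t^2
    rows[[length(rows) + 1]] <- data.frame(
      trend = c("linear", "quadratic")[degree], test = "mean",
      F = Fv, df1 = 1, df2 = N - 1, p = tt$p,
      eta_p2 = Fv / (Fv + N - 1),
      score_mean = mean(sc), stringsAsFactors = FALSE)
    if (!is.null(group)) {
      g <- droplevels(as.factor(group))
      stopifnot(nlevels(g) == 2, length(g) == N)
      tg <- stats::t.test(sc ~ g, var.equal = TRUE)
      Fg <- unname(tg$statistic)^2
      rows[[length(rows) + 1]] <- data.frame(
        trend = c("linear", "quadratic")[degree], test = "group",
        F = Fg, df1 = 1, df2 = N - 2, p = tg$p.value,
        eta_p2 = Fg / (Fg + N - 2),
        score_mean = unname(diff(rev(tapply(sc, g, mean)))),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("bse_contrast_result", class(out))
  out
}

#' Post-hoc t-tests on cluster means
#'
#' Paired t-tests between within-subject conditions (with Cohen's d from
#' the difference SD) and, optionally, independent-samples group tests per
#' condition.
#'
#' @param values Subjects x conditions matrix of cluster-mean activity.
#' @param comparisons List of length-2 vectors of column names/indices to
#'   compare pairwise within subjects; defaults to all pairs.
#' @param group Optional two-level factor; adds per-condition group tests.
#' @return Data frame with `comparison`, `type`, `t`, `df`, `p`, `d`.
#' @export
posthoc_ttests <- function(values, comparisons = NULL, group = NULL) {
  values <- as.matrix(values)
  if (nrow(values) < 2) stop("posthoc_ttests: need n >= 2", call. = FALSE)
  cn <- colnames(values)
  if (is.null(cn)) cn <- colnames(values) <- paste0("C", seq_len(ncol(values)))
  if (is.null(comparisons))
    comparisons <- utils::combn(cn, 2, simplify = FALSE)
  rows <- lapply(comparisons, function(cmp) {
    x <- values[, cmp[1]]; y <- values[, cmp[2]]
    dif <- x - y
    if (stats::sd(dif) == 0) {
      tv <- if (mean(dif) == 0) 0 else Inf * sign(mean(dif))
      tt <- list(statistic = tv, parameter = length(dif) - 1,
                 p.value = if (tv == 0) 1 else 0)
    } else tt <- stats::t.test(x, y, paired = TRUE)
    data.frame(comparison = paste(cmp[1], "vs", cmp[2]), type = "paired",
               t = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value, d = cohens_d_paired(x, y),
               stringsAsFactors = FALSE)
  })
  if (!is.null(group)) {
    g <- droplevels(as.factor(group))
    for (cc in cn) {
      gt <- group_ttest(values[, cc], g)
      rows[[length(rows) + 1]] <- data.frame(
        comparison = paste0(cc, ": ", paste(levels(g), collapse = " vs ")),
        type = if (gt$welch) "independent (Welch)" else "independent",
        t = gt$t, df = gt$df, p = gt$p, d = gt$d, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
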