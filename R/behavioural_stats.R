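#' Levene's test for equality of group variances
#'
#' One-way Levene test (mean-centred absolute deviations, the SPSS default),
#' used to decide whether the Welch correction is applied to group t-tests.
#'
#' @param x Numeric values.
#' @param g Group factor.
#' @param center `"mean"` (default) or `"median"` (Brown-Forsythe).
#' @return List with `F`, `df1`, `df2`, `p`.
#' @export
levene_test <- function(x, g, center = c("mean", "median")) {
  center <- match.arg(center)
  g <- droplevels(as.factor(g))
  cfun <- if (center == "mean") mean else stats::median
  d <- abs(x - stats::ave(x, g, FUN = cfun))
  fit <- tryCatch(suppressWarnings(stats::anova(stats::lm(d ~ g))),
                  error = function(e) NULL)
  if (is.null(fit))
    return(list(F = NA_real_, df1 = NA_real_, df2 = NA_real_, p = NA_real_))
  list(F = fit$`F value`[1], df1 = fit$Df[1], df2 = fit$Df[2],
       p = fit$`Pr(>F)`[1])
}

#' Two-group comparison with Cohen's d
#'
#' Independent-samples t-test; the Welch correction is used when Levene's
#' test rejects equal variances at `levene_alpha` (mirroring reporting
#' conventions with fractional dfs). Cohen's d uses the pooled SD.
#'
#' @param x Numeric values.
#' @param g Two-level group factor.
#' @param levene_alpha Significance level of the variance pre-test.
#' @return List with `t`, `df`, `p`, `d`, `welch`, group means.
#' @export
group_ttest <- function(x, g, levene_alpha = 0.05) {
  g <- droplevels(as.factor(g))
  stopifnot(nlevels(g) == 2)
  if (any(table(g) < 2)) stop("group_ttest: each group needs n >= 2",
                              call. = FALSE)
  lev <- levene_test(x, g)
  welch <- is.finite(lev$p) && lev$p < levene_alpha
  tt <- stats::t.test(x ~ g, var.equal = !welch)
  n <- tabulate(g)
  m <- tapply(x, g, mean)
  v <- tapply(x, g, stats::var)
  sd_pooled <- sqrt(((n[1] - 1) * v[1] + (n[2] - 1) * v[2]) / (sum(n) - 2))
  d <- if (sd_pooled > 0) unname(diff(rev(m)) / sd_pooled) else 0
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, d = d, welch = welch,
       means = m, levene_p = lev$p)
}

#' Cohen's d for paired samples
#'
#' Mean difference divided by the SD of the differences.
#'
#' @param x,y Paired numeric vectors.
#' @return Cohen's d.
#' @export
cohens_d_paired <- function(x, y) {
  d <- x - y
  s <- stats::sd(d)
  if (s == 0) return(0)
  mean(d) / s
}

#' Mixed 2 (task) x 2 (group) ANOVA on BPI values
#'
#' Classical split-plot ANOVA with one two-level within factor and one
#' two-level between factor, computed from sum and difference scores
#' (unweighted-means / Type III solution for unbalanced groups). Reports F,
#' dfs, p and partial eta^2 for the task, group, and task x group effects.
#'
#' @param value Numeric outcome (e.g. BPI).
#' @param task Two-level within factor.
#' @param group Two-level between factor.
#' @param subject Subject identifier; each subject must have both task
#'   levels.
#' @return Data frame with one row per effect.
#' @export
mixed_anova_2x2 <- function(value, task, group, subject) {
  task <- droplevels(as.factor(task)); group <- droplevels(as.factor(group))
  stopifnot(nlevels(task) == 2, nlevels(group) == 2)
  wide <- stats::reshape(
    data.frame(value = value, task = task, subject = as.character(subject)),
    idvar = "subject", timevar = "task", direction = "wide")
  if (anyNA(wide)) stop("mixed_anova_2x2: incomplete within-subject data",
                        call. = FALSE)
  g <- group[match(wide$subject, as.character(subject))]
  if (any(tabulate(g) < 2)) stop("mixed_anova_2x2: each group needs n >= 2",
                                 call. = FALSE)
  y1 <- wide[[2]]; y2 <- wide[[3]]
  zs <- (y1 + y2) / sqrt(2)   # carries the between-group effect
  zd <- (y1 - y2) / sqrt(2)   # carries task and task x group
  n <- tabulate(g); N <- sum(n)
  one <- function(z, effect) {
    m <- tapply(z, g, mean)
    sse <- sum((z - m[g])^2)
    if (effect == "intercept") {
      ss <- (mean(m))^2 * 4 / (1 / n[1] + 1 / n[2])
    } else {
      ss <- (m[1] - m[2])^2 / (1 / n[1] + 1 / n[2])
    }
    Fv <- ss / (sse / (N - 2))
    c(F = unname(Fv), ss = unname(ss), sse = sse)
  }
  rows <- rbind(
    group = one(zs, "group"),
    task = one(zd, "intercept"),
    `task:group` = one(zd, "group")
  )
  data.frame(
    effect = rownames(rows),
    F = rows[, "F"], df1 = 1, df2 = N - 2,
    p = stats::pf(rows[, "F"], 1, N - 2, lower.tail = FALSE),
    eta_p2 = rows[, "ss"] / (rows[, "ss"] + rows[, "sse"]),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Behavioural group statistics for a BPI table
#'
#' Runs the full behavioural analysis: independent-samples comparison of
#' metric BPIs (Welch-corrected when variances differ), the 2 (task: body,
#' bar) x 2 (group) mixed ANOVA on the depictive BPIs with per-task group
#' t-tests, and the median split of AN patients on body-task BPIs.
#'
#' @param bpi_table Data frame with columns `subject_id`, `group`, `kind`
#'   (`metric`, `body`, `bar`) and `bpi` (see [fit_bpi_table()]).
#' @return List of class `bse_behavioural_stats`: `metric` (t-test),
#'   `depictive_anova`, `posthoc` (per-task t-tests), `median_split`.
#' @export
behavioural_stats <- function(bpi_table) {
  stopifnot(all(c("subject_id", "group", "kind", "bpi") %in% names(bpi_table)))
  out <- list()
  met <- bpi_table[bpi_table$kind == "metric", ]
  if (nrow(met) > 3) out$metric <- group_ttest(met$bpi, met$group)
  dep <- bpi_table[bpi_table$kind %in% c("body", "bar") & !is.na(bpi_table$bpi), ]
  complete <- names(which(table(dep$subject_id) == 2))
  dep <- dep[dep$subject_id %in% complete, ]
  if (length(complete) >= 4) {
    out$depictive_anova <- mixed_anova_2x2(dep$bpi, dep$kind, dep$group,
                                           dep$subject_id)
    out$posthoc <- lapply(split(dep, dep$kind), function(sl)
      group_ttest(sl$bpi, sl$group))
  }
  an_body <- dep[dep$kind == "body" & dep$group == "AN", ]
  if (nrow(an_body) >= 2)
    out$median_split <- median_split(an_body$bpi, an_body$subject_id)
  class(out) <- "bse_behavioural_stats"
  out
}

#' @export
print.bse_behavioural_stats <- function(x, ...) {
  if (!is.null(x$metric))
    cat(sprintf("metric BPI:  t(%.2f) = %.3f, p = %.3g, d = %.3f%s\n",
                x$metric$df, x$metric$t, x$metric$p, x$metric$d,
                if (x$metric$welch) " (Welch)" else ""))
  if (!is.null(x$depictive_anova)) {
    a <- x$depictive_anova
    for (i in seq_len(nrow(a)))
      cat(sprintf("depictive %-10s F(%d,%d) = %.3f, p = %.3g, eta_p2 = %.3f\n",
                  a$effect[i], a$df1[i], a$df2[i], a$F[i], a$p[i], a$eta_p2[i]))
  }
  if (!is.null(x$median_split))
    cat(sprintf("AN median body-task BPI = %.2f (AN1 n = %d, AN2 n = %d)\n",
                x$median_split$median,
                sum(x$median_split$labels$label == "AN1"),
                sum(x$median_split$labels$label == "AN2")))
  invisible(x)
}
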