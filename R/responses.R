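#' Simulate dichotomous size judgments for one subject and task
#'
#' Draws the binary "wider" / "narrower" response for every trial from a
#' Bernoulli distribution with
#' `p(wider) = lapse/2 + (1 - lapse) * weibull_cdf(bmi, a, beta)`.
#'
#' @param trial_sequence A [make_trial_sequence()] data frame.
#' @param stimulus_set The stimulus set the sequence was built from (kept for
#'   interface symmetry; BMI values are carried on the sequence).
#' @param a,beta Weibull scale (1/(kg/m^2)) and slope of the observer.
#' @param lapse_rate Stimulus-independent guessing probability in `[0, 0.5)`.
#' @param subject_id,group,task Labels copied into the output table.
#' @param seed Integer RNG seed (`NULL` to use the current RNG stream).
#' @return Data frame (a ResponseTable slice) with columns `subject_id`,
#'   `group`, `task`, `trial_index`, `stimulus_id`, `bmi`, `category`,
#'   `response` (0 = narrower, 1 = wider).
#' @export
simulate_binary_responses <- function(trial_sequence, stimulus_set = NULL,
                                      a, beta, lapse_rate = 0,
                                      subject_id = "S001", group = "HC",
                                      task = "body", seed = NULL) {
  stopifnot(a > 0, beta > 0, lapse_rate >= 0, lapse_rate < 0.5)
  withr_seed(seed)
  p <- lapse_rate / 2 + (1 - lapse_rate) * weibull_cdf(trial_sequence$bmi, a, beta)
  data.frame(
    subject_id = subject_id,
    group = group,
    task = task,
    trial_index = trial_sequence$trial_index,
    stimulus_id = trial_sequence$stimulus_id,
    bmi = trial_sequence$bmi,
    category = trial_sequence$category,
    response = stats::rbinom(nrow(trial_sequence), 1L, p),
    stringsAsFactors = FALSE
  )
}

#' Simulate the behavioural arm of the study for a whole cohort
#'
#' For every subject and both depictive tasks (body, bar) a fresh constrained
#' trial sequence is generated and binary responses are drawn from the
#' subject's latent Weibull observer.
#'
#' @param cohort A [make_cohort()] data frame.
#' @param stimulus_set A [make_stimulus_set()] data frame.
#' @param n_repeats,max_run Passed to [make_trial_sequence()].
#' @param seed Integer base seed; per-subject/task seeds are derived from it.
#' @return A full ResponseTable data frame (rows = subjects x tasks x trials).
#' @export
simulate_cohort_responses <- function(cohort, stimulus_set, n_repeats = 3,
                                      max_run = 3, seed = 1L) {
  tasks <- c("body", "bar")
  res <- vector("list", nrow(cohort) * length(tasks))
  k <- 0L
  for (i in seq_len(nrow(cohort))) {
    for (tk in tasks) {
      k <- k + 1L
      sub_seed <- (as.numeric(seed) * 131 + i * 7 +
                     match(tk, tasks)) %% 2^31  # double arithmetic: no overflow
      ts <- make_trial_sequence(stimulus_set, n_repeats = n_repeats,
                                max_run = max_run, seed = sub_seed)
      a <- if (tk == "body") cohort$a_body[i] else cohort$a_bar[i]
      res[[k]] <- simulate_binary_responses(
        ts, stimulus_set, a = a, beta = cohort$true_beta[i],
        lapse_rate = cohort$lapse_rate[i],
        subject_id = cohort$subject_id[i],
        group = as.character(cohort$group[i]), task = tk, seed = NULL)
    }
  }
  do.call(rbind, res)
}

#' Simulate the metric (rope) size-estimation task
#'
#' Participants estimate the circumference of waist, upper arm and thigh;
#' the simulator scales each measured circumference by the subject's true
#' metric BPI with independent per-part noise.
#'
#' @param cohort A [make_cohort()] data frame.
#' @param measured_cm Named circumferences in cm used for every subject.
#' @param part_sd Multiplicative per-part log-normal noise SD.
#' @param seed Integer RNG seed.
#' @return Data frame with `subject_id`, `group`, `part`, `measured_cm`,
#'   `estimated_cm`.
#' @export
simulate_metric_task <- function(cohort,
                                 measured_cm = c(waist = 65, arm = 25, thigh = 45),
                                 part_sd = 0.05, seed = 1L) {
  withr_seed(seed)
  n <- nrow(cohort)
  parts <- names(measured_cm)
  out <- expand.grid(subject_id = cohort$subject_id, part = parts,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out <- out[order(match(out$subject_id, cohort$subject_id)), ]
  i <- match(out$subject_id, cohort$subject_id)
  out$group <- as.character(cohort$group[i])
  out$measured_cm <- measured_cm[out$part]
  out$estimated_cm <- out$measured_cm * cohort$bpi_metric_true[i] / 100 *
    exp(stats::rnorm(nrow(out), 0, part_sd))
  rownames(out) <- NULL
  out[, c("subject_id", "group", "part", "measured_cm", "estimated_cm")]
}

#' Read/write a ResponseTable as tab-separated text
#'
#' @param x ResponseTable data frame.
#' @param path File path.
#' @return `read_response_table` returns the data frame;
#'   `write_response_table` returns `path` invisibly.
#' @export
write_response_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_response_table
#' @export
read_response_table <- function(path) {
  out <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  out$category <- factor(out$category)
  out
}
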