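#' Generate a constrained pseudo-random trial sequence
#'
#' Each stimulus is presented `n_repeats` times in a shuffled order with at
#' most `max_run` consecutive trials from the same BMI category and
#' approximately equal category transition probabilities. Inter-stimulus
#' intervals are drawn uniformly from `isi_center_s` +/- `isi_jitter_s`
#' (defaults 1.25 +/- 0.5 s); each picture is on screen for
#' `stim_duration_s` (0.8 s).
#'
#' The run constraint is enforced by shuffling and then repairing violations
#' with random swaps (bounded); this keeps transitions statistically uniform
#' rather than imposing an exact balanced design.
#'
#' @param stimulus_set A [make_stimulus_set()] data frame.
#' @param n_repeats Presentations per stimulus (default 3; 66 x 3 = 198
#'   trials).
#' @param max_run Maximum allowed run of same-category trials (default 3).
#' @param isi_center_s,isi_jitter_s ISI distribution parameters in seconds.
#' @param stim_duration_s Stimulus duration in seconds.
#' @param seed Integer RNG seed.
#' @param max_tries Bound on repair iterations before giving up.
#' @return Data frame of class `bse_trial_sequence` with columns
#'   `trial_index`, `stimulus_id`, `bmi`, `category`, `onset_time` (s),
#'   `isi` (s).
#' @export
make_trial_sequence <- function(stimulus_set, n_repeats = 3, max_run = 3,
                                isi_center_s = 1.25, isi_jitter_s = 0.5,
                                stim_duration_s = 0.8,
                                seed = 1L, max_tries = 20000L) {
  stopifnot(n_repeats >= 1, max_run >= 1, isi_jitter_s >= 0,
            isi_center_s - isi_jitter_s > 0)
  withr_seed(seed)
  n <- nrow(stimulus_set) * n_repeats
  idx <- sample(rep(seq_len(nrow(stimulus_set)), n_repeats))
  cat_codes <- as.integer(stimulus_set$category)

  ok <- function(v) max_category_run(v) <= max_run
  tries <- 0L
  while (!ok(cat_codes[idx])) {
    tries <- tries + 1L
    if (tries > max_tries)
      stop("could not satisfy max_run constraint after ", max_tries,
           " repair attempts", call. = FALSE)
    runs <- rle(cat_codes[idx])
    bad_run <- which(runs$lengths > max_run)[1]
    pos <- sum(runs$lengths[seq_len(bad_run)])  # last trial of the long run
    swap <- sample.int(n, 1L)
    if (cat_codes[idx[swap]] != cat_codes[idx[pos]]) {
      tmp <- idx[pos]; idx[pos] <- idx[swap]; idx[swap] <- tmp
    }
  }

  isi <- stats::runif(n, isi_center_s - isi_jitter_s,
                      isi_center_s + isi_jitter_s)
  onset <- 1 + c(0, cumsum(stim_duration_s + isi[-n]))
  out <- data.frame(
    trial_index = seq_len(n),
    stimulus_id = stimulus_set$stimulus_id[idx],
    bmi = stimulus_set$bmi[idx],
    category = stimulus_set$category[idx],
    onset_time = onset,
    isi = isi,
    stringsAsFactors = FALSE
  )
  attr(out, "stim_duration_s") <- stim_duration_s
  class(out) <- c("bse_trial_sequence", class(out))
  out
}

#' Longest same-category run in a sequence
#'
#' @param categories Vector of category labels/codes in trial order.
#' @return Integer: length of the longest run.
#' @export
max_category_run <- function(categories) {
  if (length(categories) == 0L) return(0L)
  max(rle(as.vector(categories))$lengths)
}

#' Category transition counts of a trial sequence
#'
#' Tabulates ordered (from, to) category pairs over consecutive trials;
#' useful for checking the "equal transition probability" property.
#'
#' @param trial_sequence A [make_trial_sequence()] data frame.
#' @return A square table of transition counts.
#' @export
transition_counts <- function(trial_sequence) {
  v <- trial_sequence$category
  table(from = v[-length(v)], to = v[-1])
}

#' @export
print.bse_trial_sequence <- function(x, ...) {
  cat(sprintf("<trial sequence: %d trials, max run %d, %.1f s total>\n",
              nrow(x), max_category_run(x$category),
              max(x$onset_time) + attr(x, "stim_duration_s")))
  invisible(x)
}
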