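#' Effect specification for the sensor simulator
#'
#' Describes the source-level effect structure injected into synthetic
#' recordings as a list of components. Every component activates a set of
#' shell sites with a smooth (Hanning) source time course inside a latency
#' window, scaled per trial by a non-negative multiplier for the trial's
#' (task, category, group) design cell.
#'
#' The default specification emulates the qualitative result pattern of the
#' study design this generator targets:
#' \itemize{
#'   \item `visual`: a posterior component (100-500 ms) whose amplitude is
#'     ordered body > bar > viewing across tasks and is stronger for the
#'     extreme BMI categories (quadratic picture profile) with a slight
#'     descending linear component;
#'   \item `group_picture`: a left-parietal component confined to
#'     >= 200 ms carrying a descending linear picture profile in the AN
#'     group only, producing the group x picture interaction from
#'     mid-latency on.
#' }
#'
#' @param source_space A [build_source_shell()] object (used to select
#'   target sites by direction).
#' @param tasks,categories,groups Factor levels of the design.
#' @param task_mult Named task multipliers for the visual component.
#' @param picture_quadratic Strength of the quadratic picture profile.
#' @param picture_linear Strength of the (descending) linear picture
#'   profile of the visual component.
#' @param interaction_amp_nam Source amplitude (nAm) of the group x picture
#'   component; 0 disables it.
#' @param visual_amp_nam Source amplitude (nAm) of the visual component.
#' @param interaction_onset_ms Onset of the group-specific component.
#' @return List of class `bse_effect_spec`.
#' @export
make_effect_spec <- function(source_space,
                             tasks = c("viewing", "bar", "body"),
                             categories = LETTERS[1:6],
                             groups = c("AN", "HC"),
                             task_mult = c(viewing = 1, bar = 1.45, body = 1.8),
                             picture_quadratic = 0.5,
                             picture_linear = 0.15,
                             visual_amp_nam = 20,
                             interaction_amp_nam = 12,
                             interaction_onset_ms = 200) {
  nc <- length(categories)
  qw <- stats::poly(seq_len(nc), 2)[, 2]; qw <- qw / max(abs(qw))
  lw <- seq(1, -1, length.out = nc)
  cat_mult <- 1 + picture_quadratic * (qw - min(qw)) + picture_linear * lw
  mult_visual <- array(1, c(length(tasks), nc, length(groups)),
                       dimnames = list(tasks, categories, groups))
  for (g in groups) mult_visual[, , g] <- outer(task_mult[tasks], cat_mult)
  mult_int <- array(0, c(length(tasks), nc, length(groups)),
                    dimnames = list(tasks, categories, groups))
  mult_int[, , "AN"] <- matrix(seq(2, 0, length.out = nc),
                               length(tasks), nc, byrow = TRUE)
  mult_int[, , "HC"] <- 1
  sel_dir <- function(dirvec, frac = 0.15) {
    sc <- source_space$radial %*% (dirvec / sqrt(sum(dirvec^2)))
    order(sc, decreasing = TRUE)[seq_len(max(3, round(frac * source_space$n_sites)))]
  }
  comps <- list(
    list(name = "visual", sites = sel_dir(c(0, -1, -0.2)),
         window_ms = c(100, 500), amp_nam = visual_amp_nam,
         mult = mult_visual),
    list(name = "group_picture", sites = sel_dir(c(-0.5, 0.3, 0.8)),
         window_ms = c(interaction_onset_ms, 550), amp_nam = interaction_amp_nam,
         mult = mult_int)
  )
  if (interaction_amp_nam == 0) comps <- comps[1]
  structure(list(components = comps, tasks = tasks, categories = categories,
                 groups = groups),
            class = "bse_effect_spec")
}

validate_effect_spec <- function(spec) {
  for (cmp in spec$components) {
    stopifnot(all(cmp$mult >= 0), cmp$window_ms[1] < cmp$window_ms[2],
              length(cmp$sites) >= 1, cmp$amp_nam >= 0)
  }
  invisible(TRUE)
}

#' Simulate a continuous sensor recording for one subject and task
#'
#' Every trial adds a stereotyped source time course (a Hanning bump over
#' the component's latency window) at the component's target sites, scaled
#' by the effect-spec multiplier of the trial's (task, category, group)
#' cell and by the subject's neural gain, projected to the sensors through
#' the leadfield. White Gaussian sensor noise and optionally a sinusoidal
#' line-noise component are added. Event markers record every stimulus
#' onset.
#'
#' @param trial_sequence A [make_trial_sequence()] data frame.
#' @param task Task label of this run (`viewing`, `bar`, `body`).
#' @param group Group label of the subject (`AN`, `HC`).
#' @param leadfield A [forward_leadfield()] matrix (consistent with
#'   `source_space`).
#' @param source_space The [build_source_shell()] the leadfield was built
#'   from.
#' @param effect_spec A [make_effect_spec()] object.
#' @param noise_sd Sensor noise SD in sensor units (T or V).
#' @param sample_rate_hz Acquisition rate (>= 300 Hz; default 600).
#' @param gain Subject-level multiplicative gain on all source amplitudes.
#' @param line_noise_amp Amplitude of an optional line-noise sinusoid
#'   (same units as the data; 0 disables).
#' @param line_noise_hz Line-noise frequency (default 60).
#' @param seed Integer RNG seed (`NULL` continues the current stream).
#' @return A [new_recording()] object.
#' @export
simulate_sensor_recording <- function(trial_sequence, task, group,
                                      leadfield, source_space, effect_spec,
                                      noise_sd = 1e-12, sample_rate_hz = 600,
                                      gain = 1, line_noise_amp = 0,
                                      line_noise_hz = 60, seed = NULL) {
  stopifnot(sample_rate_hz >= 300)
  validate_effect_spec(effect_spec)
  n_orient <- attr(leadfield, "n_orient")
  if (ncol(leadfield) != source_space$n_sites * n_orient)
    stop("leadfield and source space dimensions disagree", call. = FALSE)
  withr_seed(seed)
  fs <- sample_rate_hz
  n_sens <- nrow(leadfield)
  stim_dur <- attr(trial_sequence, "stim_duration_s")
  if (is.null(stim_dur)) stim_dur <- 0.8
  n_samp <- ceiling((max(trial_sequence$onset_time) + stim_dur + 1) * fs)
  data <- if (noise_sd > 0)
    matrix(stats::rnorm(n_sens * n_samp, 0, noise_sd), n_sens, n_samp)
  else matrix(0, n_sens, n_samp)
  if (line_noise_amp > 0) {
    tvec <- (seq_len(n_samp) - 1) / fs
    phase <- stats::runif(n_sens, 0, 2 * pi)
    for (ch in seq_len(n_sens))
      data[ch, ] <- data[ch, ] +
        line_noise_amp * sin(2 * pi * line_noise_hz * tvec + phase[ch])
  }
  onset_samples <- round(trial_sequence$onset_time * fs)
  for (cmp in effect_spec$components) {
    # fixed tangential moment (first basis vector) at each target site
    pattern <- rowSums(leadfield[, (cmp$sites - 1L) * n_orient + 1L,
                                 drop = FALSE])
    w0 <- round(cmp$window_ms[1] / 1000 * fs)
    w1 <- round(cmp$window_ms[2] / 1000 * fs)
    nb <- w1 - w0
    if (nb < 2) next
    bump <- 0.5 * (1 - cos(2 * pi * seq(0, 1, length.out = nb)))
    amp <- cmp$amp_nam * 1e-9 * gain
    for (i in seq_len(nrow(trial_sequence))) {
      mlt <- cmp$mult[task, as.character(trial_sequence$category[i]), group]
      if (mlt == 0) next
      s0 <- onset_samples[i] + w0
      idx <- (s0 + 1):(s0 + nb)
      data[, idx] <- data[, idx] + (pattern * amp * mlt) %o% bump
    }
  }
  events <- data.frame(sample = onset_samples,
                       stimulus_id = trial_sequence$stimulus_id,
                       category = as.character(trial_sequence$category),
                       task = task, stringsAsFactors = FALSE)
  new_recording(data, fs, events,
                modality = attr(leadfield, "modality"))
}
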