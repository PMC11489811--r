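#' Default pipeline configuration
#'
#' Returns the full run configuration as a nested list. The `"full"`
#' preset pins every parameter at its established design value: 66 stimuli
#' in six BMI categories, 198 trials per task, 0.1/48 Hz band limits,
#' 600 -> 300 Hz sampling, 800 ms epochs with 150 ms baseline, 350 shell
#' sites at 87% of the head radius, lambda 0.1 (MEG) / 0.2 (EEG), a
#' 50-550 ms analysis window and alpha 0.05 at both the point and cluster
#' level. The `"desk"` preset keeps all of those analysis parameters but
#' shrinks the simulated cohort, sensor array, source grid and permutation
#' count so a full end-to-end run completes in minutes on one CPU.
#'
#' @param preset `"full"` (study scale) or `"desk"` (minutes on one CPU).
#' @param seed Master seed recorded in the config.
#' @return Nested configuration list.
#' @export
default_config <- function(preset = c("full", "desk"), seed = 1L) {
  preset <- match.arg(preset)
  cfg <- list(
    seed = as.integer(seed),
    preset = preset,
    cohort = list(n_an = 29, n_hc = 30, beta = 6, lapse_rate = 0),
    stimuli = list(n_per_category = 11,
                   category_ranges = default_category_ranges()),
    design = list(n_repeats = 3, max_run = 3, isi_center_s = 1.25,
                  isi_jitter_s = 0.5, stim_duration_s = 0.8,
                  tasks = c("viewing", "bar", "body")),
    behaviour = list(criterion = 0.5, bar_reference_bmi = 19.61),
    sensors = list(n_sensors = 64, head_radius = 0.09, modality = "MEG"),
    source = list(n_sites = 350, radius_fraction = 0.87,
                  lambda_meg = 0.1, lambda_eeg = 0.2, adjacency_k = 6),
    simulate = list(sample_rate_hz = 600, noise_sd = 1e-12,
                    line_noise_amp = 0, visual_amp_nam = 20,
                    interaction_amp_nam = 12, interaction_onset_ms = 200),
    preprocess = list(hp_hz = 0.1, lp_hz = 48, bandstop = TRUE,
                      bandstop_hz = 60, resample_hz = 300,
                      epoch_ms = c(-200, 600), baseline_ms = c(-150, 0),
                      z_threshold = 4),
    stats = list(window_ms = c(50, 550), n_perm = 1000, point_alpha = 0.05,
                 cluster_alpha = 0.05,
                 effects = c("task", "picture", "picture:group"))
  )
  if (preset == "desk") {
    cfg$cohort$n_an <- 6; cfg$cohort$n_hc <- 6
    cfg$sensors$n_sensors <- 24
    cfg$source$n_sites <- 60
    cfg$stats$n_perm <- 199
  }
  cfg
}

#' Validate a pipeline configuration
#'
#' Checks every structural invariant of the run configuration and returns
#' the violations as a character vector (empty if the config is valid);
#' nothing is thrown.
#'
#' @param config Configuration list (see [default_config()]).
#' @return Character vector of violation messages.
#' @export
validate_config <- function(config) {
  v <- character()
  chk <- function(cond, msg) if (!isTRUE(cond)) v <<- c(v, msg)
  chk(is.numeric(config$seed), "seed: must be numeric")
  chk(config$cohort$n_an >= 1 && config$cohort$n_hc >= 1,
      "cohort: group sizes must be >= 1")
  chk(config$cohort$lapse_rate >= 0 && config$cohort$lapse_rate < 0.5,
      "cohort: lapse_rate must be in [0, 0.5)")
  chk(config$stimuli$n_per_category >= 1,
      "stimuli: n_per_category must be >= 1")
  rng_ok <- tryCatch({validate_category_ranges(config$stimuli$category_ranges); TRUE},
                     error = function(e) FALSE)
  chk(rng_ok, "stimuli: category ranges must be ordered and non-overlapping")
  chk(config$design$max_run >= 1, "design: max_run must be >= 1")
  chk(config$design$isi_center_s - config$design$isi_jitter_s > 0,
      "design: minimum ISI must be positive")
  chk(config$behaviour$criterion > 0 && config$behaviour$criterion < 1,
      "behaviour: criterion must be in (0, 1)")
  chk(config$behaviour$bar_reference_bmi > 0,
      "behaviour: bar_reference_bmi must be positive")
  chk(config$source$n_sites >= 4, "source: n_sites must be >= 4")
  chk(config$source$radius_fraction > 0 && config$source$radius_fraction < 1,
      "source: radius_fraction must be in (0, 1)")
  chk(config$source$lambda_meg >= 0, "source: lambda_meg must be >= 0")
  chk(config$source$lambda_eeg >= 0, "source: lambda_eeg must be >= 0")
  chk(config$simulate$sample_rate_hz >= 300,
      "simulate: sample_rate_hz must be >= 300")
  chk(config$simulate$noise_sd >= 0, "simulate: noise_sd must be >= 0")
  pp <- config$preprocess
  chk(pp$hp_hz < pp$lp_hz, "preprocess: high-pass must be below low-pass")
  chk(pp$lp_hz < pp$resample_hz / 2,
      "preprocess: low-pass must be below the target Nyquist")
  chk(pp$resample_hz <= config$simulate$sample_rate_hz,
      "preprocess: resample rate must not exceed the acquisition rate")
  chk(pp$epoch_ms[1] <= pp$baseline_ms[1] && pp$baseline_ms[2] <= 0,
      "preprocess: baseline window must lie in the pre-stimulus epoch part")
  st <- config$stats
  chk(st$window_ms[1] >= pp$epoch_ms[1] && st$window_ms[2] <= pp$epoch_ms[2],
      "stats: analysis window must lie inside the epoch")
  chk(st$n_perm >= 100, "stats: n_perm must be >= 100")
  chk(st$point_alpha > 0 && st$point_alpha < 1, "stats: point_alpha in (0,1)")
  chk(st$cluster_alpha > 0 && st$cluster_alpha < 1,
      "stats: cluster_alpha in (0,1)")
  v
}

#' Read / write a configuration as YAML
#'
#' @param config Configuration list.
#' @param path File path.
#' @return `read_config` returns the configuration list.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  for (nm in c("epoch_ms", "baseline_ms")) # yaml returns lists for vectors
    cfg$preprocess[[nm]] <- as.numeric(unlist(cfg$preprocess[[nm]]))
  cfg$stats$window_ms <- as.numeric(unlist(cfg$stats$window_ms))
  cfg
}

#' Run the full analysis pipeline on synthetic data
#'
#' Executes simulate -> preprocess -> source-estimate -> cluster statistics
#' -> behavioural statistics and assembles a run report: cohort simulation,
#' behavioural responses and Weibull/BPI analysis, sensor simulation,
#' filtering/epoching/averaging, L2-MNE source activity, spatiotemporal
#' cluster-permutation ANOVA with post-hoc task comparisons and polynomial
#' picture trends. Identical configs and seeds give identical reports.
#'
#' @param config Configuration list (see [default_config()]).
#' @param out_dir Optional output directory; if given, the BPI table,
#'   cluster table and a JSON report are written there.
#' @param verbose Print stage progress.
#' @return List of class `bse_run_report`.
#' @export
run_pipeline <- function(config = default_config("desk"), out_dir = NULL,
                         verbose = FALSE) {
  viol <- validate_config(config)
  if (length(viol))
    stop("invalid config:\n  ", paste(viol, collapse = "\n  "), call. = FALSE)
  say <- function(...) if (verbose) message(sprintf(...))
  seed <- as.integer(config$seed)

  say("stage 1/5: design objects")
  stim <- make_stimulus_set(config$stimuli$n_per_category,
                            config$stimuli$category_ranges, seed = seed)
  cohort <- make_cohort(config$cohort$n_an, config$cohort$n_hc,
                        beta = config$cohort$beta,
                        lapse_rate = config$cohort$lapse_rate,
                        bar_reference_bmi = config$behaviour$bar_reference_bmi,
                        seed = seed + 1L)
  layout <- make_sensor_layout(config$sensors$n_sensors,
                               config$sensors$head_radius,
                               config$sensors$modality)
  src <- build_source_shell(config$sensors$head_radius,
                            config$source$n_sites,
                            config$source$radius_fraction)
  L <- forward_leadfield(src, layout)
  lambda <- if (layout$modality == "MEG") config$source$lambda_meg
            else config$source$lambda_eeg
  W <- mne_inverse_operator(L, lambda)
  adj <- site_adjacency(src, config$source$adjacency_k)
  espec <- make_effect_spec(
    src, tasks = config$design$tasks,
    categories = names(config$stimuli$category_ranges),
    visual_amp_nam = config$simulate$visual_amp_nam,
    interaction_amp_nam = config$simulate$interaction_amp_nam,
    interaction_onset_ms = config$simulate$interaction_onset_ms)

  say("stage 2/5: behavioural simulation and psychometrics")
  resp <- simulate_cohort_responses(cohort, stim,
                                    n_repeats = config$design$n_repeats,
                                    max_run = config$design$max_run,
                                    seed = seed + 2L)
  actual <- stats::setNames(cohort$actual_bmi, cohort$subject_id)
  bpi <- fit_bpi_table(resp, actual, criterion = config$behaviour$criterion,
                       bar_reference_bmi = config$behaviour$bar_reference_bmi)
  met <- simulate_metric_task(cohort, seed = seed + 3L)
  met_bpi <- do.call(rbind, lapply(split(met, met$subject_id), function(sl)
    data.frame(subject_id = sl$subject_id[1], group = sl$group[1],
               kind = "metric", fitted = NA_real_, reference = NA_real_,
               bpi = metric_bpi(sl$estimated_cm, sl$measured_cm),
               converged = NA, stringsAsFactors = FALSE)))
  bpi <- rbind(bpi, met_bpi)
  rownames(bpi) <- NULL
  behav <- behavioural_stats(bpi)

  say("stage 3/5: sensor simulation + preprocessing")
  tasks <- config$design$tasks
  cats <- names(config$stimuli$category_ranges)
  n_sub <- nrow(cohort)
  activity <- NULL
  time_sel <- NULL; time_ms <- NULL
  for (i in seq_len(n_sub)) {
    for (ti in seq_along(tasks)) {
      ts_seed <- (as.numeric(seed) * 977 + i * 31 + ti) %% 2^31
      tseq <- make_trial_sequence(stim, n_repeats = config$design$n_repeats,
                                  max_run = config$design$max_run,
                                  isi_center_s = config$design$isi_center_s,
                                  isi_jitter_s = config$design$isi_jitter_s,
                                  stim_duration_s = config$design$stim_duration_s,
                                  seed = ts_seed)
      rec <- simulate_sensor_recording(
        tseq, tasks[ti], as.character(cohort$group[i]), L, src, espec,
        noise_sd = config$simulate$noise_sd,
        sample_rate_hz = config$simulate$sample_rate_hz,
        gain = cohort$gain[i],
        line_noise_amp = config$simulate$line_noise_amp,
        seed = ts_seed + 1L)
      ev <- preprocess_recording(rec, config)
      if (is.null(activity)) {
        time_sel <- which(ev$time_ms >= config$stats$window_ms[1] &
                            ev$time_ms <= config$stats$window_ms[2])
        time_ms <- ev$time_ms[time_sel]
        activity <- array(0, c(n_sub, length(tasks), length(cats),
                               src$n_sites, length(time_sel)))
      }
      for (ci in seq_along(cats)) {
        row <- match(cats[ci], ev$cells$category)
        mom <- apply_inverse(W, ev$evoked[row, , ])
        mag <- activity_magnitude(mom, attr(L, "n_orient"))
        activity[i, ti, ci, , ] <- mag[, time_sel] * 1e9  # A m -> nAm
      }
    }
    say("  subject %d/%d done", i, n_sub)
  }

  say("stage 4/5: cluster-permutation statistics")
  canova <- cluster_anova(activity, cohort$group,
                          effects = config$stats$effects, adjacency = adj,
                          n_perm = config$stats$n_perm,
                          point_alpha = config$stats$point_alpha,
                          cluster_alpha = config$stats$cluster_alpha,
                          time_ms = time_ms, seed = seed + 7L)

  say("stage 5/5: post-hoc contrasts")
  posthoc <- list()
  for (eff in names(canova$tests)) {
    cls <- canova$tests[[eff]]$clusters
    if (!length(cls)) next
    best <- cls[[which.max(vapply(cls, `[[`, numeric(1), "mass"))]]
    cm <- extract_cluster_mean(activity, best)  # N x tasks x cats
    entry <- list(cluster_p = best$p, mass = best$mass)
    task_means <- apply(cm, c(1, 2), mean)
    colnames(task_means) <- tasks
    pic_means <- apply(cm, c(1, 3), mean)
    colnames(pic_means) <- cats
    if (eff == "task") {
      entry$task_means <- colMeans(task_means)
      entry$ttests <- posthoc_ttests(task_means)
    } else {
      entry$picture_means <- colMeans(pic_means)
      entry$trends <- polynomial_contrast(
        pic_means, group = if (grepl("group", eff)) cohort$group)
      if (grepl("group", eff))
        entry$picture_means_by_group <-
          apply(pic_means, 2, function(v) tapply(v, cohort$group, mean))
    }
    posthoc[[eff]] <- entry
  }

  report <- structure(list(
    config = config,
    n_subjects = n_sub,
    stimulus_set = stim,
    cohort = cohort,
    bpi_table = bpi,
    behavioural = behav,
    cluster_table = canova$table,
    cluster_anova = canova,
    posthoc = posthoc,
    time_ms = time_ms,
    activity_dim = dim(activity)
  ), class = "bse_run_report")

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_response_table(bpi, file.path(out_dir, "bpi.tsv"))
    utils::write.table(canova$table, file.path(out_dir, "clusters.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
      list(seed = seed, preset = config$preset,
           behavioural = unclass(behav)[c("metric", "depictive_anova")],
           clusters = canova$table, posthoc = posthoc),
      file.path(out_dir, "report.json"),
      auto_unbox = TRUE, digits = NA, force = TRUE)
  }
  report
}

#' @export
print.bse_run_report <- function(x, ...) {
  cat(sprintf("== run report: %d subjects, %s preset ==\n",
              x$n_subjects, x$config$preset))
  cat("-- behavioural --\n"); print(x$behavioural)
  cat("-- clusters --\n"); print(x$cluster_table)
  for (eff in names(x$posthoc)) {
    cat(sprintf("-- post hoc: %s --\n", eff))
    e <- x$posthoc[[eff]]
    if (!is.null(e$task_means)) {
      print(round(e$task_means, 3)); print(e$ttests)
    }
    if (!is.null(e$trends)) print(as.data.frame(e$trends))
  }
  invisible(x)
}
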