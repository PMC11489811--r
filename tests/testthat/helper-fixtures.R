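# Small reusable fixtures; everything is generated in code under fixed seeds.

tiny_source_setup <- function(n_sites = 30, n_sensors = 16,
                              modality = "MEG") {
  src <- build_source_shell(head_radius = 0.09, n_sites = n_sites)
  lay <- make_sensor_layout(n_sensors, modality = modality)
  list(src = src, lay = lay, L = forward_leadfield(src, lay))
}

# design-shaped noise array: subjects x tasks x pictures x sites x time
noise_activity <- function(n_sub = 10, a = 3, b = 6, S = 20, Tn = 15,
                           seed = 1) {
  set.seed(seed)
  array(rnorm(n_sub * a * b * S * Tn), c(n_sub, a, b, S, Tn))
}

# naive flood fill over a suprathreshold mask (independent clustering oracle)
naive_flood_fill <- function(mask, adjacency) {
  S <- nrow(mask); Tn <- ncol(mask)
  lab <- matrix(0L, S, Tn)
  cur <- 0L
  for (s0 in seq_len(S)) for (t0 in seq_len(Tn)) {
    if (!mask[s0, t0] || lab[s0, t0] != 0L) next
    cur <- cur + 1L
    queue <- list(c(s0, t0)); lab[s0, t0] <- cur
    while (length(queue)) {
      pt <- queue[[1]]; queue <- queue[-1]
      s <- pt[1]; tt <- pt[2]
      cand <- rbind(
        if (tt > 1) c(s, tt - 1), if (tt < Tn) c(s, tt + 1),
        do.call(rbind, lapply(adjacency[[s]], function(s2) c(s2, tt))))
      for (k in seq_len(nrow(cand))) {
        cs <- cand[k, 1]; ct <- cand[k, 2]
        if (mask[cs, ct] && lab[cs, ct] == 0L) {
          lab[cs, ct] <- cur
          queue[[length(queue) + 1]] <- c(cs, ct)
        }
      }
    }
  }
  lab
}

# a fast tiny pipeline config for end-to-end tests
tiny_config <- function(seed = 1, n_per_group = 2, n_sensors = 12,
                        n_sites = 20, n_perm = 100, n_per_category = 2,
                        n_repeats = 1) {
  cfg <- default_config("desk", seed = seed)
  cfg$cohort$n_an <- n_per_group
  cfg$cohort$n_hc <- n_per_group
  cfg$sensors$n_sensors <- n_sensors
  cfg$source$n_sites <- n_sites
  cfg$stats$n_perm <- n_perm
  cfg$stimuli$n_per_category <- n_per_category
  cfg$design$n_repeats <- n_repeats
  cfg
}
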