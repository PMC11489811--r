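#' Simulate a study cohort of Weibull observers
#'
#' Each synthetic subject carries an actual BMI, a common psychometric slope
#' `beta`, a lapse rate, and latent Weibull scale parameters for the two
#' depictive tasks. The latent point of subjective equality (PSE) in the
#' self-referential body task is `bpi_body/100 * actual_bmi`, and in the
#' non-self-referential bar task `bpi_bar/100 * bar_reference_bmi`: the
#' reference frame only shifts the scale parameter `a`, not the slope.
#' Group-level BPI distributions default to values emulating the reported
#' behavioural pattern (patients overestimate strongly in self-referential
#' tasks, both groups are accurate in the bar task).
#'
#' @param n_an,n_hc Group sizes (defaults 29 and 30, the MEG-analysis Ns).
#' @param beta Psychometric slope (dimensionless), recycled over subjects.
#' @param lapse_rate Probability of a stimulus-independent random response,
#'   in `[0, 0.5)`; default 0.
#' @param bmi_an,bmi_hc `c(mean, sd)` of actual BMI per group (kg/m^2).
#' @param bpi_body_an,bpi_body_hc `c(mean, sd)` of true body-task BPI (%).
#' @param bpi_bar_an,bpi_bar_hc `c(mean, sd)` of true bar-task BPI (%).
#' @param bpi_metric_an,bpi_metric_hc `c(mean, sd)` of true metric BPI (%).
#' @param bar_reference_bmi BMI of the picture matching the comparison bar
#'   width (default 19.61).
#' @param seed Integer RNG seed.
#' @return Data frame of class `bse_cohort` with one row per subject:
#'   `subject_id`, `group` (factor AN/HC), `actual_bmi`, `true_beta`,
#'   `lapse_rate`, latent task PSEs and scales (`pse_body`, `pse_bar`,
#'   `a_body`, `a_bar`), true BPIs, and a multiplicative neural `gain`
#'   used by the sensor simulator.
#' @export
make_cohort <- function(n_an = 29, n_hc = 30, beta = 6, lapse_rate = 0,
                        bmi_an = c(15.6, 1.34), bmi_hc = c(20.3, 1.98),
                        bpi_body_an = c(125, 15), bpi_body_hc = c(108, 12),
                        bpi_bar_an = c(100, 6), bpi_bar_hc = c(100, 6),
                        bpi_metric_an = c(135, 20), bpi_metric_hc = c(103, 13),
                        bar_reference_bmi = 19.61, seed = 1L) {
  stopifnot(n_an >= 1, n_hc >= 1, all(beta > 0),
            all(lapse_rate >= 0), all(lapse_rate < 0.5))
  withr_seed(seed)
  n <- n_an + n_hc
  group <- factor(rep(c("AN", "HC"), c(n_an, n_hc)), levels = c("AN", "HC"))
  rnorm2 <- function(n, p) stats::rnorm(n, p[1], p[2])
  actual_bmi <- ifelse(group == "AN", rnorm2(n, bmi_an), rnorm2(n, bmi_hc))
  actual_bmi <- pmax(actual_bmi, 11)
  bpi_body <- ifelse(group == "AN", rnorm2(n, bpi_body_an), rnorm2(n, bpi_body_hc))
  bpi_bar <- ifelse(group == "AN", rnorm2(n, bpi_bar_an), rnorm2(n, bpi_bar_hc))
  bpi_metric <- ifelse(group == "AN", rnorm2(n, bpi_metric_an), rnorm2(n, bpi_metric_hc))
  beta <- rep_len(beta, n)
  lapse_rate <- rep_len(lapse_rate, n)
  pse_body <- bpi_body / 100 * actual_bmi
  pse_bar <- bpi_bar / 100 * bar_reference_bmi
  # PSE p = 0.5 => a = (ln 2)^(1/beta) / PSE
  a_of_pse <- function(pse, b) log(2)^(1 / b) / pse
  out <- data.frame(
    subject_id = sprintf("S%03d", seq_len(n)),
    group = group,
    actual_bmi = actual_bmi,
    true_beta = beta,
    lapse_rate = lapse_rate,
    pse_body = pse_body,
    pse_bar = pse_bar,
    a_body = a_of_pse(pse_body, beta),
    a_bar = a_of_pse(pse_bar, beta),
    bpi_body_true = bpi_body,
    bpi_bar_true = bpi_bar,
    bpi_metric_true = bpi_metric,
    gain = exp(stats::rnorm(n, 0, 0.15)),
    stringsAsFactors = FALSE
  )
  attr(out, "bar_reference_bmi") <- bar_reference_bmi
  class(out) <- c("bse_cohort", class(out))
  out
}

#' @export
print.bse_cohort <- function(x, ...) {
  cat(sprintf("<cohort: %d subjects (AN %d, HC %d)>\n", nrow(x),
              sum(x$group == "AN"), sum(x$group == "HC")))
  invisible(x)
}

#' Build a spherical-cap sensor layout
#'
#' Places sensors quasi-uniformly (Fibonacci lattice) on a spherical cap of
#' the head sphere, emulating an MEG helmet / EEG cap at desk scale. MEG
#' sensors are modelled as magnetometers oriented along the outward radial
#' direction; EEG sensors are scalp electrodes (no orientation).
#'
#' @param n_sensors Number of sensors (default 64).
#' @param head_radius Head sphere radius in metres (default 0.09).
#' @param modality `"MEG"` or `"EEG"`.
#' @param cap_z_min Lower edge of the cap as a fraction of the radius in z
#'   (default -0.25: coverage extends a little below the equator).
#' @return List of class `bse_sensor_layout`: `positions` (n x 3, metres),
#'   `orientations` (n x 3 unit vectors, MEG only), `modality`,
#'   `head_radius`, `sensor_id`.
#' @export
make_sensor_layout <- function(n_sensors = 64, head_radius = 0.09,
                               modality = c("MEG", "EEG"), cap_z_min = -0.25) {
  modality <- match.arg(modality)
  stopifnot(n_sensors >= 4, head_radius > 0, cap_z_min > -1, cap_z_min < 1)
  pos <- fibonacci_cap(n_sensors, cap_z_min) * head_radius
  out <- list(
    sensor_id = sprintf("%s%03d", if (modality == "MEG") "M" else "E",
                        seq_len(n_sensors)),
    positions = pos,
    orientations = if (modality == "MEG") pos / head_radius else NULL,
    modality = modality,
    head_radius = head_radius
  )
  class(out) <- "bse_sensor_layout"
  out
}

#' @export
print.bse_sensor_layout <- function(x, ...) {
  cat(sprintf("<%s layout: %d sensors on r = %.3f m sphere>\n",
              x$modality, nrow(x$positions), x$head_radius))
  invisible(x)
}

# Deterministic Fibonacci lattice on the unit-sphere cap z in [z_min, 1].
fibonacci_cap <- function(n, z_min = -1) {
  golden <- (1 + sqrt(5)) / 2
  i <- seq_len(n) - 0.5
  z <- 1 - (1 - z_min) * i / n
  phi <- 2 * pi * i / golden
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(x = r * cos(phi), y = r * sin(phi), z = z)
}
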