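#' Magnetic field of a current dipole in a spherical conductor
#'
#' Analytic solution for the field outside a spherically symmetric volume
#' conductor (primary dipole plus volume currents). Radial dipoles produce
#' exactly zero field, and the radial field component equals that of the
#' primary dipole alone.
#'
#' @param r_sensor Sensor position (length-3, metres), outside the conductor
#'   region containing the dipole.
#' @param r_dipole Dipole position (length-3, metres, not at the origin's
#'   sensor radius).
#' @param q Dipole moment vector (A m).
#' @return Magnetic field vector in tesla.
#' @export
dipole_field_sphere <- function(r_sensor, r_dipole, q) {
  mu0_4pi <- 1e-7
  r <- as.numeric(r_sensor); r0 <- as.numeric(r_dipole); q <- as.numeric(q)
  a <- r - r0
  A <- sqrt(sum(a^2)); R <- sqrt(sum(r^2))
  if (A < 1e-12) stop("sensor coincides with dipole", call. = FALSE)
  ar <- sum(a * r)
  F <- A * (R * A + R^2 - sum(r0 * r))
  gradF <- (A^2 / R + ar / A + 2 * A + 2 * R) * r -
    (A + 2 * R + ar / A) * r0
  qxr0 <- c(q[2] * r0[3] - q[3] * r0[2],
            q[3] * r0[1] - q[1] * r0[3],
            q[1] * r0[2] - q[2] * r0[1])
  mu0_4pi / F^2 * (F * qxr0 - sum(qxr0 * r) * gradF)
}

#' Surface potential of a current dipole in a homogeneous conducting sphere
#'
#' Legendre-series solution for the electric potential on (or outside) a
#' homogeneous sphere of conductivity `sigma`, evaluated at electrode
#' positions. Terms decay like `(|r_dipole|/R)^n`; the series is truncated
#' at `n_terms`.
#'
#' @param r_electrodes m x 3 matrix of electrode positions on the sphere
#'   surface (metres).
#' @param r_dipole Dipole position inside the sphere (metres).
#' @param q Dipole moment vector (A m).
#' @param sigma Conductivity in S/m (default 0.33).
#' @param sphere_radius Sphere radius; defaults to the electrode radius.
#' @param n_terms Series truncation order.
#' @return Numeric vector of potentials in volts (one per electrode).
#' @export
dipole_potential_sphere <- function(r_electrodes, r_dipole, q, sigma = 0.33,
                                    sphere_radius = NULL, n_terms = 120L) {
  re <- as.matrix(r_electrodes)
  r0 <- as.numeric(r_dipole); q <- as.numeric(q)
  R <- if (is.null(sphere_radius)) sqrt(sum(re[1, ]^2)) else sphere_radius
  b <- sqrt(sum(r0^2))
  if (b >= R) stop("dipole must lie inside the sphere", call. = FALSE)
  if (b < 1e-9) { r0 <- c(0, 0, 1e-9); b <- 1e-9 }  # central dipole limit
  rhat0 <- r0 / b
  Re_norm <- sqrt(rowSums(re^2))
  ehat <- re / Re_norm
  cosg <- pmin(1, pmax(-1, as.numeric(ehat %*% rhat0)))
  sing <- sqrt(pmax(0, 1 - cosg^2))
  # tangential unit vector at each electrode: component of ehat orthogonal
  # to the dipole direction, normalised (zero where electrode is aligned)
  tvec <- ehat - outer(cosg, rhat0)
  tn <- sqrt(rowSums(tvec^2))
  safe <- tn > 1e-12
  tvec[safe, ] <- tvec[safe, ] / tn[safe]
  tvec[!safe, ] <- 0
  q_r <- sum(q * rhat0)
  q_t <- as.numeric(tvec %*% q)

  m <- nrow(re)
  V <- numeric(m)
  Pnm1 <- rep(1, m)      # P_0
  Pn <- cosg             # P_1
  ratio <- b / R
  pow <- rep(1 / R^2, m) # b^(n-1)/R^(n+1) at n = 1
  for (n in 1:n_terms) {
    if (n > 1) {
      Pnew <- ((2 * n - 1) * cosg * Pn - (n - 1) * Pnm1) / n
      Pnm1 <- Pn; Pn <- Pnew
      pow <- pow * ratio  # b^(n-1)/R^(n+1) -> next n
    }
    # associated Legendre P_n^1 (no Condon-Shortley phase):
    # P_n^1 = n (P_{n-1} - x P_n) / sin(gamma)
    Pn1 <- ifelse(sing > 1e-12, n * (Pnm1 - cosg * Pn) / pmax(sing, 1e-12), 0)
    V <- V + (2 * n + 1) / n * pow * (n * q_r * Pn + q_t * Pn1)
  }
  V / (4 * pi * sigma)
}

#' Forward leadfield for a spherical head conductor
#'
#' Maps unit dipole moments at every source site and allowed orientation to
#' the sensor array. MEG uses the analytic spherical-conductor dipole field
#' projected onto the sensor orientations, with 2 tangential orientations
#' per site (radial dipoles are silent); EEG uses the homogeneous-sphere
#' potential with 3 orientations per site and an average reference (columns
#' sum to zero across electrodes).
#'
#' @param source_space A [build_source_shell()] object.
#' @param sensor_layout A [make_sensor_layout()] object of matching
#'   modality.
#' @param modality `"MEG"` or `"EEG"`; defaults to the layout's modality.
#' @param sigma EEG conductivity (S/m).
#' @return Matrix of class `bse_leadfield`, sensors x (sites * n_orient),
#'   units T/(A m) for MEG and V/(A m) for EEG. Attributes: `n_orient`,
#'   `modality`, `n_sites`.
#' @export
forward_leadfield <- function(source_space, sensor_layout,
                              modality = sensor_layout$modality,
                              sigma = 0.33) {
  stopifnot(inherits(source_space, "bse_source_space"))
  pos_s <- sensor_layout$positions
  if (any(sqrt(rowSums(pos_s^2)) <= source_space$radius + 1e-12))
    stop("sensors must lie outside the source shell", call. = FALSE)
  n_sites <- source_space$n_sites
  n_sens <- nrow(pos_s)
  if (modality == "MEG") {
    n_orient <- 2L
    orients <- list(source_space$tangential1, source_space$tangential2)
    L <- matrix(0, n_sens, n_sites * n_orient)
    for (i in seq_len(n_sites)) {
      for (o in seq_len(n_orient)) {
        q <- orients[[o]][i, ]
        col <- (i - 1L) * n_orient + o
        for (s in seq_len(n_sens)) {
          B <- dipole_field_sphere(pos_s[s, ], source_space$positions[i, ], q)
          L[s, col] <- sum(B * sensor_layout$orientations[s, ])
        }
      }
    }
  } else {
    n_orient <- 3L
    orients <- list(source_space$tangential1, source_space$tangential2,
                    source_space$radial)
    L <- matrix(0, n_sens, n_sites * n_orient)
    for (i in seq_len(n_sites)) {
      for (o in seq_len(n_orient)) {
        col <- (i - 1L) * n_orient + o
        L[, col] <- dipole_potential_sphere(
          pos_s, source_space$positions[i, ], orients[[o]][i, ],
          sigma = sigma, sphere_radius = sensor_layout$head_radius)
      }
    }
    L <- sweep(L, 2, colMeans(L))  # average reference
  }
  structure(L, n_orient = n_orient, modality = modality, n_sites = n_sites,
            class = c("bse_leadfield", "matrix", "array"))
}
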