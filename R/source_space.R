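#' Build a spherical source shell of evenly distributed dipole sites
#'
#' Places `n_sites` dipole locations quasi-uniformly on a sphere of radius
#' `radius_fraction * head_radius` (default 87% of the head radius, roughly
#' grey-matter depth) using a deterministic Fibonacci lattice, and attaches
#' an orthonormal tangential basis at every site. MEG source models use the
#' two tangential orientations per site ("dipole pairs"; the radial
#' orientation is magnetically silent in a spherical conductor), EEG models
#' use all three ("dipole triples").
#'
#' @param head_radius Head sphere radius in metres (default 0.09).
#' @param n_sites Number of dipole sites (default 350).
#' @param radius_fraction Shell radius as a fraction of the head radius.
#' @return List of class `bse_source_space`: `positions` (n x 3, m),
#'   `tangential1`, `tangential2`, `radial` (n x 3 unit vectors), `radius`,
#'   `head_radius`, `n_sites`.
#' @export
build_source_shell <- function(head_radius = 0.09, n_sites = 350,
                               radius_fraction = 0.87) {
  stopifnot(n_sites >= 4, radius_fraction > 0, radius_fraction < 1,
            head_radius > 0)
  u <- fibonacci_cap(n_sites, z_min = -1)  # full sphere
  r <- head_radius * radius_fraction
  zhat <- c(0, 0, 1)
  t1 <- t(apply(u, 1, function(v) {
    w <- c(zhat[2] * v[3] - zhat[3] * v[2],
           zhat[3] * v[1] - zhat[1] * v[3],
           zhat[1] * v[2] - zhat[2] * v[1])
    if (sqrt(sum(w^2)) < 1e-6) w <- c(1, 0, 0)  # polar site
    w / sqrt(sum(w^2))
  }))
  t2 <- t(sapply(seq_len(n_sites), function(i) {
    v <- u[i, ]; w <- t1[i, ]
    c(v[2] * w[3] - v[3] * w[2],
      v[3] * w[1] - v[1] * w[3],
      v[1] * w[2] - v[2] * w[1])
  }))
  out <- list(positions = u * r, tangential1 = t1, tangential2 = t2,
              radial = u, radius = r, head_radius = head_radius,
              n_sites = n_sites)
  class(out) <- "bse_source_space"
  out
}

#' @export
print.bse_source_space <- function(x, ...) {
  cat(sprintf("<source shell: %d sites at r = %.4f m (%.0f%% of head radius)>\n",
              x$n_sites, x$radius, 100 * x$radius / x$head_radius))
  invisible(x)
}

#' Spatial adjacency of shell sites
#'
#' Symmetrised k-nearest-neighbour graph over the dipole sites (great-circle
#' metric is equivalent to Euclidean here since all sites share one radius).
#' Deterministic; used as the spatial neighbourhood relation for
#' spatiotemporal clustering.
#'
#' @param source_space A [build_source_shell()] object, or an n x 3 position
#'   matrix.
#' @param k Number of nearest neighbours (default 6).
#' @return List of integer vectors; element `i` holds the neighbours of site
#'   `i`. The relation is symmetric.
#' @export
site_adjacency <- function(source_space, k = 6) {
  pos <- if (inherits(source_space, "bse_source_space")) source_space$positions
         else as.matrix(source_space)
  n <- nrow(pos)
  stopifnot(k >= 1, k < n)
  d2 <- as.matrix(stats::dist(pos))^2
  adj <- vector("list", n)
  for (i in seq_len(n)) {
    nb <- order(d2[i, ])[2:(k + 1)]
    adj[[i]] <- sort(unique(c(adj[[i]], nb)))
    for (j in nb) adj[[j]] <- sort(unique(c(adj[[j]], i)))
  }
  adj
}
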