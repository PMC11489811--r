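#' L2 minimum-norm inverse operator with Tikhonov regularisation
#'
#' Computes `W = L' (L L' + lambda * s * I)^-1` where
#' `s = trace(L L') / n_sensors` scales the regulariser so that `lambda` is
#' dimensionless (the conventional source-imaging values are 0.1 for MEG and
#' 0.2 for EEG). At `lambda = 0` with a full-row-rank leadfield, `W` is the
#' Moore-Penrose pseudoinverse and `W %*% b` is the minimum-L2-norm solution
#' of `L x = b`.
#'
#' @param leadfield Sensors x sources leadfield matrix.
#' @param lambda Non-negative regularisation parameter.
#' @return Matrix of class `bse_inverse_operator` (sources x sensors) with
#'   attributes `lambda`, `gram_scale`, `n_orient`.
#' @export
mne_inverse_operator <- function(leadfield, lambda = 0.1) {
  stopifnot(lambda >= 0)
  L <- unclass(leadfield)
  if (all(L == 0)) stop("leadfield is identically zero", call. = FALSE)
  G <- L %*% t(L)
  s <- sum(diag(G)) / nrow(L)
  A <- G + lambda * s * diag(nrow(G))
  W <- tryCatch(t(L) %*% solve(A),
                error = function(e)
                  stop("sensor Gram matrix is singular; use lambda > 0 ",
                       "for a rank-deficient leadfield", call. = FALSE))
  structure(W, lambda = lambda, gram_scale = s,
            n_orient = attr(leadfield, "n_orient"),
            class = c("bse_inverse_operator", "matrix", "array"))
}

#' Apply an inverse operator to sensor data
#'
#' @param inverse_operator A [mne_inverse_operator()] matrix.
#' @param data Sensors x time matrix (or a vector for one time point).
#' @return Dipole moments, (sites * orientations) x time.
#' @export
apply_inverse <- function(inverse_operator, data) {
  if (is.null(dim(data))) data <- matrix(data, ncol = 1)
  if (anyNA(data)) stop("apply_inverse: NA in sensor data", call. = FALSE)
  if (nrow(data) != ncol(inverse_operator))
    stop("apply_inverse: sensor dimension mismatch", call. = FALSE)
  unclass(inverse_operator) %*% data
}

#' Direction-independent source activity
#'
#' Collapses the per-site orientation components of estimated dipole
#' moments into their Euclidean vector length per site and time point.
#'
#' @param moments (sites * n_orient) x time matrix of dipole moments (A m),
#'   orientations blocked per site.
#' @param n_orient Orientations per site (2 for MEG pairs, 3 for EEG
#'   triples). Defaults to the `n_orient` attribute if present.
#' @return Sites x time matrix of non-negative magnitudes.
#' @export
activity_magnitude <- function(moments, n_orient = NULL) {
  if (is.null(n_orient)) n_orient <- attr(moments, "n_orient")
  stopifnot(!is.null(n_orient), nrow(moments) %% n_orient == 0)
  n_sites <- nrow(moments) / n_orient
  sq <- moments^2
  out <- matrix(0, n_sites, ncol(moments))
  for (o in seq_len(n_orient))
    out <- out + sq[seq(o, by = n_orient, length.out = n_sites), , drop = FALSE]
  sqrt(out)
}
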