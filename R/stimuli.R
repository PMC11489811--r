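#' Default BMI ranges of the six body-picture categories
#'
#' The stimulus database classifies computer-generated female body pictures
#' into six BMI categories, A (severely underweight) through F (severely
#' overweight). Ranges are in kg/m^2, non-overlapping and ordered.
#'
#' @return Named list of length-2 numeric vectors `c(lo, hi)` for categories
#'   `A`..`F`.
#' @export
default_category_ranges <- function() {
  list(
    A = c(12.19, 14.74),
    B = c(14.77, 17.17),
    C = c(17.19, 19.78),
    D = c(19.80, 29.91),
    E = c(29.92, 32.45),
    F = c(32.46, 56.26)
  )
}

#' Generate a body-picture stimulus set
#'
#' Draws stimulus BMIs uniformly within each category's range. The default
#' design has 11 stimuli in each of the six categories, i.e. 66 body pictures.
#'
#' @param n_per_category Number of stimuli per category (>= 1).
#' @param category_ranges Named list of `c(lo, hi)` BMI ranges, ordered and
#'   non-overlapping; see [default_category_ranges()].
#' @param seed Integer RNG seed; identical seeds give identical sets.
#' @return A data frame of class `bse_stimulus_set` with columns
#'   `stimulus_id`, `bmi` (kg/m^2) and `category` (factor A..F).
#' @export
make_stimulus_set <- function(n_per_category = 11,
                              category_ranges = default_category_ranges(),
                              seed = 1L) {
  stopifnot(n_per_category >= 1, length(category_ranges) >= 1)
  validate_category_ranges(category_ranges)
  cats <- names(category_ranges)
  withr_seed(seed)
  bmi <- unlist(lapply(category_ranges, function(rg) {
    stats::runif(n_per_category, rg[1], rg[2])
  }), use.names = FALSE)
  out <- data.frame(
    stimulus_id = sprintf("%s%02d", rep(cats, each = n_per_category),
                          rep(seq_len(n_per_category), length(cats))),
    bmi = bmi,
    category = factor(rep(cats, each = n_per_category), levels = cats),
    stringsAsFactors = FALSE
  )
  class(out) <- c("bse_stimulus_set", class(out))
  out
}

validate_category_ranges <- function(category_ranges) {
  if (is.null(names(category_ranges)) || anyDuplicated(names(category_ranges)))
    stop("category_ranges must be a uniquely named list", call. = FALSE)
  m <- do.call(rbind, category_ranges)
  if (any(m[, 2] <= m[, 1]))
    stop("each category range must have lo < hi", call. = FALSE)
  if (nrow(m) > 1 && any(m[-1, 1] <= m[-nrow(m), 2]))
    stop("category ranges must be non-overlapping and ordered", call. = FALSE)
  invisible(TRUE)
}

# set.seed without clobbering the caller's RNG state is deliberately NOT used:
# generator functions own the stream so that a given seed is reproducible
# irrespective of what ran before.
withr_seed <- function(seed) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  invisible(NULL)
}

#' @export
print.bse_stimulus_set <- function(x, ...) {
  cat(sprintf("<stimulus set: %d pictures, %d categories, BMI %.2f-%.2f>\n",
              nrow(x), nlevels(x$category), min(x$bmi), max(x$bmi)))
  invisible(x)
}
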