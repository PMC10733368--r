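#' Bank of direction-tuned units
#'
#' Builds the discretized population of units whose preferred directions
#' phi_j tile the circle of possible error directions. The grid is the
#' symmetric inclusive lattice phi_j = -180 + (j - 1) * 360 / (M - 1),
#' j = 1..M, so it contains 0 and +/-180 exactly and is odd-symmetric
#' (phi in grid implies -phi in grid). Exact symmetry is what makes the
#' integrated response identically zero for a zero error.
#'
#' @param M Odd integer >= 3; number of units.
#' @param s Tuning width in degrees, > 0.
#' @return An object of class `neural_population`: a list with `phi`
#'   (preferred directions, degrees), `s`, and `spacing` (degrees).
#' @examples
#' pop <- make_population(3601, 22)
#' pop$spacing  # 0.1 degree
#' @export
make_population <- function(M, s) {
  stopifnot(is.numeric(M), length(M) == 1L, is.finite(M),
            is.numeric(s), length(s) == 1L, is.finite(s))
  M <- as.integer(M)
  if (M < 3L || M %% 2L == 0L)
    stop("'M' must be an odd integer >= 3", call. = FALSE)
  if (s <= 0) stop("'s' must be positive", call. = FALSE)
  spacing <- 360 / (M - 1)
  # built as a mirrored half-grid so that -phi[j] is bitwise equal to
  # phi[M + 1 - j]: the response can then be made exactly odd
  half <- (seq_len((M - 1L) %/% 2L) / ((M - 1L) %/% 2L)) * 180
  phi <- c(-rev(half), 0, half)
  structure(list(phi = phi, s = s, spacing = spacing),
            class = "neural_population")
}

#' @export
print.neural_population <- function(x, ...) {
  cat(sprintf("Neural population: %d units, spacing %g deg, tuning width %g deg\n",
              length(x$phi), x$spacing, x$s))
  invisible(x)
}

#' Tuning gains of the population for a set of cursor errors
#'
#' Each unit's gain is a Gaussian of the distance between its preferred
#' direction and the nearest cursor: f_j = max_i exp(-(e_i - phi_j)^2 / (2 s^2)).
#' The max operation means a unit responds only to the cursor closest to the
#' peak of its tuning curve, so duplicated cursors are inert. Evaluated as a
#' plain (non-wrapped) Gaussian in degrees; this is the stated small-angle
#' approximation of circular tuning.
#'
#' @param errors An [error_set()] or numeric vector of errors (degrees).
#' @param pop A [make_population()] object.
#' @return Numeric vector of length M with gains in (0, 1]; f_j = 1 exactly
#'   when some cursor sits on phi_j.
#' @export
tuning <- function(errors, pop) {
  e <- as_error_set(errors)
  stopifnot(inherits(pop, "neural_population"))
  d <- outer(pop$phi, as.numeric(e), "-")
  g <- exp(-d * d / (2 * pop$s^2))
  f <- g[, 1L]
  for (j in seq_len(ncol(g))[-1L]) f <- pmax(f, g[, j])
  f
}
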