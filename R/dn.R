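#' Divisively normalized learning response to a set of cursor errors
#'
#' Evaluates the population model: every unit transforms its tuning gain into
#' a compensatory command x_j = w * phi_j * f_j(e), and the commands are
#' integrated under divisive normalization,
#' X(e) = sum_j x_j / (k M + sum_j x_j^2).
#' The sign convention is positive response for a positive error. With
#' `normalization = FALSE` the pooled-activity term is dropped from the
#' denominator (kept as k M only), which for a single cursor reduces to the
#' linear model of [linear_response_single()].
#'
#' @param errors An [error_set()] or numeric vector of cursor errors (degrees).
#' @param params A [dn_params()] object.
#' @param normalization Logical; drop the divisive term when `FALSE`.
#' @return Scalar learning response in arbitrary force-impulse units.
#' @examples
#' p <- dn_params(w = 5.3271e-4, k = 7.7806e-7)
#' dn_response(30, p)
#' dn_response(c(30, 30), p)  # duplicated cursors are inert
#' @export
dn_response <- function(errors, params, normalization = TRUE) {
  stopifnot(inherits(params, "dn_params"))
  e <- as_error_set(errors)
  pop <- make_population(params$M, params$s)
  f <- tuning(e, pop)
  x <- params$w * pop$phi * f
  # mirror-paired summation: the grid is bitwise sign-symmetric, so pairing
  # unit j with M + 1 - j makes X(0) = 0 and X(-e) = -X(e) hold exactly
  M <- params$M
  i <- seq_len((M - 1L) %/% 2L)
  j <- M + 1L - i
  num <- sum(x[j] + x[i])
  denom <- params$k * M
  if (normalization) denom <- denom + sum(x[j] * x[j] + x[i] * x[i])
  num / denom
}

# Vectorized DN response for a matrix of error draws (rows = draws, columns =
# cursors). Chunked so the M-wide intermediate stays modest in memory.
dn_response_rows <- function(E, params, chunk = 2000L) {
  pop <- make_population(params$M, params$s)
  wphi <- params$w * pop$phi
  wphi2 <- wphi * wphi
  inv2s2 <- 1 / (2 * params$s^2)
  kM <- params$k * params$M
  n <- nrow(E)
  out <- numeric(n)
  for (lo in seq(1L, n, by = chunk)) {
    hi <- min(lo + chunk - 1L, n)
    Ec <- E[lo:hi, , drop = FALSE]
    f <- NULL
    for (i in seq_len(ncol(Ec))) {
      d <- outer(Ec[, i], pop$phi, "-")
      g <- exp(-d * d * inv2s2)
      f <- if (is.null(f)) g else pmax(f, g)
    }
    num <- f %*% wphi
    den <- kM + (f * f) %*% wphi2
    out[lo:hi] <- num / den
  }
  out
}

#' Linear (no-normalization) single-cursor response
#'
#' Closed form of the integrated response to a single cursor when the divisive
#' term is absent: X(e) = sqrt(2 pi) w s e / (360 k). Linear in the error, as
#' assumed by classic trial-by-trial adaptation models.
#'
#' @param e Error(s) in degrees (vectorized).
#' @param params A [dn_params()] object.
#' @return Response(s) in arbitrary units.
#' @export
linear_response_single <- function(e, params) {
  stopifnot(inherits(params, "dn_params"))
  sqrt(2 * pi) * params$w * params$s * e / (360 * params$k)
}

#' Closed-form single-cursor response of the DN model
#'
#' Analytical solution of the normalized population response to one cursor,
#' obtained by replacing the sums over units with Gaussian integrals:
#' X(e) = 2 sqrt(2 pi) w s e / (720 k + sqrt(pi) w^2 s (s^2 + 2 e^2)).
#' Odd in e, with a single interior maximum at
#' e* = sqrt((720 k + sqrt(pi) w^2 s^3) / (2 sqrt(pi) w^2 s))
#' beyond which the response declines: the saturation signature of divisive
#' normalization.
#'
#' @param e Error(s) in degrees (vectorized).
#' @param params A [dn_params()] object.
#' @return Response(s) in arbitrary units.
#' @seealso [analytic_peak()] for e*.
#' @export
analytic_single <- function(e, params) {
  stopifnot(inherits(params, "dn_params"))
  w <- params$w; k <- params$k; s <- params$s
  2 * sqrt(2 * pi) * w * s * e / (720 * k + sqrt(pi) * w^2 * s * (s^2 + 2 * e^2))
}

#' @describeIn analytic_single Location e* (degrees) of the single-cursor
#'   response peak.
#' @export
analytic_peak <- function(params) {
  stopifnot(inherits(params, "dn_params"))
  w <- params$w; k <- params$k; s <- params$s
  sqrt((720 * k + sqrt(pi) * w^2 * s^3) / (2 * sqrt(pi) * w^2 * s))
}

#' Strength of the response nonlinearity
#'
#' The ratio w^2 / k controls how strongly the divisive term bends the
#' response away from linearity (for fixed M): larger values mean stronger
#' saturation. Learning responses show values several orders of magnitude
#' larger than within-trial feedback responses.
#'
#' @param params A [dn_params()] object, or a positive gain `w` when `k` is
#'   supplied.
#' @param k Normalization constant, required when `params` is a bare gain.
#' @return Scalar w^2 / k.
#' @examples
#' nonlinearity_index(dn_params(w = 5.3271e-4, k = 7.7806e-7))
#' @export
nonlinearity_index <- function(params, k = NULL) {
  if (inherits(params, "dn_params")) {
    w <- params$w; k <- params$k
  } else {
    w <- params
    if (is.null(k)) stop("supply 'k' when 'params' is a bare gain", call. = FALSE)
  }
  stopifnot(is.numeric(w), is.numeric(k), length(w) == 1L, length(k) == 1L)
  if (k <= 0) stop("'k' must be positive", call. = FALSE)
  if (w < 0) stop("'w' must be non-negative", call. = FALSE)
  w^2 / k
}

#' Monte-Carlo expected DN response to a cursor cloud
#'
#' Draws `n_draws` independent clouds of `n_cursors` errors from
#' N(mu, sigma^2), evaluates the DN response on each draw, and returns the
#' sample mean with its standard error. With sigma = 0 every draw collapses to
#' `n_cursors` identical cursors, which by the max operation equals the
#' single-cursor response at mu (standard error 0).
#'
#' @param spec A [cloud_spec()] object.
#' @param params A [dn_params()] object.
#' @param n_draws Number of Monte-Carlo cloud draws (default 1e5).
#' @param seed Integer seed; the caller's RNG state is untouched.
#' @return A list with `mean`, `se`, and `n_draws`.
#' @export
expected_cloud_response <- function(spec, params, n_draws = 1e5,
                                    seed = 20231220) {
  stopifnot(inherits(spec, "cloud_spec"), inherits(params, "dn_params"),
            n_draws >= 1)
  n_draws <- as.integer(n_draws)
  if (spec$sigma == 0) {
    # degenerate cloud: every draw is n_cursors identical cursors at mu
    return(list(mean = dn_response(rep(spec$mu, spec$n_cursors), params),
                se = 0, n_draws = n_draws))
  }
  E <- with_local_seed(seed,
    matrix(stats::rnorm(n_draws * spec$n_cursors, spec$mu, spec$sigma),
           nrow = n_draws, ncol = spec$n_cursors))
  x <- dn_response_rows(E, params)
  list(mean = mean(x),
       se = if (n_draws > 1L) stats::sd(x) / sqrt(n_draws) else 0,
       n_draws = n_draws)
}
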