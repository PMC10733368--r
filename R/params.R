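#' Divisive-normalization model parameters
#'
#' Bundles the parameters of the divisive-normalization (DN) learning-response
#' model: a positive gain `w` (response units per degree of weighted tuning
#' output), a positive normalization constant `k`, the Gaussian tuning width
#' `s` (degrees), and the number of direction-tuned units `M`. `M` must be odd
#' so that 0 degrees is a grid point of the preferred-direction lattice and
#' the response is exactly odd in the error.
#'
#' @param w Positive gain.
#' @param k Positive normalization constant.
#' @param s Tuning width in degrees (default 22, the value used throughout).
#' @param M Odd integer number of units, at least 3 (default 3601, i.e. a
#'   0.1-degree grid).
#' @return An object of class `dn_params`.
#' @examples
#' p <- dn_params(w = 5.3271e-4, k = 7.7806e-7)
#' nonlinearity_index(p)
#' @export
dn_params <- function(w, k, s = 22, M = 3601) {
  stopifnot(is.numeric(w), length(w) == 1L, is.finite(w),
            is.numeric(k), length(k) == 1L, is.finite(k),
            is.numeric(s), length(s) == 1L, is.finite(s),
            is.numeric(M), length(M) == 1L, is.finite(M))
  if (w <= 0) stop("'w' must be positive", call. = FALSE)
  if (k <= 0) stop("'k' must be positive", call. = FALSE)
  if (s <= 0) stop("'s' must be positive", call. = FALSE)
  M <- as.integer(M)
  if (M < 3L || M %% 2L == 0L)
    stop("'M' must be an odd integer >= 3", call. = FALSE)
  structure(list(w = w, k = k, s = s, M = M), class = "dn_params")
}

#' @export
print.dn_params <- function(x, ...) {
  cat(sprintf("DN parameters: w = %g, k = %g, s = %g deg, M = %d (w^2/k = %g)\n",
              x$w, x$k, x$s, x$M, x$w^2 / x$k))
  invisible(x)
}

#' Maximum-likelihood model parameters
#'
#' Parameters of the cue-combination (MLE) learning-response model in its
#' identifiable form. Only the gain `c` and the noise ratios sigma_v/sigma_p
#' (`ratio_sv`, dimensionless) and k_v/sigma_p (`ratio_kv`, per degree) enter
#' the response, so only those are stored. Setting `constant_sigma = TRUE`
#' selects the ordinary-MLE variant in which the observation noise does not
#' grow with the error size (`ratio_kv` forced to zero), which makes the
#' single-cursor response exactly linear in the error.
#'
#' @param gain Positive gain `c` (response units per degree).
#' @param ratio_sv Baseline noise ratio sigma_v/sigma_p, >= 0.
#' @param ratio_kv Signal-dependent noise ratio k_v/sigma_p (per degree), >= 0.
#' @param constant_sigma Logical; if `TRUE`, force `ratio_kv = 0`.
#' @return An object of class `mle_params`.
#' @seealso [mle_params_absolute()] for the absolute-sigma constructor.
#' @examples
#' mle_params(gain = 2.963e5, ratio_sv = 122.2, ratio_kv = 8.055)
#' @export
mle_params <- function(gain, ratio_sv, ratio_kv = 0, constant_sigma = FALSE) {
  stopifnot(is.numeric(gain), length(gain) == 1L, is.finite(gain),
            is.numeric(ratio_sv), length(ratio_sv) == 1L, is.finite(ratio_sv),
            is.numeric(ratio_kv), length(ratio_kv) == 1L, is.finite(ratio_kv))
  if (gain <= 0) stop("'gain' must be positive", call. = FALSE)
  if (ratio_sv < 0 || ratio_kv < 0)
    stop("noise ratios must be non-negative", call. = FALSE)
  if (isTRUE(constant_sigma)) ratio_kv <- 0
  structure(list(gain = gain, ratio_sv = ratio_sv, ratio_kv = ratio_kv,
                 constant_sigma = isTRUE(constant_sigma)),
            class = "mle_params")
}

#' @describeIn mle_params Construct from absolute noise magnitudes. Only the
#'   ratios are identifiable, so the arguments are normalized immediately:
#'   `ratio_sv = sigma_v / sigma_p`, `ratio_kv = k_v / sigma_p`.
#' @param sigma_p Standard deviation of the predicted error (> 0).
#' @param sigma_v Baseline standard deviation of the observed error (>= 0).
#' @param k_v Slope of the signal-dependent noise (per degree, >= 0).
#' @export
mle_params_absolute <- function(gain, sigma_p, sigma_v, k_v = 0,
                                constant_sigma = FALSE) {
  stopifnot(is.numeric(sigma_p), length(sigma_p) == 1L, sigma_p > 0)
  mle_params(gain, ratio_sv = sigma_v / sigma_p, ratio_kv = k_v / sigma_p,
             constant_sigma = constant_sigma)
}

#' @export
print.mle_params <- function(x, ...) {
  cat(sprintf("MLE parameters: c = %g, sigma_v/sigma_p = %g, k_v/sigma_p = %g%s\n",
              x$gain, x$ratio_sv, x$ratio_kv,
              if (x$constant_sigma) " [constant-sigma mode]" else ""))
  invisible(x)
}

#' Set of concurrent cursor errors
#'
#' A validated vector of cursor direction errors in degrees, the input to the
#' multi-cursor model evaluations. The Gaussian tuning function is a
#' small-angle approximation of a circular (von Mises) tuning curve, so error
#' sets containing magnitudes above 90 degrees are accepted but flagged: the
#' approximation is unreliable there.
#'
#' @param errors Numeric vector of errors in degrees, length >= 1, all finite,
#'   magnitudes <= 180.
#' @return An object of class `error_set`; attribute `flagged` is `TRUE` when
#'   any magnitude exceeds 90 degrees.
#' @export
error_set <- function(errors) {
  errors <- as.numeric(errors)
  if (length(errors) < 1L)
    stop("an error set needs at least one cursor error", call. = FALSE)
  if (!all(is.finite(errors)))
    stop("cursor errors must be finite", call. = FALSE)
  if (any(abs(errors) > 180))
    stop("cursor errors must lie in [-180, 180] degrees", call. = FALSE)
  flagged <- any(abs(errors) > 90)
  if (flagged)
    warning("error magnitudes above 90 degrees: Gaussian tuning is only a small-angle approximation",
            call. = FALSE)
  structure(errors, class = "error_set", flagged = flagged)
}

as_error_set <- function(x) {
  if (inherits(x, "error_set")) x else error_set(x)
}

#' Normal-distribution specification for a cursor cloud
#'
#' Describes a perturbation condition in which `n_cursors` cursor directions
#' are drawn independently from N(mu, sigma^2) on every perturbation trial.
#'
#' @param mu Mean direction error in degrees.
#' @param sigma Standard deviation in degrees, >= 0.
#' @param n_cursors Positive integer number of cursors (default 5).
#' @return An object of class `cloud_spec`.
#' @export
cloud_spec <- function(mu, sigma, n_cursors = 5) {
  stopifnot(is.numeric(mu), length(mu) == 1L, is.finite(mu),
            is.numeric(sigma), length(sigma) == 1L, is.finite(sigma),
            is.numeric(n_cursors), length(n_cursors) == 1L)
  if (sigma < 0) stop("'sigma' must be non-negative", call. = FALSE)
  n_cursors <- as.integer(n_cursors)
  if (n_cursors < 1L) stop("'n_cursors' must be >= 1", call. = FALSE)
  structure(list(mu = mu, sigma = sigma, n_cursors = n_cursors),
            class = "cloud_spec")
}

# Run expr with a temporary RNG state seeded by `seed`, restoring the caller's
# state afterwards so library code never clobbers the user's stream.
with_local_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}
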