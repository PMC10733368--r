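#' Signal-dependent observation-noise ratio
#'
#' Standard deviation of the observed visual error relative to that of the
#' predicted error: sigma(e)/sigma_p = sigma_v/sigma_p + (k_v/sigma_p) |e|.
#' Even in e; constant when the ordinary-MLE (constant-sigma) variant is
#' selected.
#'
#' @param e Error(s) in degrees (vectorized).
#' @param params An [mle_params()] object.
#' @return Dimensionless noise ratio(s).
#' @export
sd_ratio <- function(e, params) {
  stopifnot(inherits(params, "mle_params"))
  params$ratio_sv + params$ratio_kv * abs(e)
}

#' MLE learning response to a single cursor
#'
#' The cue-combination point estimate shrinks the observed error toward the
#' predicted (zero) error by the relative reliabilities:
#' x(e) = c e / (1 + (sigma(e)/sigma_p)^2).
#' With signal-dependent noise the shrinkage grows with |e|, producing a
#' saturating curve; in constant-sigma mode the response is exactly linear.
#'
#' @param e Error(s) in degrees (vectorized).
#' @param params An [mle_params()] object.
#' @return Response(s) in arbitrary units; odd in e.
#' @export
mle_single <- function(e, params) {
  stopifnot(inherits(params, "mle_params"))
  params$gain * e / (1 + sd_ratio(e, params)^2)
}

#' MLE learning response to multiple concurrent cursors
#'
#' Precision-weighted combination of all cursors with the prediction:
#' x(e) = c (1 + sum_i w_i)^-1 sum_i w_i e_i, with weights
#' w_i = 1 / (sigma(e_i)/sigma_p)^2. Reduces exactly to [mle_single()] for one
#' cursor. Unlike the DN model, duplicating a cursor adds an independent
#' observation and strictly increases the response magnitude: the key
#' qualitative discriminator between the two models.
#'
#' @param errors An [error_set()] or numeric vector of errors (degrees).
#' @param params An [mle_params()] object.
#' @return Scalar response in arbitrary units.
#' @export
mle_multi <- function(errors, params) {
  stopifnot(inherits(params, "mle_params"))
  e <- as.numeric(as_error_set(errors))
  wts <- 1 / sd_ratio(e, params)^2
  params$gain * sum(wts * e) / (1 + sum(wts))
}

# Monte-Carlo expected MLE response to a cursor cloud: the multi-cursor
# combination rule applied to each cloud draw, sharing the DN module's
# draw scheme so model predictions are comparable.
#' Monte-Carlo expected MLE response to a cursor cloud
#'
#' @inheritParams expected_cloud_response
#' @param params An [mle_params()] object.
#' @return A list with `mean`, `se`, and `n_draws`.
#' @export
mle_cloud_response <- function(spec, params, n_draws = 1e5, seed = 20231220) {
  stopifnot(inherits(spec, "cloud_spec"), inherits(params, "mle_params"),
            n_draws >= 1)
  n_draws <- as.integer(n_draws)
  E <- with_local_seed(seed,
    matrix(stats::rnorm(n_draws * spec$n_cursors, spec$mu, spec$sigma),
           nrow = n_draws, ncol = spec$n_cursors))
  S <- params$ratio_sv + params$ratio_kv * abs(E)
  W <- 1 / (S * S)
  x <- params$gain * rowSums(W * E) / (1 + rowSums(W))
  list(mean = mean(x),
       se = if (n_draws > 1L) stats::sd(x) / sqrt(n_draws) else 0,
       n_draws = n_draws)
}

#' Declining-rate ratio under the ordinary MLE model
#'
#' Under the ordinary MLE account of cursor-cloud experiments the cloud
#' dispersion is read as the uncertainty of the visual feedback, entering the
#' shrinkage factor of the single-estimate response:
#' x(mu, sigma) = c mu / (1 + (sigma_v/sigma_p + u sigma)^2),
#' where `u` (`uncertainty_scaling`, per degree) maps the cloud standard
#' deviation into the observation-noise ratio. Because observation noise is
#' constant in the error size, the shrinkage factor is independent of the mean
#' error mu; the declining rate of the expected response relative to sigma = 0
#' is therefore the same function of sigma at every mu, and the ratio of
#' declining rates between a small and a large mean error equals 1 for every
#' sigma. This function computes that ratio from the model responses — either
#' analytically (the expectation of the cloud mean is mu) or by Monte Carlo
#' over cloud draws — rather than asserting it.
#'
#' @param mu_small,mu_large Mean error sizes in degrees (both nonzero).
#' @param sigma_grid Cloud standard deviations in degrees; must include 0 (the
#'   reference) and at least one positive value.
#' @param params An [mle_params()] object in constant-sigma mode.
#' @param uncertainty_scaling Positive per-degree factor `u` above.
#' @param n_cursors Cursors per cloud (default 5).
#' @param n_draws `NULL` for the analytic expectation (default), or a
#'   Monte-Carlo draw count.
#' @param seed Integer seed used when `n_draws` is given.
#' @return Named numeric vector: the declining-rate ratio (small-mu over
#'   large-mu) at each sigma > 0. Attribute `rates` holds the two rate maps.
#' @export
ordinary_mle_decline_ratio <- function(mu_small, mu_large, sigma_grid, params,
                                       uncertainty_scaling = 1, n_cursors = 5,
                                       n_draws = NULL, seed = 20231220) {
  stopifnot(inherits(params, "mle_params"))
  if (!params$constant_sigma && params$ratio_kv != 0)
    stop("ordinary-MLE decline ratio requires constant-sigma parameters",
         call. = FALSE)
  if (uncertainty_scaling <= 0)
    stop("'uncertainty_scaling' must be positive", call. = FALSE)
  sigma_grid <- sort(unique(as.numeric(sigma_grid)))
  if (!any(sigma_grid == 0) || !any(sigma_grid > 0))
    stop("'sigma_grid' must contain 0 and at least one positive sigma",
         call. = FALSE)
  shrink <- function(sigma)
    params$gain / (1 + (params$ratio_sv + uncertainty_scaling * sigma)^2)
  respond <- function(mu, sigma, seed) {
    if (is.null(n_draws)) return(shrink(sigma) * mu)
    E <- with_local_seed(seed,
      matrix(stats::rnorm(n_draws * n_cursors, mu, sigma),
             nrow = as.integer(n_draws), ncol = n_cursors))
    mean(shrink(sigma) * rowMeans(E))
  }
  rate_map <- function(mu, seed_off) {
    r0 <- respond(mu, 0, seed + seed_off)
    if (r0 == 0) stop("sigma = 0 response is zero: declining rate undefined",
                      call. = FALSE)
    vapply(sigma_grid, function(sg)
      (r0 - respond(mu, sg, seed + seed_off + round(100 * sg))) / r0,
      numeric(1))
  }
  rs <- rate_map(mu_small, 0L)
  rl <- rate_map(mu_large, 10000L)
  pos <- sigma_grid > 0
  if (any(rl[pos] == 0))
    stop("large-mu declining rate is zero: ratio undefined", call. = FALSE)
  out <- rs[pos] / rl[pos]
  names(out) <- sigma_grid[pos]
  attr(out, "rates") <- list(small = stats::setNames(rs, sigma_grid),
                             large = stats::setNames(rl, sigma_grid))
  out
}
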