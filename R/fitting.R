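#' Coefficient of determination
#'
#' R^2 = 1 - SS_res / SS_tot with the total sum of squares taken about the
#' mean of the observations. For out-of-condition predictions (computed
#' without refitting) the value can be negative: the prediction is then worse
#' than predicting the observed mean.
#'
#' @param observed,predicted Numeric vectors of equal length >= 2.
#' @return Scalar <= 1; equals 1 iff all residuals are zero.
#' @examples
#' r_squared(c(1, 2, 3), c(3, 2, 1))  # -3
#' @export
r_squared <- function(observed, predicted) {
  stopifnot(is.numeric(observed), is.numeric(predicted),
            length(observed) == length(predicted), length(observed) >= 2L)
  ss_tot <- sum((observed - mean(observed))^2)
  if (ss_tot == 0)
    stop("observations are all equal: R^2 is undefined", call. = FALSE)
  1 - sum((observed - predicted)^2) / ss_tot
}

# Shared multi-start bounded Levenberg-Marquardt driver. `starts` is a matrix
# of start vectors (rows) in natural units. Parameters span orders of
# magnitude and the MLE model has a poorly conditioned scaling ridge, so the
# optimizer works on log-parameters (which also enforces positivity); the
# lower bounds are the log of the smallest admissible values. Returns the
# best fit across restarts with `par` back on the natural scale.
multistart_lm <- function(resid_fn, starts, lower) {
  ctrl <- minpack.lm::nls.lm.control(ftol = 1e-12, ptol = 1e-12,
                                     maxiter = 1000, maxfev = 10000)
  log_resid <- function(lp) resid_fn(exp(lp))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      suppressWarnings(
        minpack.lm::nls.lm(par = log(pmax(starts[i, ], exp(lower))),
                           lower = lower, fn = log_resid, control = ctrl)),
      error = function(e) NULL)
    if (is.null(fit)) next
    dev <- sum(fit$fvec^2)
    if (!is.finite(dev)) next
    if (is.null(best) || dev < best_dev) {
      best <- fit
      best_dev <- dev
    }
  }
  if (is.null(best))
    stop("all restarts failed to produce a fit", call. = FALSE)
  best$par <- exp(best$par)
  best
}

check_fit_points <- function(e, response) {
  stopifnot(is.numeric(e), is.numeric(response), length(e) == length(response))
  if (length(unique(abs(e[e != 0]))) < 2L)
    stop("need at least 2 distinct non-zero error magnitudes", call. = FALSE)
  if (all(response == 0))
    stop("all responses are zero: degenerate fit", call. = FALSE)
}

make_fit_result <- function(model, params, e, response, predicted, fit,
                            n_restarts) {
  structure(list(model = model,
                 params = params,
                 r_squared = r_squared(response, predicted),
                 residuals = response - predicted,
                 fitted = predicted,
                 e = e,
                 observed = response,
                 loss = sum((response - predicted)^2),
                 n_restarts_used = n_restarts,
                 converged = fit$info %in% 1:4),
            class = "dn_fit")
}

#' @export
print.dn_fit <- function(x, ...) {
  cat(sprintf("%s fit: R^2 = %.4f over %d conditions (%s)\n",
              x$model, x$r_squared, length(x$residuals),
              if (x$converged) "converged" else "NOT converged"))
  print(x$params)
  invisible(x)
}

#' Fit the DN model to single-cursor condition means
#'
#' Least-squares fit of the closed-form single-cursor response
#' ([analytic_single()]) to condition-mean learning (or feedback) responses,
#' over the gain `w` and normalization constant `k` with the tuning width `s`
#' fixed. Because the two parameters span orders of magnitude, the optimizer
#' is restarted from a log-spaced grid (w in 1e-5..1e-2 by k in 1e-8..1e-4,
#' 5 x 5) and the best restart is returned.
#'
#' @param e Errors in degrees (condition levels, e = 0 allowed).
#' @param response Condition-mean responses (arbitrary units).
#' @param s Tuning width, degrees (fixed; default 22).
#' @param M Unit count carried into the returned [dn_params()].
#' @param start_grid Optional matrix of custom (w, k) starts.
#' @return A `dn_fit` object: fitted params, R^2, residuals, convergence flag.
#' @examples
#' p <- dn_params(w = 5.3271e-4, k = 7.7806e-7)
#' e <- c(0, 7.5, 15, 30, 45)
#' fit <- fit_dn_single(e, analytic_single(e, p))
#' fit$params$w / p$w  # ~1
#' @export
fit_dn_single <- function(e, response, s = 22, M = 3601, start_grid = NULL) {
  check_fit_points(e, response)
  if (is.null(start_grid)) {
    start_grid <- as.matrix(expand.grid(w = 10^seq(-5, -2, length.out = 5),
                                        k = 10^seq(-8, -4, length.out = 5)))
  }
  resid_fn <- function(p) {
    w <- p[1]; k <- p[2]
    response - 2 * sqrt(2 * pi) * w * s * e /
      (720 * k + sqrt(pi) * w^2 * s * (s^2 + 2 * e^2))
  }
  fit <- multistart_lm(resid_fn, start_grid, lower = log(c(1e-12, 1e-15)))
  params <- dn_params(w = fit$par[1], k = fit$par[2], s = s, M = M)
  make_fit_result("DN", params, e, response, analytic_single(e, params), fit,
                  nrow(start_grid))
}

#' Fit the MLE model to single-cursor condition means
#'
#' Least-squares fit of the signal-dependent-noise shrinkage model
#' ([mle_single()]) over the identifiable triplet (c, sigma_v/sigma_p,
#' k_v/sigma_p), all bounded below by zero, with multi-start over a log grid
#' (c in 1e3..1e7, sigma_v/sigma_p in 10..1e3, k_v/sigma_p in 0.1..1e2).
#' Exactly linear data drive the fitted k_v/sigma_p to zero, recovering the
#' ordinary-MLE limit.
#'
#' @inheritParams fit_dn_single
#' @param start_grid Optional matrix of custom (gain, ratio_sv, ratio_kv)
#'   starts.
#' @return A `dn_fit` object with [mle_params()] in `$params`.
#' @export
fit_mle_single <- function(e, response, start_grid = NULL) {
  check_fit_points(e, response)
  if (is.null(start_grid)) {
    start_grid <- as.matrix(expand.grid(
      gain = 10^seq(3, 7, length.out = 5),
      ratio_sv = 10^seq(1, 3, length.out = 3),
      ratio_kv = 10^seq(-1, 2, length.out = 4)))
  }
  resid_fn <- function(p)
    response - p[1] * e / (1 + (p[2] + p[3] * abs(e))^2)
  fit <- multistart_lm(resid_fn, start_grid, lower = log(c(1e-9, 1e-6, 1e-9)))
  params <- mle_params(gain = fit$par[1], ratio_sv = fit$par[2],
                       ratio_kv = fit$par[3])
  make_fit_result("MLE", params, e, response, mle_single(e, params), fit,
                  nrow(start_grid))
}

#' Predict condition responses from fitted parameters
#'
#' Dispatches each held-out condition to the appropriate evaluator: error
#' sets go to [dn_response()] or [mle_multi()], cloud specifications to the
#' Monte-Carlo expectation ([expected_cloud_response()] or
#' [mle_cloud_response()]). Predictions are computed from already-fitted
#' parameters without refitting, which is what allows a negative prediction
#' R^2 for a poor model.
#'
#' @param params A [dn_params()] or [mle_params()] object.
#' @param conditions List of [error_set()] / [cloud_spec()] objects (bare
#'   numeric vectors are treated as error sets).
#' @param n_draws,seed Monte-Carlo settings for cloud conditions; each cloud
#'   condition uses an independent seed offset so draws are per-condition
#'   independent.
#' @return Numeric vector of predicted responses, one per condition.
#' @export
predict_conditions <- function(params, conditions, n_draws = 1e5,
                               seed = 20231220) {
  stopifnot(is.list(conditions))
  is_dn <- inherits(params, "dn_params")
  if (!is_dn && !inherits(params, "mle_params"))
    stop("'params' must be dn_params or mle_params", call. = FALSE)
  vapply(seq_along(conditions), function(i) {
    cond <- conditions[[i]]
    if (inherits(cond, "cloud_spec")) {
      res <- if (is_dn)
        expected_cloud_response(cond, params, n_draws, seed + i)
      else mle_cloud_response(cond, params, n_draws, seed + i)
      res$mean
    } else {
      if (is_dn) dn_response(cond, params) else mle_multi(cond, params)
    }
  }, numeric(1))
}
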