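default_true_params <- function(experiment, response_type) {
  # Generating parameters default to the single-cursor fits reported for the
  # corresponding experiment and response type.
  key <- paste(experiment, response_type, sep = "/")
  switch(key,
         "exp1/learning"  = list(w = 5.3271e-4, k = 7.7806e-7),
         "exp1/feedback"  = list(w = 4.0541e-4, k = 9.2642e-5),
         "exp2/learning"  = list(w = 2.0002e-4, k = 2.1434e-6),
         "exp2/feedback"  = list(w = 2.3700e-4, k = 1.2071e-5),
         "exp3/learning"  = list(w = 4.7525e-4, k = 2.1102e-6),
         stop("no default generating parameters for ", key, call. = FALSE))
}

#' Build and validate an analysis configuration
#'
#' Fills defaults for any field not supplied and validates types and bounds.
#' Fields: `experiment` ("exp1"/"exp2"/"exp3"), `response_type`
#' ("learning"/"feedback"), `model` ("dn"/"mle"/"both"), `M`, `s`, `n_draws`
#' (Monte-Carlo draws for cloud predictions), `seed`, `input_responses`
#' (optional CSV path; when absent data are simulated), and `synthetic`
#' (`w`, `k`, `noise_sd`, `n_participants` of the generator).
#'
#' @param config A named list, or a path to a JSON file with those fields.
#' @return Validated config list of class `analysis_config`.
#' @export
analysis_config <- function(config = list()) {
  if (is.character(config) && length(config) == 1L) {
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  stopifnot(is.list(config))
  cfg <- list(experiment = "exp1", response_type = "learning",
              model = "both", M = 3601, s = 22, n_draws = 1e5,
              seed = 20231220, input_responses = NULL,
              synthetic = list())
  cfg[names(config)] <- config
  problems <- character(0)
  chk <- function(ok, msg) if (!ok) problems <<- c(problems, msg)
  chk(cfg$experiment %in% c("exp1", "exp2", "exp3"),
      "experiment must be exp1, exp2 or exp3")
  chk(cfg$response_type %in% c("learning", "feedback"),
      "response_type must be learning or feedback")
  chk(!(cfg$experiment == "exp3" && cfg$response_type == "feedback"),
      "exp3 provides endpoint feedback only: no feedback response exists")
  chk(cfg$model %in% c("dn", "mle", "both"), "model must be dn, mle or both")
  chk(is.numeric(cfg$M) && cfg$M >= 3 && cfg$M %% 2 == 1,
      "M must be an odd integer >= 3")
  chk(is.numeric(cfg$s) && cfg$s > 0, "s must be positive")
  chk(is.numeric(cfg$n_draws) && cfg$n_draws >= 1, "n_draws must be >= 1")
  chk(is.numeric(cfg$seed) && cfg$seed == round(cfg$seed),
      "seed must be an integer")
  chk(is.null(cfg$input_responses) ||
        (is.character(cfg$input_responses) && file.exists(cfg$input_responses)),
      "input_responses must be an existing CSV path")
  if (length(problems) > 0)
    stop("invalid configuration:\n  - ", paste(problems, collapse = "\n  - "),
         call. = FALSE)
  syn_default <- c(default_true_params(cfg$experiment, cfg$response_type),
                   list(noise_sd = NULL, n_participants = 8))
  syn <- syn_default
  syn[names(cfg$synthetic)] <- cfg$synthetic
  cfg$synthetic <- syn
  structure(cfg, class = "analysis_config")
}

fit_points_for <- function(schedule, means) {
  # Single-cursor (or sigma = 0) collapsed conditions used for fitting; every
  # other condition is held out for prediction.
  csched <- collapsed_schedule(schedule)
  if (csched$type[1] == "cloud") {
    pick <- csched$sigma == 0
    e <- csched$mu[pick]
  } else {
    pick <- csched$type == "single"
    e <- csched$e1[pick]
  }
  ids <- csched$condition_id[pick]
  list(ids = ids, e = e, response = means[ids],
       holdout = csched$condition_id[!pick])
}

#' Run the full fit-then-predict workflow
#'
#' Executes the analysis the models were designed for: obtain (or simulate)
#' condition-level responses, collapse sign-mirrored conditions within
#' participant, average across participants, fit the single-cursor (or
#' zero-dispersion) condition means with the DN and/or MLE model, predict the
#' strictly held-out multi-cursor or cursor-cloud conditions from the fitted
#' parameters, and derive the summary statistics (averaged double-cursor
#' response for the multi-cursor design; declining rates and their
#' small-vs-large mean-error ratio for the cloud design). Results are
#' returned and, when `out_dir` is given, written as CSV/JSON with a run log.
#'
#' @param config An [analysis_config()], list, or JSON path.
#' @param out_dir Optional output directory (created if needed).
#' @return Invisibly, a list with the schedule, response tables, fits,
#'   predictions, prediction R^2 per model, and derived statistics.
#' @export
run_analysis <- function(config = list(), out_dir = NULL) {
  cfg <- if (inherits(config, "analysis_config")) config
         else analysis_config(config)
  schedule <- switch(cfg$experiment,
                     exp1 = build_exp1_schedule(),
                     exp2 = build_exp23_schedule("online"),
                     exp3 = build_exp23_schedule("endpoint"))
  simulated <- is.null(cfg$input_responses)
  if (simulated) {
    true_params <- dn_params(cfg$synthetic$w, cfg$synthetic$k,
                             s = cfg$s, M = cfg$M)
    responses <- simulate_responses(schedule, true_params,
                                    noise_sd = cfg$synthetic$noise_sd,
                                    n_participants = cfg$synthetic$n_participants,
                                    seed = cfg$seed,
                                    response_type = cfg$response_type)
  } else {
    responses <- read_response_csv(cfg$input_responses)
    responses <- responses[responses$response_type == cfg$response_type, ]
  }
  collapsed <- collapse_symmetric(responses, schedule)
  cm <- condition_means(collapsed)
  means <- stats::setNames(cm$mean_response, cm$condition_id)
  fp <- fit_points_for(schedule, means)

  models <- if (cfg$model == "both") c("dn", "mle") else cfg$model
  fits <- list()
  preds <- list()
  pred_r2 <- list()
  hold_conds <- schedule_conditions(schedule)[fp$holdout]
  for (m in models) {
    fit <- if (m == "dn") fit_dn_single(fp$e, fp$response, s = cfg$s, M = cfg$M)
           else fit_mle_single(fp$e, fp$response)
    fits[[m]] <- fit
    pr <- predict_conditions(fit$params, hold_conds,
                             n_draws = cfg$n_draws, seed = cfg$seed)
    names(pr) <- fp$holdout
    preds[[m]] <- pr
    pred_r2[[m]] <- if (length(pr) >= 2) r_squared(means[fp$holdout], pr)
                    else NA_real_
  }

  derived <- derive_stats(cfg, schedule, means, fits)
  result <- list(config = cfg, schedule = schedule, responses = responses,
                 collapsed = collapsed, condition_means = cm, fits = fits,
                 fit_conditions = fp$ids, holdout_conditions = fp$holdout,
                 predictions = preds, prediction_r_squared = pred_r2,
                 derived = derived, simulated = simulated)
  if (!is.null(out_dir)) write_bundle(result, out_dir)
  invisible(result)
}

derive_stats <- function(cfg, schedule, means, fits) {
  derived <- list()
  for (m in names(fits)) {
    params <- fits[[m]]$params
    if (cfg$experiment == "exp1") {
      full_conds <- schedule_conditions(schedule)
      full_pred <- predict_conditions(params, full_conds,
                                      n_draws = cfg$n_draws, seed = cfg$seed)
      names(full_pred) <- names(full_conds)
      av <- averaged_response(full_pred, schedule)
      derived[[m]] <- list(
        averaged_response_by_e2 = stats::setNames(av$mean_response, av$e2),
        single_reference = attr(av, "single_reference"))
    } else {
      rate_at <- function(mu) {
        cl <- lapply(c(0, 7, 20), function(sg) cloud_spec(mu, sg, 5))
        pr <- predict_conditions(params, cl, n_draws = cfg$n_draws,
                                 seed = cfg$seed + round(mu))
        declining_rate(stats::setNames(pr, c(0, 7, 20)))
      }
      rs <- rate_at(14); rl <- rate_at(40)
      dr <- decline_ratio(rs, rl)
      derived[[m]] <- list(declining_rate_mu14 = as.list(rs),
                           declining_rate_mu40 = as.list(rl),
                           decline_ratio = dr)
    }
  }
  # Observed-data version of the same statistics.
  obs <- tryCatch({
    if (cfg$experiment == "exp1") {
      full_obs <- expand_collapsed(means, schedule)
      av <- averaged_response(full_obs, schedule)
      list(averaged_response_by_e2 = stats::setNames(av$mean_response, av$e2),
           single_reference = attr(av, "single_reference"))
    } else {
      rate_obs <- function(mu) {
        ids <- sprintf("C_mu%s_sd%g", fmt_angle(mu), c(0, 7, 20))
        declining_rate(stats::setNames(means[ids], c(0, 7, 20)))
      }
      rs <- rate_obs(14); rl <- rate_obs(40)
      list(declining_rate_mu14 = as.list(rs),
           declining_rate_mu40 = as.list(rl),
           decline_ratio = decline_ratio(rs, rl))
    }
  }, error = function(e) list(error = conditionMessage(e)))
  derived$observed <- obs
  if (cfg$experiment != "exp1") {
    # Figure-facing orientation: the one below unity for the DN model at the
    # largest sigma (both orientations are retained above).
    ref <- derived[[if ("dn" %in% names(fits)) "dn" else names(fits)[1]]]
    dr <- ref$decline_ratio
    last <- which.max(dr$sigma)
    derived$reported_orientation <-
      if (dr$ratio_large_over_small[last] < 1) "large_over_small"
      else "small_over_large"
  }
  derived
}

serialize_fit <- function(fit) {
  list(model = fit$model, params = unclass(fit$params),
       r_squared = fit$r_squared, loss = fit$loss,
       converged = fit$converged, n_restarts_used = fit$n_restarts_used,
       e = fit$e, observed = fit$observed, fitted = fit$fitted,
       residuals = fit$residuals)
}

write_bundle <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wj <- function(x, file)
    jsonlite::write_json(x, file.path(out_dir, file), pretty = TRUE,
                         auto_unbox = TRUE, digits = NA, null = "null")
  write_schedule_csv(result$schedule, file.path(out_dir, "schedule.csv"))
  write_response_csv(result$responses, file.path(out_dir, "responses.csv"))
  utils::write.csv(result$condition_means,
                   file.path(out_dir, "condition_means.csv"),
                   row.names = FALSE, fileEncoding = "UTF-8")
  for (m in names(result$fits))
    wj(serialize_fit(result$fits[[m]]), sprintf("fit_%s.json", m))
  pred_df <- do.call(rbind, lapply(names(result$predictions), function(m)
    data.frame(model = m,
               condition_id = names(result$predictions[[m]]),
               predicted = as.numeric(result$predictions[[m]]),
               observed = as.numeric(
                 stats::setNames(result$condition_means$mean_response,
                                 result$condition_means$condition_id)[
                                   names(result$predictions[[m]])]))))
  utils::write.csv(pred_df, file.path(out_dir, "predictions.csv"),
                   row.names = FALSE, fileEncoding = "UTF-8")
  wj(result$derived, "derived_stats.json")
  cfg <- result$config
  wj(list(config = unclass(cfg),
          seed = cfg$seed,
          n_draws = cfg$n_draws,
          simulated = result$simulated,
          prediction_r_squared = result$prediction_r_squared,
          n_conditions = nrow(result$schedule),
          n_collapsed = nrow(collapsed_schedule(result$schedule)),
          package_version = as.character(utils::packageVersion("divnorm")),
          r_version = paste(R.version$major, R.version$minor, sep = ".")),
     "run_log.json")
  invisible(out_dir)
}
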