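# Canonical keys used to identify sign-mirrored condition pairs. For
# error-set conditions the key is the sorted error multiset; for clouds it is
# (mu, sigma). The mirror negates all errors (clouds: mu only).
condition_keys <- function(schedule) {
  key1 <- character(nrow(schedule))
  keym <- character(nrow(schedule))
  orient <- numeric(nrow(schedule))
  for (i in seq_len(nrow(schedule))) {
    row <- schedule[i, ]
    if (row$type == "cloud") {
      key1[i] <- sprintf("cloud|%g|%g", row$mu, row$sigma)
      keym[i] <- sprintf("cloud|%g|%g", 0 - row$mu, row$sigma)  # 0 - x avoids "-0"
      orient[i] <- row$mu
    } else {
      e <- condition_errors(row)
      key1[i] <- paste0(row$type, "|", paste(sort(e), collapse = ","))
      keym[i] <- paste0(row$type, "|", paste(sort(-e), collapse = ","))
      orient[i] <- sum(e)
    }
  }
  data.frame(condition_id = schedule$condition_id, key = key1, mirror = keym,
             orientation = orient, stringsAsFactors = FALSE)
}

#' Schedule restricted to collapsed (sign-representative) conditions
#'
#' Sign-mirrored condition pairs are represented by their positively oriented
#' member (positive error sum; for clouds, positive mu); self-mirrored
#' conditions (all errors zero, or mu = 0) represent themselves.
#'
#' @param schedule A `perturbation_schedule`.
#' @return The schedule rows of the representative conditions.
#' @export
collapsed_schedule <- function(schedule) {
  keys <- condition_keys(schedule)
  self <- keys$key == keys$mirror
  rep_rows <- self | keys$orientation > 0
  missing <- setdiff(keys$mirror, keys$key)
  if (length(missing) > 0)
    stop("schedule is missing mirror conditions: ",
         paste(missing, collapse = ", "), call. = FALSE)
  out <- schedule[rep_rows, , drop = FALSE]
  new_schedule(as.data.frame(out), attr(schedule, "cycles"),
               attr(schedule, "experiment"))
}

#' Simulate condition-level responses under a ground-truth DN model
#'
#' For every participant x condition x cycle the generating model is
#' evaluated — fixed error sets directly, cloud conditions with a fresh
#' 5-cursor draw each perturbation trial — and independent Gaussian noise of
#' standard deviation `noise_sd` is added to the scalar response. Cycle
#' responses are averaged within participant, mirroring the analysis order
#' (cycles within participant first, participants after).
#'
#' @param schedule A `perturbation_schedule`.
#' @param true_params Generating [dn_params()].
#' @param noise_sd Response-unit noise SD; default 15% of the generating
#'   model's peak single-cursor response.
#' @param n_participants Number of simulated participants (default 8).
#' @param seed Integer seed; caller's RNG state is preserved.
#' @param response_type `"learning"` or `"feedback"` label for the table.
#' @return A data frame with columns `participant_id`, `condition_id`,
#'   `response_type`, `response` (one row per participant x condition).
#' @export
simulate_responses <- function(schedule, true_params, noise_sd = NULL,
                               n_participants = 8, seed = 1L,
                               response_type = c("learning", "feedback")) {
  stopifnot(inherits(schedule, "perturbation_schedule"),
            inherits(true_params, "dn_params"))
  response_type <- match.arg(response_type)
  if (is.null(noise_sd))
    noise_sd <- 0.15 * analytic_single(analytic_peak(true_params), true_params)
  stopifnot(noise_sd >= 0, n_participants >= 1)
  cycles <- attr(schedule, "cycles")
  conds <- schedule_conditions(schedule)
  with_local_seed(seed, {
    rows <- vector("list", length(conds))
    for (ci in seq_along(conds)) {
      cond <- conds[[ci]]
      if (inherits(cond, "cloud_spec")) {
        E <- matrix(stats::rnorm(n_participants * cycles * cond$n_cursors,
                                 cond$mu, cond$sigma),
                    nrow = n_participants * cycles, ncol = cond$n_cursors)
        base <- matrix(dn_response_rows(E, true_params),
                       nrow = n_participants, ncol = cycles)
      } else {
        base <- matrix(dn_response(cond, true_params),
                       nrow = n_participants, ncol = cycles)
      }
      noise <- matrix(stats::rnorm(n_participants * cycles, 0, noise_sd),
                      nrow = n_participants, ncol = cycles)
      rows[[ci]] <- data.frame(
        participant_id = sprintf("P%02d", seq_len(n_participants)),
        condition_id = names(conds)[ci],
        response_type = response_type,
        response = rowMeans(base + noise))
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' Collapse sign-mirrored conditions
#'
#' Responses to a condition and its sign mirror carry the same information
#' with opposite sign, so each mirrored pair (C, -C) is collapsed to
#' (response(C) - response(-C)) / 2, assigned to the positively oriented
#' representative. The antisymmetric combination also removes any constant
#' response offset. Self-mirrored conditions (all-zero errors, mu = 0 clouds)
#' pass through unchanged. Collapsing is done within participant.
#'
#' @param table A response table as produced by [simulate_responses()].
#' @param schedule The `perturbation_schedule` the table was generated under.
#' @return A response table over the [collapsed_schedule()] conditions.
#' @export
collapse_symmetric <- function(table, schedule) {
  stopifnot(all(c("participant_id", "condition_id", "response_type",
                  "response") %in% names(table)))
  keys <- condition_keys(schedule)
  mirror_of <- keys$condition_id[match(keys$mirror, keys$key)]
  if (anyNA(mirror_of))
    stop("schedule is missing mirror conditions: ",
         paste(keys$condition_id[is.na(mirror_of)], collapse = ", "),
         call. = FALSE)
  names(mirror_of) <- keys$condition_id
  reps <- collapsed_schedule(schedule)$condition_id
  unknown <- setdiff(table$condition_id, keys$condition_id)
  if (length(unknown) > 0)
    stop("response table has conditions absent from the schedule: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  out <- lapply(reps, function(id) {
    mid <- mirror_of[[id]]
    a <- table[table$condition_id == id, ]
    if (mid == id) return(a)
    b <- table[table$condition_id == mid, ]
    m <- match(paste(a$participant_id, a$response_type),
               paste(b$participant_id, b$response_type))
    if (anyNA(m))
      stop("mirror responses missing for condition ", id, call. = FALSE)
    a$response <- (a$response - b$response[m]) / 2
    a
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Condition means across participants
#'
#' @param table A response table.
#' @return Data frame of `condition_id`, `response_type`, `mean_response`,
#'   `se`, `n`.
#' @export
condition_means <- function(table) {
  agg <- stats::aggregate(response ~ condition_id + response_type,
                          data = table,
                          FUN = function(x) c(mean = mean(x),
                                              sd = stats::sd(x),
                                              n = length(x)))
  data.frame(condition_id = agg$condition_id,
             response_type = agg$response_type,
             mean_response = agg$response[, "mean"],
             se = agg$response[, "sd"] / sqrt(agg$response[, "n"]),
             n = agg$response[, "n"])
}

#' Write or read a response table as CSV
#'
#' @param table A response table.
#' @param path File path.
#' @export
write_response_csv <- function(table, path) {
  utils::write.csv(table[, c("participant_id", "condition_id",
                             "response_type", "response")],
                   path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_response_csv
#' @export
read_response_csv <- function(path) {
  df <- utils::read.csv(path, fileEncoding = "UTF-8")
  need <- c("participant_id", "condition_id", "response_type", "response")
  if (!all(need %in% names(df)))
    stop("response CSV must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (!all(is.finite(df$response)))
    stop("responses must be finite", call. = FALSE)
  df
}
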