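fmt_angle <- function(x) {
  ifelse(is.na(x), "", sprintf("%+g", x))
}

new_schedule <- function(df, cycles, experiment) {
  structure(df, cycles = as.integer(cycles), trials_per_set = 4L,
            experiment = experiment,
            class = c("perturbation_schedule", "data.frame"))
}

#' Multi-cursor perturbation schedule (experiment 1 design)
#'
#' Builds the 39-condition single/double/triple-cursor design: 9 single-cursor
#' conditions (e1 = 0, +/-7.5, +/-15, +/-30, +/-45 degrees), 18 double-cursor
#' conditions (unordered pairs from 0, +/-15, +/-30, +/-45 excluding
#' |e1| = |e2|), and 12 triple-cursor conditions (e1 in -45, -30, -15, 0, 15,
#' 22.5 with e2 = 30, e3 = 45, plus the 6 sign-mirrored patterns). Each
#' condition is run once per cycle inside a 4-trial set (perturbation, probe,
#' 2 washout nulls); with 9 cycles the design totals 1404 trials.
#'
#' @return A `perturbation_schedule` data frame with columns `condition_id`,
#'   `type`, `n_cursors`, `e1`, `e2`, `e3`, `mu`, `sigma`, `feedback_mode`,
#'   and attributes `cycles` (9) and `trials_per_set` (4).
#' @examples
#' sched <- build_exp1_schedule()
#' nrow(sched)        # 39
#' n_trials(sched)    # 1404
#' @export
build_exp1_schedule <- function() {
  singles <- c(0, 7.5, -7.5, 15, -15, 30, -30, 45, -45)
  vals <- c(-45, -30, -15, 0, 15, 30, 45)
  pairs <- utils::combn(vals, 2)
  keep <- abs(pairs[1, ]) != abs(pairs[2, ])
  pairs <- pairs[, keep, drop = FALSE]
  tri_e1 <- c(-45, -30, -15, 0, 15, 22.5)
  rows <- rbind(
    data.frame(type = "single", n_cursors = 1L,
               e1 = singles, e2 = NA_real_, e3 = NA_real_),
    data.frame(type = "double", n_cursors = 2L,
               e1 = pairs[1, ], e2 = pairs[2, ], e3 = NA_real_),
    data.frame(type = "triple", n_cursors = 3L,
               e1 = tri_e1, e2 = 30, e3 = 45),
    data.frame(type = "triple", n_cursors = 3L,
               e1 = -tri_e1, e2 = -30, e3 = -45))
  rows$mu <- NA_real_
  rows$sigma <- NA_real_
  rows$feedback_mode <- "online"
  rows$condition_id <- paste0(toupper(substr(rows$type, 1, 1)),
                              fmt_angle(rows$e1),
                              ifelse(is.na(rows$e2), "", paste0("_", fmt_angle(rows$e2))),
                              ifelse(is.na(rows$e3), "", paste0("_", fmt_angle(rows$e3))))
  rows <- rows[, c("condition_id", "type", "n_cursors", "e1", "e2", "e3",
                   "mu", "sigma", "feedback_mode")]
  new_schedule(rows, cycles = 9L, experiment = "exp1")
}

#' Cursor-cloud perturbation schedule (experiments 2 and 3 design)
#'
#' Builds the 15-condition cursor-cloud design: on every perturbation trial 5
#' cursor directions are drawn from one of the normal distributions
#' N(mu, sigma^2) with mu = 0, +/-14, +/-40 degrees and sigma = 0, 7, 20
#' degrees. With 12 cycles of 4-trial sets the design totals 720 trials.
#' `feedback_mode` records whether cursors are visible during the movement
#' ("online", experiment 2) or only after it ("endpoint", experiment 3).
#'
#' @param feedback_mode `"online"` or `"endpoint"`.
#' @return A `perturbation_schedule` data frame (see [build_exp1_schedule()]).
#' @examples
#' n_trials(build_exp23_schedule("online"))  # 720
#' @export
build_exp23_schedule <- function(feedback_mode = c("online", "endpoint")) {
  feedback_mode <- match.arg(feedback_mode)
  grid <- expand.grid(mu = c(0, 14, -14, 40, -40), sigma = c(0, 7, 20))
  rows <- data.frame(type = "cloud", n_cursors = 5L,
                     e1 = NA_real_, e2 = NA_real_, e3 = NA_real_,
                     mu = grid$mu, sigma = grid$sigma,
                     feedback_mode = feedback_mode)
  rows$condition_id <- sprintf("C_mu%s_sd%g", fmt_angle(rows$mu), rows$sigma)
  rows <- rows[, c("condition_id", "type", "n_cursors", "e1", "e2", "e3",
                   "mu", "sigma", "feedback_mode")]
  new_schedule(rows, cycles = 12L,
               experiment = if (feedback_mode == "online") "exp2" else "exp3")
}

#' @describeIn build_exp1_schedule Total trial count of a schedule:
#'   trials_per_set x cycles x number of conditions.
#' @param schedule A `perturbation_schedule`.
#' @export
n_trials <- function(schedule) {
  stopifnot(inherits(schedule, "perturbation_schedule"))
  attr(schedule, "trials_per_set") * attr(schedule, "cycles") * nrow(schedule)
}

# Error multiset (or cloud spec) of one schedule row.
condition_errors <- function(row) {
  if (row$type == "cloud") return(NULL)
  e <- c(row$e1, row$e2, row$e3)
  e[!is.na(e)]
}

#' Convert schedule rows to model-evaluable condition objects
#'
#' @param schedule A `perturbation_schedule`.
#' @return Named list (by `condition_id`) of [error_set()] / [cloud_spec()]
#'   objects.
#' @export
schedule_conditions <- function(schedule) {
  stopifnot(inherits(schedule, "perturbation_schedule"))
  out <- lapply(seq_len(nrow(schedule)), function(i) {
    row <- schedule[i, ]
    if (row$type == "cloud")
      cloud_spec(row$mu, row$sigma, row$n_cursors)
    else
      error_set(condition_errors(row))
  })
  names(out) <- schedule$condition_id
  out
}

#' Write or read a schedule as CSV
#'
#' Plain UTF-8 CSV with header and `.` decimal separator; the cycle count and
#' trials-per-set are carried in extra columns so the file round-trips.
#'
#' @param schedule A `perturbation_schedule`.
#' @param path File path.
#' @export
write_schedule_csv <- function(schedule, path) {
  stopifnot(inherits(schedule, "perturbation_schedule"))
  df <- as.data.frame(schedule)
  df$cycles <- attr(schedule, "cycles")
  df$experiment <- attr(schedule, "experiment")
  utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_schedule_csv
#' @export
read_schedule_csv <- function(path) {
  df <- utils::read.csv(path, fileEncoding = "UTF-8")
  cycles <- unique(df$cycles)
  experiment <- unique(df$experiment)
  stopifnot(length(cycles) == 1L, length(experiment) == 1L)
  df$cycles <- NULL
  df$experiment <- NULL
  new_schedule(df, cycles = cycles, experiment = experiment)
}
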