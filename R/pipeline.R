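#' Expand collapsed condition-mean responses to the full schedule
#'
#' A collapsed response table assigns one value to each sign-representative
#' condition; the mirrored partner's value is its negative. This helper
#' rebuilds a named vector over the full schedule from collapsed means, which
#' is convenient when a full signed grid is needed (e.g. for
#' [averaged_response()]).
#'
#' @param collapsed Named numeric vector of mean responses over
#'   [collapsed_schedule()] condition ids.
#' @param schedule The full `perturbation_schedule`.
#' @return Named numeric vector over all schedule condition ids.
#' @export
expand_collapsed <- function(collapsed, schedule) {
  keys <- condition_keys(schedule)
  mirror_of <- keys$condition_id[match(keys$mirror, keys$key)]
  names(mirror_of) <- keys$condition_id
  reps <- collapsed_schedule(schedule)$condition_id
  out <- stats::setNames(numeric(nrow(schedule)), keys$condition_id)
  for (id in keys$condition_id) {
    if (id %in% reps) {
      out[id] <- collapsed[[id]]
    } else {
      out[id] <- -collapsed[[mirror_of[[id]]]]
    }
  }
  out
}

#' Mean double-cursor response averaged over the primary error
#'
#' Summarizes the influence of an added second cursor by averaging the
#' learning response over primary errors e1 = 15, 30, 45 degrees at each
#' second-cursor level e2 in -45 ... +45. Grid cells with e1 = e2 are served
#' by the single-cursor condition at e1 (an identical duplicated cursor);
#' cells with e1 = -e2 do not exist in the design and are skipped. The
#' single-cursor reference is the mean response over e1 = 15, 30, 45.
#'
#' @param responses Named numeric vector of responses over the full schedule
#'   condition ids (model predictions, or observed means via
#'   [expand_collapsed()]).
#' @param schedule The full experiment-1 `perturbation_schedule`.
#' @param e1_levels Primary errors averaged over (default 15, 30, 45).
#' @param e2_levels Second-cursor levels (default -45 ... +45).
#' @return Data frame of `e2`, `mean_response`, `n_cells`, with the
#'   single-cursor reference in attribute `single_reference`.
#' @export
averaged_response <- function(responses, schedule,
                              e1_levels = c(15, 30, 45),
                              e2_levels = c(-45, -30, -15, 0, 15, 30, 45)) {
  stopifnot(inherits(schedule, "perturbation_schedule"))
  lookup <- function(errs) {
    key <- paste(sort(errs), collapse = ",")
    for (i in seq_len(nrow(schedule))) {
      row <- schedule[i, ]
      if (row$type == "cloud") next
      if (paste(sort(condition_errors(row)), collapse = ",") == key) {
        if (!row$condition_id %in% names(responses)) return(NA_real_)
        return(responses[[row$condition_id]])
      }
    }
    NA_real_
  }
  singles <- vapply(e1_levels, function(e) lookup(e), numeric(1))
  if (anyNA(singles))
    stop("incomplete design: missing single-cursor reference conditions",
         call. = FALSE)
  out <- lapply(e2_levels, function(e2) {
    vals <- vapply(e1_levels, function(e1) {
      if (e1 == e2) return(lookup(e1))      # duplicated cursor = single
      if (e1 == -e2) return(NA_real_)       # |e1| = |e2| excluded by design
      lookup(c(e1, e2))
    }, numeric(1))
    vals <- vals[!is.na(vals)]
    if (length(vals) == 0)
      stop("incomplete design: no double-cursor conditions at e2 = ", e2,
           call. = FALSE)
    data.frame(e2 = e2, mean_response = mean(vals), n_cells = length(vals))
  })
  out <- do.call(rbind, out)
  attr(out, "single_reference") <- mean(singles)
  out
}

#' Declining rate of the response under feedback uncertainty
#'
#' Fractional reduction of the response at cloud dispersion sigma relative to
#' the sigma = 0 response at the same mean error:
#' rate(sigma) = (r(0) - r(sigma)) / r(0). Rate 0 at sigma = 0 by
#' construction; negative rates (responses above the zero-dispersion
#' baseline) are passed through unaltered.
#'
#' @param response_by_sigma Named numeric vector of responses; names are the
#'   sigma values in degrees and must include `"0"`.
#' @return Named numeric vector of rates on the same sigma grid.
#' @export
declining_rate <- function(response_by_sigma) {
  sig <- as.numeric(names(response_by_sigma))
  if (anyNA(sig) || !any(sig == 0))
    stop("'response_by_sigma' must be named by sigma values including 0",
         call. = FALSE)
  r0 <- response_by_sigma[[which(sig == 0)[1]]]
  if (r0 == 0)
    stop("sigma = 0 response is zero: declining rate undefined", call. = FALSE)
  stats::setNames((r0 - response_by_sigma) / r0, names(response_by_sigma))
}

#' Ratio of declining rates between a small and a large mean error
#'
#' Forms, at each sigma > 0 shared by the two rate maps, both orientations of
#' the ratio of declining rates: small-mu over large-mu and its reciprocal.
#' Both are returned because the sign and orientation conventions in the
#' literature are ambiguous when a rate is negative; the reporting code
#' chooses the figure-facing orientation (the one below unity for the DN
#' model at the largest sigma).
#'
#' @param rates_small,rates_large Named rate vectors from [declining_rate()]
#'   on a shared sigma grid.
#' @return Data frame of `sigma`, `ratio_small_over_large`,
#'   `ratio_large_over_small`.
#' @export
decline_ratio <- function(rates_small, rates_large) {
  shared <- intersect(names(rates_small), names(rates_large))
  sig <- as.numeric(shared)
  shared <- shared[sig > 0]
  sig <- sig[sig > 0]
  if (length(shared) == 0)
    stop("no shared sigma > 0 between the rate maps", call. = FALSE)
  rs <- rates_small[shared]
  rl <- rates_large[shared]
  if (any(rl == 0) || any(rs == 0))
    stop("zero declining rate: ratio undefined", call. = FALSE)
  data.frame(sigma = sig,
             ratio_small_over_large = as.numeric(rs / rl),
             ratio_large_over_small = as.numeric(rl / rs))
}
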