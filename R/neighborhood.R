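#' Compute teleworking profiles from work-shift records
#'
#' The teleworking rate is the number of days worked from home divided by
#' the number of days worked (absence days excluded), over the whole study
#' period by default. Participants with zero worked days have no defined
#' rate and are dropped with a warning (they cannot be placed in a
#' neighborhood).
#'
#' @param shifts a work-shift data frame ([read_shifts()] dialect).
#' @param weeks optional integer vector of week indices to restrict the
#'   rate computation to (e.g. `1:7` for training-period rates); requires
#'   `start_date`.
#' @param start_date first day of week 1 (needed only with `weeks`).
#' @return A data frame with `participant_id`, `days_wfh`, `days_worked`,
#'   `rate`.
#' @export
telework_profiles <- function(shifts, weeks = NULL, start_date = NULL) {
  if (!is.null(weeks)) {
    if (is.null(start_date)) stopf("weeks filtering requires start_date")
    shifts <- shifts[week_of(shifts$date, start_date) %in% weeks, ,
                     drop = FALSE]
  }
  ids <- sort(unique(shifts$participant_id))
  worked <- !is.na(shifts$absent) & !shifts$absent
  dw <- tapply(worked, shifts$participant_id, sum)
  dh <- tapply(worked & !is.na(shifts$wfh) & shifts$wfh,
               shifts$participant_id, sum)
  out <- data.frame(
    participant_id = ids,
    days_wfh = as.integer(dh[ids]),
    days_worked = as.integer(dw[ids]),
    stringsAsFactors = FALSE
  )
  undef <- out$days_worked == 0L
  if (any(undef)) {
    warnf("teleworking rate undefined for %d participant(s) with no worked days: %s",
          sum(undef), paste(out$participant_id[undef], collapse = ", "))
    out <- out[!undef, , drop = FALSE]
  }
  out$rate <- out$days_wfh / out$days_worked
  rownames(out) <- NULL
  out
}

#' Assign a teleworking level
#'
#' Levels: low (rate < 0.2, more than 4 office days per week on average),
#' middle (0.2 to < 0.6), high (>= 0.6, fewer than 2 office days per week).
#'
#' @param rate numeric vector of teleworking rates in [0, 1].
#' @return Character vector of `"low"`, `"middle"`, `"high"`.
#' @export
#' @examples
#' assign_telework_level(c(0.19, 0.2, 0.59, 0.6))
assign_telework_level <- function(rate) {
  if (any(is.na(rate) | rate < 0 | rate > 1)) {
    stopf("teleworking rates must lie in [0, 1]")
  }
  ifelse(rate < 0.2, "low", ifelse(rate < 0.6, "middle", "high"))
}

#' Extract the neighborhood cluster of a prediction target
#'
#' Selects the `n` participants whose teleworking rates are nearest the
#' target's (absolute difference). When a tie on the boundary distance
#' would make the cluster larger than `n`, the boundary participants are
#' sampled uniformly without replacement under `seed`; with a pool smaller
#' than `n`, all pool members are taken and a warning is raised.
#'
#' @param target_id participant id of the prediction target.
#' @param profiles a profile data frame from [telework_profiles()]
#'   containing the target and the candidate pool.
#' @param n cluster size (default 20).
#' @param seed integer seed for boundary-tie sampling.
#' @return A list with `target_id`, `member_ids`, `distances` (named by
#'   member), `n_requested`, and `tie_broken` (logical).
#' @export
extract_neighborhood <- function(target_id, profiles, n = 20L, seed = 1L) {
  if (!target_id %in% profiles$participant_id) {
    stopf("target %s has no teleworking profile", target_id)
  }
  pool <- profiles[profiles$participant_id != target_id, , drop = FALSE]
  if (nrow(pool) == 0L) stopf("empty candidate pool for target %s", target_id)
  rate_t <- profiles$rate[match(target_id, profiles$participant_id)]
  d <- abs(pool$rate - rate_t)
  names(d) <- pool$participant_id
  if (nrow(pool) <= n) {
    if (nrow(pool) < n) {
      warnf("pool of %d smaller than requested cluster size %d for target %s",
            nrow(pool), n, target_id)
    }
    ord <- order(d, names(d))
    return(list(target_id = target_id, member_ids = names(d)[ord],
                distances = d[ord], n_requested = as.integer(n),
                tie_broken = FALSE))
  }
  ord <- order(d, names(d))
  d_sorted <- d[ord]
  cutoff <- d_sorted[n]
  inner <- names(d_sorted)[d_sorted < cutoff]
  boundary <- names(d_sorted)[d_sorted == cutoff]
  need <- n - length(inner)
  tie_broken <- length(boundary) > need
  chosen_boundary <- if (tie_broken) {
    with_seed(seed, sample(boundary, need))
  } else boundary
  members <- c(inner, sort(chosen_boundary))
  list(target_id = target_id, member_ids = members,
       distances = d[members], n_requested = as.integer(n),
       tie_broken = tie_broken)
}
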