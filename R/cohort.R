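#' Specify a planted stress effect
#'
#' A planted effect adds `coefficient * s(feature)` to the latent stress
#' logit of the following week, where `s` standardizes the shaped feature
#' over the cohort. Effects can be scoped to one teleworking level so the
#' simulated stress process differs between mostly-office and
#' mostly-at-home participants, as the stratified analyses assume.
#'
#' @param feature name of a registry feature of the week before the label.
#' @param level one of `"low"`, `"middle"`, `"high"`, `"all"`: the
#'   teleworking level of participants the effect applies to.
#' @param shape `"linear"` (the standardized feature), `"absolute_deviation"`
#'   (|x - participant mean|, standardized) or `"u_shaped"`
#'   ((x - participant mean)^2, standardized).
#' @param coefficient signed effect size on the logit scale.
#' @return A `planted_effect` list.
#' @export
planted_effect <- function(feature, level = "all",
                           shape = c("linear", "absolute_deviation",
                                     "u_shaped"),
                           coefficient = 1) {
  shape <- match.arg(shape)
  level <- match.arg(level, c("low", "middle", "high", "all"))
  if (!is.finite(coefficient)) stopf("effect coefficient must be finite")
  structure(list(feature = feature, level = level, shape = shape,
                 coefficient = coefficient), class = "planted_effect")
}

#' Default planted effect table
#'
#' Encodes level-specific stress drivers with opposite directions across
#' teleworking levels: longer mean sleep raises stress for low-telework
#' participants but lowers it for high-telework ones, fewer weekly steps
#' raise stress in the middle level, and skipping lunch raises stress only
#' in the high level. Opposite-signed effects on the same feature are what
#' make training-data selection by teleworking rate matter: a model pooled
#' over all levels sees the effects cancel.
#'
#' @return List of [planted_effect()] objects.
#' @export
default_planted_effects <- function() {
  list(
    planted_effect("sleep_duration_mean", "low", "linear", -1.5),
    planted_effect("sleep_duration_mean", "high", "linear", 1.5),
    planted_effect("steps_sum", "middle", "linear", -1.5),
    planted_effect("lunches_skipped", "high", "linear", 1.5)
  )
}

#' Specify a synthetic cohort
#'
#' Holds every knob of the synthetic cohort generator: cohort size, study
#' length, the distribution of per-participant teleworking rates (capped at
#' 0.79 — full-time teleworking is not permitted in the emulated workforce),
#' the target marginal prevalence of stress-positive weeks, the planted
#' effect table, and noise levels.
#'
#' @param n_participants number of participants (default 190).
#' @param n_weeks study weeks, at least 3 (default 12).
#' @param telework_distribution `NULL` for the default level mixture
#'   (43.2\% low, 36.3\% middle, 20.5\% high, uniform within level, max
#'   0.79), a single number for a point mass, a numeric vector of length
#'   `n_participants`, or a `function(n)` returning rates in [0, 0.79].
#' @param positive_prevalence target marginal probability of a
#'   stress-positive week, in (0, 1); the latent-model intercept is solved
#'   numerically to match it.
#' @param effects list of [planted_effect()]s (default
#'   [default_planted_effects()]).
#' @param noise_scale SD of the week-level logit noise (default 1).
#' @param random_intercept_sd SD of the participant random intercept on the
#'   logit scale (default 0.5).
#' @param wearable_missing_prob probability a day's wearable record is
#'   absent (default 0.05); sleep fields are additionally blanked with the
#'   same probability.
#' @param questionnaire_missing_prob probability a weekly questionnaire is
#'   skipped (default 0.02).
#' @param absence_prob probability a scheduled workday is an absence day
#'   (default 0.03).
#' @param seed integer RNG seed; identical specs give identical cohorts.
#' @param start_date first day of week 1; must be a Monday.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_participants = 190L, n_weeks = 12L,
                        telework_distribution = NULL,
                        positive_prevalence = 0.3,
                        effects = default_planted_effects(),
                        noise_scale = 1, random_intercept_sd = 0.5,
                        wearable_missing_prob = 0.05,
                        questionnaire_missing_prob = 0.02,
                        absence_prob = 0.03,
                        seed = 1L,
                        start_date = as.Date("2024-01-01")) {
  if (n_weeks < 3L) stopf("n_weeks must be >= 3 (got %d)", n_weeks)
  if (n_participants < 0L) stopf("n_participants must be >= 0")
  if (!(positive_prevalence > 0 && positive_prevalence < 1)) {
    stopf("positive_prevalence must lie in (0, 1)")
  }
  if (noise_scale < 0) stopf("noise_scale must be non-negative")
  if (as.POSIXlt(start_date)$wday != 1L) {
    stopf("start_date must be a Monday (weeks run Monday-Sunday)")
  }
  for (e in effects) {
    if (!inherits(e, "planted_effect")) {
      stopf("effects must be a list of planted_effect objects")
    }
  }
  structure(list(
    n_participants = as.integer(n_participants),
    n_weeks = as.integer(n_weeks),
    telework_distribution = telework_distribution,
    positive_prevalence = positive_prevalence,
    effects = effects,
    noise_scale = noise_scale,
    random_intercept_sd = random_intercept_sd,
    wearable_missing_prob = wearable_missing_prob,
    questionnaire_missing_prob = questionnaire_missing_prob,
    absence_prob = absence_prob,
    seed = as.integer(seed),
    start_date = start_date
  ), class = "cohort_spec")
}

# Draw per-participant teleworking rates in [0, 0.79].
draw_telework_rates <- function(spec) {
  n <- spec$n_participants
  d <- spec$telework_distribution
  rates <- if (is.null(d)) {
    # Level mixture matching observed workforce shares; uniform within level.
    lv <- sample(c("low", "middle", "high"), n, replace = TRUE,
                 prob = c(0.432, 0.363, 0.205))
    lo <- c(low = 0, middle = 0.2, high = 0.6)[lv]
    hi <- c(low = 0.2, middle = 0.6, high = 0.79)[lv]
    stats::runif(n, lo, hi)
  } else if (is.function(d)) {
    d(n)
  } else if (is.numeric(d) && length(d) == 1L) {
    rep(d, n)
  } else if (is.numeric(d) && length(d) == n) {
    d
  } else {
    stopf("telework_distribution must be NULL, a number, a length-%d vector, or a function(n)", n)
  }
  if (length(rates) != n || any(rates < 0 | rates > 0.79)) {
    stopf("teleworking rates must lie in [0, 0.79]")
  }
  rates
}

# Distribute a K6 total (0-24) over six 0-4 items, uniformly at random.
distribute_k6_items <- function(total) {
  items <- integer(6)
  for (k in seq_len(total)) {
    open <- which(items < 4L)
    pick <- if (length(open) == 1L) open else sample(open, 1L)
    items[pick] <- items[pick] + 1L
  }
  items
}

#' Generate a synthetic cohort
#'
#' Simulates the three raw data streams — daily wearable records, daily
#' work-shift records, weekly questionnaires — for a cohort of teleworking
#' office employees, with stress labels produced by a planted logistic
#' process: the K6 total of week t is driven by a latent logit built from
#' the (standardized, level-scoped) planted-effect features of week t - 1, a
#' participant random intercept, and Gaussian noise. The model intercept is
#' solved numerically so that the marginal stress-positive rate matches
#' `spec$positive_prevalence`. Work-from-home days are allocated so that
#' each participant's empirical teleworking rate equals the assigned rate to
#' within rounding (at most 1 / days worked).
#'
#' The generator is a pure function of the spec: the same spec (including
#' seed) reproduces the cohort exactly.
#'
#' @param spec a [cohort_spec()].
#' @return A `telestress_cohort`: list with data frames `wearable`,
#'   `shifts`, `questionnaires`, `ground_truth` (latent logit, probability
#'   and label per participant-week), `assigned_rates`, and the `spec`.
#' @export
simulate_cohort <- function(spec = cohort_spec()) {
  if (!inherits(spec, "cohort_spec")) stopf("spec must be a cohort_spec")
  with_seed(spec$seed, simulate_cohort_impl(spec))
}

simulate_cohort_impl <- function(spec) {
  n <- spec$n_participants
  nw <- spec$n_weeks
  ids <- sprintf("P%04d", seq_len(n))
  empty <- function(cols) {
    df <- as.data.frame(setNames(rep(list(numeric(0)), length(cols)), cols))
    df
  }
  if (n == 0L) {
    return(structure(list(
      wearable = empty(c("participant_id", "date", wearable_value_cols())),
      shifts = empty(c("participant_id", "date", shift_value_cols())),
      questionnaires = empty(c("participant_id", "week_index",
                               paste0("k6_item", 1:6), "k6_total", "outings",
                               "lunches_skipped")),
      ground_truth = empty(c("participant_id", "week_index", "logit",
                             "probability", "label")),
      assigned_rates = numeric(0),
      spec = spec
    ), class = "telestress_cohort"))
  }

  rates <- draw_telework_rates(spec)
  dates <- spec$start_date + 0:(nw * 7L - 1L)
  dow <- rep(1:7, nw)  # 1 = Monday under a Monday start_date

  # Participant-level baselines (plausible office-worker physiology).
  base <- data.frame(
    id = ids,
    sleep_dur = stats::rnorm(n, 420, 35),
    sleep_eff = stats::rnorm(n, 92, 2),
    sleep_start = stats::rnorm(n, -30, 35),   # signed min from midnight
    hr = stats::rnorm(n, 70, 7),
    hr_sd = pmax(stats::rnorm(n, 8, 1.5), 2),
    log_steps = stats::rnorm(n, log(8000), 0.30),
    cal = stats::rnorm(n, 2100, 180),
    floors = pmax(stats::rnorm(n, 9, 3), 0.5),
    work_start = stats::rnorm(n, 540, 15),    # around 9:00
    lunch_p = stats::rbeta(n, 1.2, 8),
    outings_mu = pmax(stats::rnorm(n, 3, 1), 0.3),
    b = stats::rnorm(n, 0, spec$random_intercept_sd)
  )

  wearable <- vector("list", n)
  shifts <- vector("list", n)
  quest <- vector("list", n)

  for (i in seq_len(n)) {
    nd <- nw * 7L
    sleep_dur <- round(stats::rnorm(nd, base$sleep_dur[i], 45))
    sleep_start <- round(stats::rnorm(nd, base$sleep_start[i], 35))
    sleep_end <- sleep_start + sleep_dur + round(stats::rnorm(nd, 25, 10))
    w <- data.frame(
      participant_id = ids[i], date = dates,
      sleep_duration = sleep_dur,
      sleep_efficiency = round(pmin(pmax(
        stats::rnorm(nd, base$sleep_eff[i], 3), 50), 100)),
      sleep_start = sleep_start,
      sleep_end = sleep_end,
      steps = round(stats::rlnorm(nd, base$log_steps[i], 0.35)),
      stringsAsFactors = FALSE
    )
    w$distance <- round(w$steps * 0.0007 * stats::rnorm(nd, 1, 0.05), 2)
    w$floors <- stats::rpois(nd, base$floors[i])
    w$calories <- round(stats::rnorm(nd, base$cal[i] + 0.03 * w$steps, 120))
    w$hr_mean <- round(stats::rnorm(nd, base$hr[i], 3), 1)
    w$hr_sd <- round(pmax(stats::rnorm(nd, base$hr_sd[i], 1.2), 0.5), 1)
    # Missingness: whole-day device gaps, plus blanked sleep fields.
    keep <- stats::runif(nd) >= spec$wearable_missing_prob
    blank_sleep <- stats::runif(nd) < spec$wearable_missing_prob
    w[blank_sleep, c("sleep_duration", "sleep_efficiency", "sleep_start",
                     "sleep_end")] <- NA
    wearable[[i]] <- w[keep, , drop = FALSE]

    wd <- which(dow <= 5L)                     # Mon-Fri scheduled
    ndw <- length(wd)
    sched_start <- round(base$work_start[i] / 5) * 5
    s <- data.frame(
      participant_id = ids[i], date = dates[wd],
      actual_start = NA_real_, actual_end = NA_real_,
      scheduled_start = sched_start,
      scheduled_end = sched_start + 510,       # 8 h work + 30 min break
      scheduled_hours = 8,
      wfh = FALSE, absent = stats::runif(ndw) < spec$absence_prob,
      stringsAsFactors = FALSE
    )
    worked <- which(!s$absent)
    s$actual_start[worked] <- round(sched_start +
                                      stats::rnorm(length(worked), 0, 15))
    s$actual_end[worked] <- round(s$actual_start[worked] + 510 +
                                    stats::rnorm(length(worked), 10, 45))
    n_wfh <- round(rates[i] * length(worked))
    if (n_wfh > 0L) {
      s$wfh[sample(worked, n_wfh)] <- TRUE
    }
    shifts[[i]] <- s

    quest[[i]] <- data.frame(
      participant_id = ids[i], week_index = seq_len(nw),
      outings = stats::rpois(nw, base$outings_mu[i]),
      lunches_skipped = stats::rbinom(nw, 5, base$lunch_p[i]),
      stringsAsFactors = FALSE
    )
  }

  # Latent stress process on lagged weekly features.
  participants <- lapply(seq_len(n), function(i) {
    q <- quest[[i]]; q$k6_total <- NA_real_
    list(participant_id = ids[i], wearable = wearable[[i]],
         shifts = shifts[[i]], questionnaires = q)
  })
  registry <- default_feature_registry()
  weekly <- build_cohort_features(participants, registry, nw,
                                  spec$start_date)
  levels_i <- assign_telework_level(rates)

  eta <- matrix(0, n, nw)                      # effect + intercept terms
  eta <- eta + base$b
  for (e in spec$effects) {
    if (!e$feature %in% registry$name) {
      stopf("planted effect names unknown feature '%s'", e$feature)
    }
    if (registry$source[match(e$feature, registry$name)] == "k6_total") {
      stopf("planted effects may not use K6-derived features ('%s')",
            e$feature)
    }
    x <- weekly[[e$feature]]
    pid <- weekly$participant_id
    if (e$shape != "linear") {
      pmean <- stats::ave(x, pid, FUN = function(v)
        if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE))
      x <- if (e$shape == "absolute_deviation") abs(x - pmean)
           else (x - pmean)^2
    }
    mu <- mean(x, na.rm = TRUE); sdx <- stats::sd(x, na.rm = TRUE)
    z <- if (is.na(sdx) || sdx == 0) rep(0, length(x)) else (x - mu) / sdx
    z[is.na(z)] <- 0
    zmat <- matrix(z[order(match(pid, ids), weekly$week_index)], n, nw,
                   byrow = TRUE)
    scope <- if (e$level == "all") rep(TRUE, n) else levels_i == e$level
    # Week t label uses the feature of week t - 1.
    contrib <- cbind(0, zmat[, -nw, drop = FALSE]) * e$coefficient
    eta[scope, ] <- eta[scope, , drop = FALSE] +
      contrib[scope, , drop = FALSE]
  }
  eta <- eta + matrix(stats::rnorm(n * nw, 0, spec$noise_scale), n, nw)

  # Intercept solved so the marginal positive rate hits the target.
  f <- function(c0) mean(stats::plogis(c0 + eta)) - spec$positive_prevalence
  intercept <- stats::uniroot(f, c(-30, 30), tol = 1e-10)$root
  prob <- stats::plogis(intercept + eta)
  lab <- matrix(stats::runif(n * nw) < prob, n, nw)

  for (i in seq_len(n)) {
    q <- quest[[i]]
    pos <- lab[i, ]
    p_extra <- 0.08 + 0.2 * prob[i, ]
    tot <- integer(nw)
    tot[!pos] <- stats::rbinom(sum(!pos), 4, 0.25)
    tot[pos] <- 5L + stats::rbinom(sum(pos), 19, p_extra[pos])
    items <- t(vapply(tot, distribute_k6_items, integer(6)))
    colnames(items) <- paste0("k6_item", 1:6)
    q <- cbind(q[, c("participant_id", "week_index")], items,
               k6_total = tot,
               q[, c("outings", "lunches_skipped"), drop = FALSE])
    keep <- stats::runif(nw) >= spec$questionnaire_missing_prob
    quest[[i]] <- q[keep, , drop = FALSE]
  }

  gt <- data.frame(
    participant_id = rep(ids, each = nw),
    week_index = rep(seq_len(nw), n),
    logit = as.vector(t(intercept + eta)),
    probability = as.vector(t(prob)),
    label = as.integer(as.vector(t(lab))),
    stringsAsFactors = FALSE
  )

  structure(list(
    wearable = do.call(rbind, wearable),
    shifts = do.call(rbind, shifts),
    questionnaires = do.call(rbind, quest),
    ground_truth = gt,
    assigned_rates = stats::setNames(rates, ids),
    spec = spec
  ), class = "telestress_cohort")
}

wearable_value_cols <- function() {
  c("sleep_duration", "sleep_efficiency", "sleep_start", "sleep_end",
    "steps", "distance", "floors", "calories", "hr_mean", "hr_sd")
}
shift_value_cols <- function() {
  c("actual_start", "actual_end", "scheduled_start", "scheduled_end",
    "scheduled_hours", "wfh", "absent")
}

#' @export
print.telestress_cohort <- function(x, ...) {
  cat("Synthetic telework cohort\n")
  cat(sprintf("  participants: %d, weeks: %d\n", x$spec$n_participants,
              x$spec$n_weeks))
  cat(sprintf("  wearable days: %d, shift days: %d, questionnaires: %d\n",
              nrow(x$wearable), nrow(x$shifts), nrow(x$questionnaires)))
  if (nrow(x$ground_truth)) {
    cat(sprintf("  stress-positive weeks: %.1f%%\n",
                100 * mean(x$ground_truth$label)))
  }
  invisible(x)
}
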