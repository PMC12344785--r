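# Eligibility, follow-up windows, and person-month expansion.
#
# Time grid: follow-up is partitioned into consecutive 30-day intervals
# from the index date; interval t is the half-open day range
# [30t, 30(t+1)). A full interval contributes 1/12 person-year; the final
# partial interval contributes pro-rata. An event on a boundary day
# belongs to the later interval.

#' Eligibility specification
#'
#' @param age_min,age_max inclusive age bounds at index (defaults 6 and 64).
#' @param washout_months required ADHD-drug-free months before index
#'   (default 18; one month = 30 days).
#' @param subcohort_age_min optional stricter lower age bound (e.g. 15 for
#'   outcomes tied to the minimum age of criminal responsibility/driving).
#' @param enrolment_window optional date range the index date must fall in.
#' @param admin_end_date administrative end of follow-up.
#' @return object of class `eligibility_spec`.
#' @export
eligibility_spec <- function(age_min = 6, age_max = 64,
                             washout_months = 18L,
                             subcohort_age_min = NULL,
                             enrolment_window = NULL,
                             admin_end_date = as.Date("2020-12-31")) {
  if (age_min > age_max) stop_validation("age_min must be <= age_max")
  washout_months <- check_positive_int(washout_months, "washout_months")
  structure(list(age_min = age_min, age_max = age_max,
                 washout_months = washout_months,
                 subcohort_age_min = subcohort_age_min,
                 enrolment_window = enrolment_window,
                 admin_end_date = as.Date(admin_end_date)),
            class = "eligibility_spec")
}

#' Apply eligibility criteria
#'
#' Retains persons with age at index inside the allowed range (using
#' `subcohort_age_min` when set) and no ADHD-drug dispensation during the
#' washout window before the index date. Exclusions are counted per
#' criterion in a fixed application order (age, incident diagnosis,
#' washout) so cohort flowcharts are reproducible.
#'
#' @param persons,dispensations register tables.
#' @param spec an [eligibility_spec()].
#' @return list with `persons` (eligible rows) and `exclusions`
#'   (data.table criterion/excluded counts in application order).
#' @export
apply_eligibility <- function(persons, dispensations,
                              spec = eligibility_spec()) {
  stopifnot(inherits(spec, "eligibility_spec"))
  persons <- data.table::as.data.table(persons)
  check_columns(persons, c("person_id", "age_at_index", "index_date"),
                "persons")
  if (anyNA(persons$index_date)) {
    stop_validation("persons: missing index_date")
  }
  amin <- if (!is.null(spec$subcohort_age_min)) spec$subcohort_age_min
          else spec$age_min
  ok_age <- persons$age_at_index >= amin &
    persons$age_at_index <= spec$age_max
  n_age <- sum(!ok_age)
  cur <- persons[ok_age]
  # incident diagnosis: index date must exist (and fall in the enrolment
  # window when one is set)
  ok_inc <- rep(TRUE, nrow(cur))
  if (!is.null(spec$enrolment_window)) {
    ok_inc <- cur$index_date >= spec$enrolment_window[1] &
      cur$index_date <= spec$enrolment_window[2]
  }
  n_inc <- sum(!ok_inc)
  cur <- cur[ok_inc]
  disp <- data.table::as.data.table(dispensations)
  if (nrow(disp)) {
    disp <- disp[drug_class %in% ADHD_CLASSES]
  }
  if (nrow(disp)) {
    idx <- cur[, .(person_id, index_date)]
    w <- disp[idx, on = "person_id", nomatch = 0L]
    w <- w[date < index_date &
             date >= index_date - 30L * spec$washout_months]
    bad <- unique(w$person_id)
  } else {
    bad <- integer(0)
  }
  n_wash <- sum(cur$person_id %in% bad)
  cur <- cur[!person_id %in% bad]
  exclusions <- data.table::data.table(
    criterion = c("age", "incident_diagnosis", "washout"),
    excluded = c(n_age, n_inc, n_wash)
  )
  list(persons = cur[], exclusions = exclusions)
}

.end_reasons <- c("event", "death", "emigration", "admin_end", "horizon")

# vectorized follow-up windows for all persons; returns data.table
# person_id, start, end, end_day (inclusive day offset), end_reason
followup_windows <- function(persons, events, outcome_type, horizon_months,
                             admin_end_date, stop_at_event = TRUE) {
  horizon_months <- check_positive_int(horizon_months, "horizon_months")
  ot <- outcome_type
  persons <- data.table::as.data.table(persons)
  ev <- data.table::as.data.table(events)
  first_ev <- NULL
  if (stop_at_event && nrow(ev)) {
    ev <- ev[which(ev$outcome_type == ot)]
    if (nrow(ev)) {
      ev <- ev[persons[, .(person_id, index_date)], on = "person_id",
               nomatch = 0L][date >= index_date]
      first_ev <- ev[, .(event_date = min(date)), by = person_id]
    }
  }
  w <- persons[, .(person_id, start = index_date)]
  if (!is.null(first_ev)) {
    w <- first_ev[w, on = "person_id"]
    data.table::setcolorder(w, c("person_id", "start"))
  } else {
    w[, event_date := as.Date(NA)]
  }
  d_event <- as.numeric(w$event_date - w$start)
  d_death <- as.numeric(persons$death_date - w$start)
  d_emig <- as.numeric(persons$emigration_date - w$start)
  d_admin <- as.numeric(as.Date(admin_end_date) - w$start)
  d_hor <- rep(30 * horizon_months - 1, nrow(w))
  repl_inf <- function(x) {
    x[is.na(x)] <- Inf
    x
  }
  d_event <- repl_inf(d_event); d_death <- repl_inf(d_death)
  d_emig <- repl_inf(d_emig); d_admin <- repl_inf(d_admin)
  end_day <- pmin(d_event, d_death, d_emig, d_admin, d_hor)
  # tie precedence: event > death > emigration > admin_end > horizon
  reason <- rep("horizon", nrow(w))
  reason[d_admin == end_day] <- "admin_end"
  reason[d_emig == end_day] <- "emigration"
  reason[d_death == end_day] <- "death"
  reason[d_event == end_day] <- "event"
  data.table::data.table(
    person_id = w$person_id, start = w$start,
    end = w$start + as.integer(end_day),
    end_day = as.integer(end_day),
    end_reason = reason
  )
}

#' Determine one person's follow-up window
#'
#' Follow-up runs from the index date (time zero) until the earliest of:
#' the first outcome event (unless `stop_at_event = FALSE`, as in
#' recurrent-event analyses), death, emigration, the horizon, or the
#' administrative end date. Ties are resolved with precedence
#' event > death > emigration > admin_end > horizon.
#'
#' @param person one-row persons table.
#' @param events events table.
#' @param outcome_type outcome defining the event terminator.
#' @param horizon_months follow-up horizon in 30-day intervals.
#' @param admin_end_date administrative end of registry follow-up.
#' @param stop_at_event disable the event terminator by setting `FALSE`.
#' @return one-row data.table `person_id`, `start`, `end`, `end_day`,
#'   `end_reason`.
#' @export
build_followup_window <- function(person, events, outcome_type,
                                  horizon_months = 24L,
                                  admin_end_date = as.Date("2020-12-31"),
                                  stop_at_event = TRUE) {
  if (nrow(person) != 1L) stop_validation("person must be a single row")
  followup_windows(person, events, outcome_type, horizon_months,
                   admin_end_date, stop_at_event)
}

# per-interval event indicator (n x H, capped at one per interval) and
# the day offset of the earliest event in each interval (NA when none)
event_matrix <- function(persons, events, outcome_type, horizon_months,
                         with_days = FALSE) {
  n <- nrow(persons)
  M <- matrix(0L, n, horizon_months)
  D <- if (with_days) matrix(NA_integer_, n, horizon_months) else NULL
  done <- function() if (with_days) list(ind = M, day = D) else M
  ev <- data.table::as.data.table(events)
  if (!nrow(ev)) return(done())
  mask <- ev$outcome_type == outcome_type
  ev <- ev[which(mask)]
  if (!nrow(ev)) return(done())
  idx <- match(ev$person_id, persons$person_id)
  keep <- !is.na(idx)
  day <- as.integer(ev$date[keep] - persons$index_date[idx[keep]])
  t <- day %/% 30L
  ok <- day >= 0L & t < horizon_months
  M[cbind(idx[keep][ok], t[ok] + 1L)] <- 1L
  if (with_days) {
    dd <- data.table::data.table(i = idx[keep][ok], t = t[ok],
                                 day = day[ok])
    dd <- dd[, .(day = min(day)), by = .(i, t)]
    D[cbind(dd$i, dd$t + 1L)] <- dd$day
  }
  done()
}

# lag-1 time-varying co-medication indicator (n x H): row t uses interval
# t-1 dispensations of other_psychotropic (never information from t itself)
tv_comed_matrix <- function(persons, dispensations, horizon_months) {
  n <- nrow(persons)
  M <- matrix(0L, n, horizon_months)
  disp <- data.table::as.data.table(dispensations)
  if (!nrow(disp)) return(M)
  disp <- disp[drug_class == "other_psychotropic"]
  if (!nrow(disp)) return(M)
  idx <- match(disp$person_id, persons$person_id)
  keep <- !is.na(idx)
  day <- as.integer(disp$date[keep] - persons$index_date[idx[keep]])
  t_meas <- day %/% 30L # floored division: day -23 is interval -1
  t_use <- t_meas + 1L # lagged one interval
  ok <- t_use >= 0L & t_use < horizon_months
  M[cbind(idx[keep][ok], t_use[ok] + 1L)] <- 1L
  M
}

#' Expand one person's follow-up window into person-month rows
#'
#' One row per 30-day interval fully or partially inside the window. The
#' event indicator is 1 when an event of the outcome type falls in the
#' interval (capped at one per interval); the final partial interval
#' contributes person-time pro-rata; time-varying covariates are attached
#' with a one-interval lag.
#'
#' @param person one-row persons table.
#' @param window one-row window from [build_followup_window()].
#' @param events events table.
#' @param outcome_type outcome generating the event indicator.
#' @param covariate_history optional data.table `person_id`, `t`, plus
#'   covariate columns measured in interval `t`; values are attached to
#'   panel row `t + 1`.
#' @return data.table with columns `person_id`, `t`, `pt` (person-years),
#'   `event`, and any lagged covariates.
#' @export
expand_person_months <- function(person, window, events, outcome_type,
                                 covariate_history = NULL) {
  if (nrow(person) != 1L) stop_validation("person must be a single row")
  if (nrow(window) != 1L) {
    stop_validation("overlapping or multiple windows for one person")
  }
  H <- window$end_day %/% 30L + 1L
  days_in <- pmin(30L, window$end_day + 1L - 30L * (0:(H - 1L)))
  M <- event_matrix(person, events, outcome_type, H)
  out <- data.table::data.table(
    person_id = person$person_id,
    t = 0:(H - 1L),
    pt = days_in / 30 / 12,
    event = as.integer(M[1L, ])
  )
  if (!is.null(covariate_history)) {
    ch <- data.table::as.data.table(covariate_history)
    ch <- ch[person_id == person$person_id]
    covs <- setdiff(names(ch), c("person_id", "t"))
    ch[, t := t + 1L] # lag one interval
    out <- ch[out, on = c("person_id", "t")]
    for (cv in covs) data.table::set(out, which(is.na(out[[cv]])), cv, 0)
    data.table::setcolorder(out, c("person_id", "t", "pt", "event"))
  }
  out[]
}
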