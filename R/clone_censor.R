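# Cloning and artificial censoring at protocol deviation.

#' Declarative description of one emulated trial
#'
#' The default variant contrasts the strategy "start drug treatment within
#' the grace period and remain on the initial drug" against "never start
#' during follow-up". The `active_comparator` variant emulates a
#' head-to-head trial of initiating one drug class versus the other, with
#' time zero at the initiation date and deviation defined as
#' discontinuation or class switch.
#'
#' @param outcome_type outcome analysed.
#' @param grace_months grace period in 30-day intervals (default 3;
#'   6 in sensitivity analyses). Initiation in intervals
#'   `0 .. grace_months - 1` is adherent.
#' @param horizon_months follow-up horizon (default 24).
#' @param allow_switching if `TRUE`, switching between drug classes after
#'   the grace period does not censor the initiation clone (sensitivity
#'   analysis); switches during the grace period never censor.
#' @param recurrent recurrent-event analysis: follow-up is not censored at
#'   outcome occurrences and each interval may carry at most one event.
#' @param variant `"initiation"` (default) or `"active_comparator"`.
#' @param eligibility an [eligibility_spec()].
#' @param negative_control marks the run as a negative-outcome-control
#'   analysis (bookkeeping only).
#' @param max_gap_intervals,supply_carryover exposure reconstruction
#'   parameters, see [compute_exposure_intervals()].
#' @return object of class `trial_spec`.
#' @export
trial_spec <- function(outcome_type,
                       grace_months = 3L,
                       horizon_months = 24L,
                       allow_switching = FALSE,
                       recurrent = FALSE,
                       variant = c("initiation", "active_comparator"),
                       eligibility = eligibility_spec(),
                       negative_control = FALSE,
                       max_gap_intervals = 1L,
                       supply_carryover = TRUE) {
  variant <- match.arg(variant)
  grace_months <- check_positive_int(grace_months, "grace_months")
  horizon_months <- check_positive_int(horizon_months, "horizon_months")
  if (grace_months > horizon_months) {
    stop_validation("grace_months must be <= horizon_months")
  }
  structure(list(
    outcome_type = outcome_type, grace_months = grace_months,
    horizon_months = horizon_months, allow_switching = allow_switching,
    recurrent = recurrent, variant = variant, eligibility = eligibility,
    negative_control = negative_control,
    max_gap_intervals = as.integer(max_gap_intervals),
    supply_carryover = supply_carryover
  ), class = "trial_spec")
}

#' @export
print.trial_spec <- function(x, ...) {
  cat(sprintf(
    "<trial_spec> %s: %s, grace %d, horizon %d, %s%s%s\n",
    x$variant, x$outcome_type, x$grace_months, x$horizon_months,
    if (x$recurrent) "recurrent events" else "first event",
    if (x$allow_switching) ", switching allowed" else "",
    if (x$negative_control) ", negative control" else ""))
  invisible(x)
}

get_meta <- function(panel) attr(panel, "ccw_meta")
set_meta <- function(panel, meta) {
  data.table::setattr(panel, "ccw_meta", meta)
  panel
}

# model covariate columns derivable for every person: demographics plus
# any 0/1 baseline column, plus the lagged co-medication indicator
panel_covariates <- function(persons) {
  extra <- setdiff(names(persons), PERSONS_CORE)
  binary <- extra[vapply(extra, function(cn) {
    v <- persons[[cn]]
    is.numeric(v) && all(v %in% c(0, 1))
  }, TRUE)]
  c("male", "young", binary, "tv_comed")
}

# expand all persons into an (uncloned) person-month panel
expand_panel <- function(persons, windows, events, dispensations, spec) {
  H <- spec$horizon_months
  n <- nrow(persons)
  E <- event_matrix(persons, events, spec$outcome_type, H,
                    with_days = TRUE)
  L <- tv_comed_matrix(persons, dispensations, H)
  n_int <- pmin(windows$end_day %/% 30L + 1L, H)
  pid <- rep.int(seq_len(n), n_int)
  t <- sequence(n_int) - 1L
  panel <- data.table::data.table(
    pid = pid,
    person_id = persons$person_id[pid],
    t = t,
    pt = pmin(30L, windows$end_day[pid] + 1L - 30L * t) / 30 / 12,
    event = E$ind[cbind(pid, t + 1L)],
    event_day = E$day[cbind(pid, t + 1L)],
    tv_comed = L[cbind(pid, t + 1L)]
  )
  panel[, male := as.integer(persons$sex[pid] == "male")]
  panel[, young := as.integer(persons$age_at_index[pid] < 25)]
  extra <- setdiff(names(persons), PERSONS_CORE)
  for (cn in extra) {
    data.table::set(panel, j = cn, value = persons[[cn]][panel$pid])
  }
  panel
}

#' Clone a person-month panel into the two strategy arms
#'
#' Every person appears in both arms with identical rows at creation;
#' pre-deviation histories of the two clones are identical by
#' construction.
#'
#' @param panel person-month panel (no `clone_arm` column yet).
#' @return panel doubled, with `clone_arm` in
#'   `{"initiation", "non_initiation"}`.
#' @export
make_clones <- function(panel) {
  if ("clone_arm" %in% names(panel)) {
    stop_validation("panel is already cloned (clone_arm present)")
  }
  meta <- get_meta(panel)
  cloned <- data.table::rbindlist(list(
    data.table::copy(panel)[, clone_arm := "initiation"],
    data.table::copy(panel)[, clone_arm := "non_initiation"]
  ))
  set_meta(cloned, meta)
}

# censoring interval per arm from timeline fields; Inf = never censored
censor_intervals <- function(timelines, spec) {
  init <- timelines$initiation_interval
  disc <- timelines$discontinuation_interval
  swi <- timelines$switch_interval
  grace <- spec$grace_months
  c_init <- rep(Inf, nrow(timelines))
  no_start <- is.na(init) | init > grace - 1L
  c_init[no_start] <- grace
  has_disc <- !no_start & !is.na(disc)
  c_init[has_disc] <- pmax(disc[has_disc], grace)
  if (!spec$allow_switching) {
    # switches during the grace period are non-deviating
    has_swi <- !no_start & !is.na(swi) & swi >= grace
    c_init[has_swi] <- pmin(c_init[has_swi], swi[has_swi])
  }
  c_non <- rep(Inf, nrow(timelines))
  c_non[!is.na(init)] <- init[!is.na(init)]
  # deviation days, for the date comparison against same-interval events:
  # initiation-arm deviations (grace deadline, supply exhaustion, switch)
  # take effect at the start of the censoring interval; the non-initiation
  # deviation is the initiating dispensation itself
  day_non <- if ("initiation_day" %in% names(timelines)) {
    as.numeric(timelines$initiation_day)
  } else {
    30 * as.numeric(init)
  }
  day_non[is.na(day_non)] <- Inf
  data.table::data.table(person_id = timelines$person_id,
                         initiation = c_init, non_initiation = c_non,
                         initiation_day = 30 * c_init,
                         non_initiation_day = day_non)
}

#' Censor clones at protocol deviation
#'
#' Initiation-arm clones are censored at the end of the grace period when
#' treatment was not started within it, at discontinuation (no earlier
#' than the end of grace), and at a post-grace class switch unless
#' `allow_switching`. Non-initiation-arm clones are censored at receipt of
#' any ADHD drug. Rows after the censoring interval are removed; the first
#' censored interval is kept and flagged (`censored = 1`) as the event for
#' the censoring-weight model. Deviation is assessed at the end of the
#' interval, so an event dated in the censoring interval is counted before
#' censoring applies (`in_outcome = 1`).
#'
#' @param panel cloned panel from [make_clones()].
#' @param timelines data.table `person_id`, `initiation_interval`,
#'   `discontinuation_interval`, `switch_interval` (one row per person).
#' @param spec a [trial_spec()].
#' @return censored panel with `censored` and `in_outcome` columns.
#' @export
apply_protocol_censoring <- function(panel, timelines, spec) {
  if (!"clone_arm" %in% names(panel)) {
    stop_validation("panel must be cloned first (no clone_arm column)")
  }
  timelines <- data.table::as.data.table(timelines)
  miss <- setdiff(unique(panel$person_id), timelines$person_id)
  if (length(miss)) {
    stop_validation("timelines missing %d person(s) present in panel",
                    length(miss))
  }
  meta <- get_meta(panel)
  ci <- censor_intervals(timelines, spec)
  idx <- match(panel$person_id, ci$person_id)
  is_init <- panel$clone_arm == "initiation"
  c_arm <- ifelse(is_init, ci$initiation[idx], ci$non_initiation[idx])
  c_day <- ifelse(is_init, ci$initiation_day[idx],
                  ci$non_initiation_day[idx])
  keep <- panel$t <= c_arm
  out <- panel[keep]
  c_arm <- c_arm[keep]
  c_day <- c_day[keep]
  out[, censored := as.integer(t == c_arm)]
  # date comparison in the deviation interval: the event counts when it
  # is dated on or before the deviation (ties favour the event);
  # otherwise it happened after deviation and belongs to neither clone
  at_c <- which(out$censored == 1L & out$event == 1L)
  if (length(at_c)) {
    ev_first <- !is.na(out$event_day[at_c]) &
      out$event_day[at_c] <= c_day[at_c]
    if (!spec$recurrent) {
      # event precedes deviation: the clone exits at the event, never
      # observed censored
      data.table::set(out, at_c[ev_first], "censored", 0L)
    }
    data.table::set(out, at_c[!ev_first], "event", 0L)
    data.table::set(out, at_c[!ev_first], "event_day", NA_integer_)
  }
  out[, in_outcome := as.integer(censored == 0L | event == 1L)]
  set_meta(out, meta)
}

#' Build the censored clone panel from register tables
#'
#' Orchestrates follow-up windows, person-month expansion, exposure
#' reconstruction, cloning, and protocol censoring for one trial
#' specification. Eligibility must already have been applied (see
#' [apply_eligibility()]).
#'
#' @param persons,dispensations,events register tables (eligible persons).
#' @param spec a [trial_spec()].
#' @return censored clone panel (data.table) with metadata attribute used
#'   by the weighting and estimation steps.
#' @export
build_clone_panel <- function(persons, dispensations, events, spec) {
  stopifnot(inherits(spec, "trial_spec"))
  persons <- data.table::as.data.table(persons)
  if (!nrow(persons)) stop_validation("no persons in panel input")
  if (spec$variant == "active_comparator") {
    return(build_comparator_panel(persons, dispensations, events, spec))
  }
  H <- spec$horizon_months
  windows <- followup_windows(persons, events, spec$outcome_type, H,
                              spec$eligibility$admin_end_date,
                              stop_at_event = !spec$recurrent)
  m <- exposure_matrices(persons, dispensations, H,
                         spec$supply_carryover, spec$max_gap_intervals)
  timelines <- data.table::data.table(
    person_id = persons$person_id,
    initiation_interval = m$initiation,
    discontinuation_interval = m$discontinuation,
    switch_interval = m$switch,
    initiation_day = m$initiation_day
  )
  panel <- expand_panel(persons, windows, events, dispensations, spec)
  panel[, treated := as.integer(m$treated[cbind(pid, t + 1L)])]
  covs <- panel_covariates(persons)
  meta <- list(
    grace = spec$grace_months, horizon = H,
    outcome_type = spec$outcome_type, recurrent = spec$recurrent,
    covariates = covs,
    baseline_covariates = setdiff(covs, "tv_comed"),
    arms = c("initiation", "non_initiation"),
    n_persons = nrow(persons),
    timelines = timelines
  )
  set_meta(panel, meta)
  cloned <- make_clones(panel)
  apply_protocol_censoring(cloned, timelines, spec)
}

# head-to-head variant: cohort restricted to initiators within grace,
# time zero moved to the initiation date, arm = initial drug class,
# one copy per person, censoring at discontinuation or switch
build_comparator_panel <- function(persons, dispensations, events, spec) {
  H <- spec$horizon_months
  m <- exposure_matrices(persons, dispensations, H,
                         spec$supply_carryover, spec$max_gap_intervals)
  keep <- !is.na(m$initiation) & m$initiation <= spec$grace_months - 1L
  if (!any(keep)) stop_validation("no initiators for active comparator")
  init <- m$initiation[keep]
  init_cls <- m$cls[cbind(which(keep), init + 1L)]
  persons2 <- data.table::copy(persons[keep])
  persons2[, index_date := index_date + 30L * init]
  windows <- followup_windows(persons2, events, spec$outcome_type, H,
                              spec$eligibility$admin_end_date,
                              stop_at_event = !spec$recurrent)
  m2 <- exposure_matrices(persons2, dispensations, H,
                          spec$supply_carryover, spec$max_gap_intervals)
  panel <- expand_panel(persons2, windows, events, dispensations, spec)
  panel[, treated := as.integer(m2$treated[cbind(pid, t + 1L)])]
  panel[, clone_arm := ADHD_CLASSES[init_cls[pid]]]
  # deviation: first untreated interval, or first switch (always censors)
  c_dev <- pmin(data.table::fifelse(is.na(m2$discontinuation), Inf,
                                    as.numeric(m2$discontinuation)),
                data.table::fifelse(is.na(m2$switch), Inf,
                                    as.numeric(m2$switch)))
  c_arm <- c_dev[panel$pid]
  out <- panel[panel$t <= c_arm]
  c_arm <- c_arm[panel$t <= c_arm]
  out[, censored := as.integer(t == c_arm)]
  at_c <- which(out$censored == 1L & out$event == 1L)
  if (length(at_c)) {
    ev_first <- !is.na(out$event_day[at_c]) &
      out$event_day[at_c] <= 30 * c_arm[at_c]
    if (!spec$recurrent) {
      data.table::set(out, at_c[ev_first], "censored", 0L)
    }
    data.table::set(out, at_c[!ev_first], "event", 0L)
    data.table::set(out, at_c[!ev_first], "event_day", NA_integer_)
  }
  out[, in_outcome := as.integer(censored == 0L | event == 1L)]
  meta <- list(
    grace = spec$grace_months, horizon = H,
    outcome_type = spec$outcome_type, recurrent = spec$recurrent,
    covariates = panel_covariates(persons2),
    arms = ADHD_CLASSES, n_persons = nrow(persons2),
    timelines = NULL
  )
  set_meta(out, meta)
}
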