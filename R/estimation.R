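# Weighted outcome estimation: incidence rate ratios, rates, cumulative
# incidence.

#' Fit the weighted pooled logistic outcome model
#'
#' Regresses the interval event indicator on treatment arm and time
#' (interval dummies by default) by weighted maximum likelihood on the
#' rows contributing outcome information. With small per-interval
#' hazards the arm coefficient approximates the log incidence rate
#' ratio of the first-listed (treatment) arm versus the other.
#'
#' @param panel weighted clone panel (a missing `weight` column means
#'   unit weights).
#' @param time_form `"dummies"` or `"polynomial"`.
#' @param poly_degree degree for the polynomial time form.
#' @return object of class `ccw_estimate` with `irr`, `log_irr`,
#'   per-arm weighted events, person-years and rates per 1000
#'   person-years, and `model_meta`.
#' @export
fit_outcome_model <- function(panel, time_form = c("dummies",
                                                   "polynomial"),
                              poly_degree = 3L) {
  time_form <- match.arg(time_form)
  meta <- get_meta(panel)
  arms <- if (!is.null(meta)) meta$arms else sort(unique(panel$clone_arm))
  if (!all(arms %in% panel$clone_arm)) {
    stop_ccw("empty arm '%s'", setdiff(arms, unique(panel$clone_arm))[1L],
             class = "ccwtrial_estimation_error")
  }
  dt <- data.table::as.data.table(panel)
  if (!"in_outcome" %in% names(dt)) dt[, in_outcome := 1L]
  if (!"weight" %in% names(dt)) dt[, weight := 1]
  dt <- dt[in_outcome == 1L]
  agg <- dt[, .(ev = sum(weight * event), tr = sum(weight)),
            by = .(clone_arm, t)]
  ev_arm <- agg[, .(ev = sum(ev)), by = clone_arm]
  for (a in arms) {
    if (!a %in% ev_arm$clone_arm || ev_arm[clone_arm == a, ev] == 0) {
      stop_ccw("zero events in arm '%s'", a,
               class = "ccwtrial_estimation_error")
    }
  }
  if (time_form == "dummies") {
    ev_t <- agg[, .(ev = sum(ev)), by = t]
    keep_t <- sort(ev_t[ev > 0, t])
    agg <- agg[t %in% keep_t]
    X <- cbind(time_dummies(agg$t, keep_t),
               treat = as.integer(agg$clone_arm == arms[1L]))
  } else {
    ts <- agg$t / max(agg$t, 1)
    X <- cbind(1, stats::poly(ts, degree = poly_degree, raw = TRUE),
               treat = as.integer(agg$clone_arm == arms[1L]))
  }
  fit <- fit_binomial_agg(X, agg$ev, agg$tr)
  log_irr <- fit$coef[length(fit$coef)]
  ev_by <- vapply(arms, function(a) dt[clone_arm == a,
                                       sum(weight * event)], 0)
  py_by <- vapply(arms, function(a) dt[clone_arm == a,
                                       sum(weight * pt)], 0)
  new_ccw_estimate(
    log_irr = log_irr, arms = arms, events = ev_by, py = py_by,
    model_meta = list(time_form = time_form, n_rows = nrow(dt),
                      converged = fit$converged))
}

new_ccw_estimate <- function(log_irr, arms, events, py, model_meta,
                             ci_low = NA_real_, ci_high = NA_real_,
                             se_log_irr = NA_real_, extra = list()) {
  structure(c(list(
    irr = exp(log_irr), log_irr = log_irr,
    ci_low = ci_low, ci_high = ci_high, se_log_irr = se_log_irr,
    arms = arms,
    weighted_events = stats::setNames(events, arms),
    weighted_person_years = stats::setNames(py, arms),
    weighted_rate_per_1000py = stats::setNames(1000 * events / py, arms),
    model_meta = model_meta), extra),
    class = "ccw_estimate")
}

#' @export
print.ccw_estimate <- function(x, ...) {
  ci <- if (!is.na(x$ci_low)) sprintf(" (95%% CI %.3f to %.3f)",
                                      x$ci_low, x$ci_high) else ""
  cat(sprintf("<ccw_estimate> IRR %.3f%s\n", x$irr, ci))
  for (a in x$arms) {
    cat(sprintf(
      "  %s: %.1f weighted events / %.1f person-years = %.1f per 1000 py\n",
      a, x$weighted_events[[a]], x$weighted_person_years[[a]],
      x$weighted_rate_per_1000py[[a]]))
  }
  invisible(x)
}

#' Weighted incidence rate per 1000 person-years
#'
#' `1000 * sum(w * event) / sum(w * person_years)` over the arm's rows
#' contributing outcome information; one full 30-day interval is 1/12
#' person-year, partial final intervals count pro-rata.
#'
#' @param panel (weighted) panel.
#' @param arm clone arm name.
#' @return rate per 1000 person-years.
#' @export
weighted_incidence_rate <- function(panel, arm) {
  dt <- data.table::as.data.table(panel)
  if (!"in_outcome" %in% names(dt)) dt[, in_outcome := 1L]
  if (!"weight" %in% names(dt)) dt[, weight := 1]
  a <- arm
  dt <- dt[in_outcome == 1L & clone_arm == a]
  py <- dt[, sum(weight * pt)]
  if (!is.finite(py) || py <= 0) {
    stop_ccw("zero person-time in arm '%s': rate undefined", a,
             class = "ccwtrial_computation_error")
  }
  1000 * dt[, sum(weight * event)] / py
}

#' Weighted cumulative incidence curve
#'
#' Discrete-time weighted hazard `h_t` (weighted event fraction among
#' at-risk rows at t) turned into `CI(t) = 1 - prod_{k<=t}(1 - h_k)`.
#' First-event panels only.
#'
#' @param panel weighted first-event panel.
#' @param arm clone arm name.
#' @return data.table `t`, `hazard`, `cum_inc` (non-decreasing, in
#'   `[0, 1]`).
#' @export
cumulative_incidence_curve <- function(panel, arm) {
  meta <- get_meta(panel)
  if (!is.null(meta) && isTRUE(meta$recurrent)) {
    stop_validation("cumulative incidence requires a first-event panel")
  }
  dt <- data.table::as.data.table(panel)
  if (!"in_outcome" %in% names(dt)) dt[, in_outcome := 1L]
  if (!"weight" %in% names(dt)) dt[, weight := 1]
  a <- arm
  dt <- dt[in_outcome == 1L & clone_arm == a]
  if (!nrow(dt)) stop_validation("empty arm: %s", a)
  hz <- dt[, .(hazard = sum(weight * event) / sum(weight)), by = t]
  data.table::setorder(hz, t)
  hz[, cum_inc := 1 - cumprod(1 - hazard)]
  hz[]
}

#' Expand persons into a recurrent-event panel
#'
#' Follow-up is not censored at outcome occurrences: a person with
#' events in intervals 2 and 5 contributes an event indicator of 1 in
#' both, and person-time continues to the usual terminators (death,
#' emigration, horizon, administrative end). At most one event per
#' outcome type is counted per interval, so repeated same-month records
#' (e.g. follow-up visits) do not inflate the count.
#'
#' @param persons eligible persons table.
#' @param events events table.
#' @param windows follow-up windows built with `stop_at_event = FALSE`
#'   (an `end_reason` of `"event"` is rejected).
#' @param outcome_type outcome analysed.
#' @return person-month panel (uncloned).
#' @export
prepare_recurrent_panel <- function(persons, events, windows,
                                    outcome_type) {
  windows <- data.table::as.data.table(windows)
  if (any(windows$end_reason == "event")) {
    stop_validation(
      "windows were built with stop_at_event = TRUE; recurrent panels must not end at events")
  }
  persons <- data.table::as.data.table(persons)
  spec <- trial_spec(outcome_type = outcome_type, recurrent = TRUE,
                     horizon_months = max(windows$end_day) %/% 30L + 1L)
  empty_disp <- data.table::data.table(
    person_id = integer(0), date = as.Date(character(0)),
    drug_class = character(0), days_supply = integer(0))
  panel <- expand_panel(persons, windows, events, empty_disp, spec)
  panel[, tv_comed := NULL]
  panel[]
}
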