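# Covariate balance, negative-control harness, and the naive
# (immortal-time-biased) comparison.

#' Standardized mean difference between two weighted samples
#'
#' `(m_a - m_b) / sqrt((v_a + v_b) / 2)` with weighted means and
#' weighted (population-style, `sum(w (x - m)^2) / sum(w)`) variances;
#' the sign convention is group A minus group B. Binary covariates are
#' expected coded 0/1.
#'
#' @param values_a,values_b covariate values per group.
#' @param weights_a,weights_b optional nonnegative weights (default
#'   unit).
#' @return the standardized mean difference (0 when the means are
#'   equal; an error when the pooled variance is zero with unequal
#'   means).
#' @export
standardized_mean_difference <- function(values_a, values_b,
                                         weights_a = NULL,
                                         weights_b = NULL) {
  if (!length(values_a) || !length(values_b)) {
    stop_validation("both groups must be non-empty")
  }
  if (is.null(weights_a)) weights_a <- rep(1, length(values_a))
  if (is.null(weights_b)) weights_b <- rep(1, length(values_b))
  wmean <- function(x, w) sum(w * x) / sum(w)
  wvar <- function(x, w) {
    m <- wmean(x, w)
    sum(w * (x - m)^2) / sum(w)
  }
  m_a <- wmean(values_a, weights_a)
  m_b <- wmean(values_b, weights_b)
  if (isTRUE(all.equal(m_a, m_b, tolerance = 1e-12))) return(0)
  v <- (wvar(values_a, weights_a) + wvar(values_b, weights_b)) / 2
  if (v <= 0) {
    stop_ccw("zero pooled variance with unequal means: SMD undefined",
             class = "ccwtrial_computation_error")
  }
  (m_a - m_b) / sqrt(v)
}

#' Covariate balance table at a given interval
#'
#' Standardized mean differences between the two arms among clones
#' still at risk (uncensored) at `at_interval`, unweighted and weighted
#' by the inverse probability of censoring weights at that interval.
#' The conventional adequacy threshold |SMD| < 0.10 is flagged. By
#' default only time-fixed (baseline) covariates are evaluated: a
#' time-varying covariate measured after time zero can be causally
#' affected by treatment, in which case an arm difference is expected
#' rather than a sign of inadequate weighting.
#'
#' @param panel weighted clone panel.
#' @param covariates covariate columns to evaluate (default: the
#'   panel's baseline modelled set).
#' @param at_interval evaluation interval (default: end of the grace
#'   period).
#' @return data.table of class `ccw_balance_table`: `covariate`,
#'   `smd_unweighted`, `smd_weighted`, `flag_unweighted`,
#'   `flag_weighted`.
#' @export
balance_table <- function(panel, covariates = NULL, at_interval = NULL) {
  meta <- get_meta(panel)
  if (is.null(meta)) stop_validation("panel lacks ccw metadata")
  if (is.null(at_interval)) at_interval <- meta$grace
  if (is.null(covariates)) {
    covariates <- meta$baseline_covariates %||% meta$covariates
  }
  miss <- setdiff(covariates, names(panel))
  if (length(miss)) {
    stop_validation("covariate(s) missing from panel: %s",
                    paste(miss, collapse = ", "))
  }
  ai <- at_interval
  at_risk <- panel[t == ai & censored == 0L]
  arms <- meta$arms
  a_rows <- at_risk[clone_arm == arms[1L]]
  b_rows <- at_risk[clone_arm == arms[2L]]
  if (!nrow(a_rows) || !nrow(b_rows)) {
    stop_validation("no at-risk clones at interval %d in both arms", ai)
  }
  w_a <- if ("weight" %in% names(a_rows)) a_rows$weight
         else rep(1, nrow(a_rows))
  w_b <- if ("weight" %in% names(b_rows)) b_rows$weight
         else rep(1, nrow(b_rows))
  res <- lapply(covariates, function(cv) {
    su <- standardized_mean_difference(a_rows[[cv]], b_rows[[cv]])
    sw <- standardized_mean_difference(a_rows[[cv]], b_rows[[cv]],
                                       w_a, w_b)
    data.table::data.table(covariate = cv, smd_unweighted = su,
                           smd_weighted = sw)
  })
  out <- data.table::rbindlist(res)
  out[, `:=`(flag_unweighted = abs(smd_unweighted) >= 0.10,
             flag_weighted = abs(smd_weighted) >= 0.10)]
  data.table::setattr(out, "at_interval", ai)
  data.table::setattr(out, "class",
                      c("ccw_balance_table", class(out)))
  out[]
}

#' Negative-control-outcome analysis
#'
#' Runs the full clone-censor-weight pipeline on an outcome believed to
#' be unaffected by treatment; an estimate away from the null signals
#' residual confounding or design bias.
#'
#' @param tables register tables list.
#' @param spec a [trial_spec()] whose `outcome_type` is the control
#'   outcome.
#' @param cens_spec a [censoring_model_spec()].
#' @param boot optional [boot_spec()] for a confidence interval; when
#'   `NULL` only the point estimate is computed.
#' @return `ccw_estimate`.
#' @export
run_negative_control <- function(tables, spec,
                                 cens_spec = censoring_model_spec(),
                                 boot = NULL) {
  if (!spec$outcome_type %in% unique(tables$events$outcome_type)) {
    stop_validation("control outcome '%s' absent from events table",
                    spec$outcome_type)
  }
  spec$negative_control <- TRUE
  if (is.null(boot)) {
    estimate_ccw(tables$persons, tables$dispensations, tables$events,
                 spec, cens_spec)
  } else {
    bootstrap_ci(tables, spec, boot, cens_spec)
  }
}

#' Naive ever-initiator versus never comparison (immortal time bias)
#'
#' The flawed analysis the clone-censor-weight design exists to avoid:
#' persons are classified by whether a dispensation is observed within
#' the grace period *during their follow-up* (which ends at the first
#' event), everyone is followed from diagnosis, and an unweighted
#' pooled logistic model of event on group and time is fitted. Because
#' initiators must remain event-free until initiation, their waiting
#' time is immortal and the estimate is biased below 1 under the null.
#'
#' @param persons,dispensations,events register tables (eligible
#'   persons).
#' @param spec a [trial_spec()].
#' @return `ccw_estimate` with arms `ever_initiator` / `never`.
#' @export
naive_initiator_estimate <- function(persons, dispensations, events,
                                     spec) {
  persons <- data.table::as.data.table(persons)
  H <- spec$horizon_months
  windows <- followup_windows(persons, events, spec$outcome_type, H,
                              spec$eligibility$admin_end_date,
                              stop_at_event = TRUE)
  m <- exposure_matrices(persons, dispensations, H,
                         spec$supply_carryover, spec$max_gap_intervals)
  end_int <- windows$end_day %/% 30L
  ever <- !is.na(m$initiation) &
    m$initiation <= spec$grace_months - 1L &
    m$initiation <= end_int
  panel <- expand_panel(persons, windows, events, dispensations, spec)
  panel[, clone_arm := data.table::fifelse(ever[pid], "ever_initiator",
                                           "never")]
  panel[, `:=`(censored = 0L, in_outcome = 1L)]
  meta <- list(grace = spec$grace_months, horizon = H,
               outcome_type = spec$outcome_type, recurrent = FALSE,
               covariates = panel_covariates(persons),
               arms = c("ever_initiator", "never"),
               n_persons = nrow(persons), timelines = NULL)
  set_meta(panel, meta)
  fit_outcome_model(panel)
}
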