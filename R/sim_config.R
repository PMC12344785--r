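#' Default outcome process definitions for the synthetic register
#'
#' One entry per outcome type. Each entry gives the monthly baseline hazard
#' on the probability scale, per-covariate log-rate terms, and the true
#' log incidence rate ratio applied while an individual is on sustained
#' drug treatment. The default primary outcome is calibrated to the upper
#' range of registry outcome rates so that cohorts of a few thousand
#' individuals already carry informative event counts; `t1d_control` is a
#' rare outcome generated independently of treatment and of all
#' confounders, for negative-control analyses.
#'
#' @param true_irr true per-protocol incidence rate ratio under sustained
#'   treatment for the primary outcome (default 0.85).
#' @return named list of outcome model definitions.
#' @export
default_outcome_models <- function(true_irr = 0.85) {
  list(
    substance_misuse = list(
      base_hazard = 0.006,
      log_irr = log(true_irr),
      effects = c(male = 0.15, young = 0.1, comorbidity = 0.5,
                  prior_event = 0.6, tv_comed = 0.8)
    ),
    t1d_control = list(
      base_hazard = 0.002,
      log_irr = 0,
      effects = c()
    )
  )
}

default_baseline_covariates <- function() {
  list(
    comorbidity = list(dist = "bernoulli", p = 0.25),
    prior_event = list(dist = "bernoulli", p = 0.25),
    healthcare_visits = list(dist = "poisson", lambda = 2)
  )
}

#' Configuration of the synthetic register generator
#'
#' Describes the full data-generating process: baseline covariates, a
#' confounded monthly initiation process during the grace period, refill
#' and discontinuation dynamics driven by a binary time-varying confounder,
#' drug-class switching, outcome hazards with a configurable true incidence
#' rate ratio under sustained treatment, and death/emigration censoring.
#'
#' Time runs on consecutive 30-day intervals from each person's index date
#' (one interval = 1/12 person-year). The time-varying confounder
#' `U_t` follows first-order dynamics
#' `P(U_t = 1) = plogis(intercept + persistence * U_{t-1} + treated * T_{t-1})`
#' and is surfaced in the dispensations table as `other_psychotropic`
#' co-medication, so the analysis side observes it the way registry analyses
#' observe psychotropic co-medication. Initiation at month `t` and
#' discontinuation at a refill due in month `t` depend on `U_{t-1}`;
#' the outcome hazard at `t` depends on `U_{t-1}` and on treatment coverage
#' in `t`. All model vectors are named log-odds / log-rate terms with an
#' `intercept` entry plus entries named after model covariates
#' (`male`, `young`, `comorbidity`, `prior_event`, `tv_comed`).
#'
#' @param n_individuals number of individuals to simulate.
#' @param seed master seed; identical config + seed gives byte-identical
#'   tables. Randomness is pre-drawn in a fixed per-person budget so that
#'   increasing `n_individuals` leaves earlier individuals unchanged.
#' @param horizon_months follow-up horizon in 30-day intervals (default 24).
#' @param grace_months grace period length (default 3).
#' @param outcome_models named list per outcome type, see
#'   [default_outcome_models()].
#' @param initiation_model named log-odds vector for monthly initiation
#'   during grace.
#' @param discontinuation_model named log-odds vector for discontinuation
#'   at a refill opportunity.
#' @param switch_prob monthly probability of switching drug class at refill.
#' @param stimulant_prob probability the initial drug class is `stimulant`.
#' @param tv_confounder_model named vector `intercept`, `persistence`,
#'   `treated`, `p_baseline` for the binary time-varying confounder.
#' @param death_emigration_hazard monthly probability of death/emigration.
#' @param baseline_covariate_spec list of distribution specs for extra
#'   baseline covariates (`bernoulli` with `p`, or `poisson` with `lambda`).
#' @param p_male probability of male sex.
#' @param age_shape,age_scale gamma parameters of `age - 6`, truncated at 64.
#' @param education_probs probabilities of the three education levels.
#' @param supply_probs named probabilities over days-supply `{30, 60, 90}`.
#' @param recurrent if `TRUE`, all monthly events are emitted (at most one
#'   per outcome type per interval); if `FALSE`, only each type's first.
#' @param washout_violation_frac fraction of individuals given an ADHD
#'   dispensation inside the washout window (for exercising eligibility).
#' @param underage_frac fraction of individuals with age below 6.
#' @param enrolment_window date range over which index dates are drawn.
#' @param admin_end_date administrative end of registry follow-up.
#' @return object of class `sim_config`.
#' @seealso [simulate_cohort()], [simulate_counterfactual_truth()]
#' @export
sim_config <- function(n_individuals,
                       seed = 1L,
                       horizon_months = 24L,
                       grace_months = 3L,
                       outcome_models = default_outcome_models(),
                       initiation_model = c(intercept = -1.0, male = 0.1,
                                            young = 0.3, comorbidity = -0.5,
                                            prior_event = -0.5,
                                            tv_comed = -0.4),
                       discontinuation_model = c(intercept = -2.8, male = 0,
                                                 young = -0.2,
                                                 comorbidity = 0.4,
                                                 prior_event = 0.3,
                                                 tv_comed = 1.5),
                       switch_prob = 0.03,
                       stimulant_prob = 0.9,
                       tv_confounder_model = c(intercept = -1.6,
                                               persistence = 2.2,
                                               treated = -1.0,
                                               p_baseline = 0.3),
                       death_emigration_hazard = 0.001,
                       baseline_covariate_spec = default_baseline_covariates(),
                       p_male = 0.587,
                       age_shape = 1.5,
                       age_scale = 11,
                       education_probs = c(primary = 0.17, secondary = 0.51,
                                           post_secondary = 0.32),
                       supply_probs = c("30" = 0.7, "60" = 0.2, "90" = 0.1),
                       recurrent = FALSE,
                       washout_violation_frac = 0,
                       underage_frac = 0,
                       enrolment_window = as.Date(c("2007-01-01",
                                                    "2018-12-31")),
                       admin_end_date = as.Date("2020-12-31")) {
  n_individuals <- check_positive_int(n_individuals, "n_individuals")
  horizon_months <- check_positive_int(horizon_months, "horizon_months")
  grace_months <- check_positive_int(grace_months, "grace_months")
  if (horizon_months < grace_months) {
    stop_validation("horizon_months must be >= grace_months")
  }
  check_prob(switch_prob, "switch_prob")
  check_prob(stimulant_prob, "stimulant_prob")
  check_prob(death_emigration_hazard, "death_emigration_hazard")
  check_prob(p_male, "p_male")
  check_prob(tv_confounder_model[["p_baseline"]],
             "tv_confounder_model['p_baseline']")
  check_prob(washout_violation_frac, "washout_violation_frac")
  check_prob(underage_frac, "underage_frac")
  if (abs(sum(supply_probs) - 1) > 1e-8) {
    stop_validation("supply_probs must sum to 1")
  }
  if (abs(sum(education_probs) - 1) > 1e-8) {
    stop_validation("education_probs must sum to 1")
  }
  for (nm in names(outcome_models)) {
    om <- outcome_models[[nm]]
    check_prob(om$base_hazard, sprintf("outcome_models$%s$base_hazard", nm))
    if (!is.numeric(om$log_irr) || !is.finite(om$log_irr)) {
      stop_validation("outcome_models$%s$log_irr must be finite", nm)
    }
  }
  structure(list(
    n_individuals = n_individuals, seed = as.integer(seed),
    horizon_months = horizon_months, grace_months = grace_months,
    outcome_models = outcome_models,
    initiation_model = initiation_model,
    discontinuation_model = discontinuation_model,
    switch_prob = switch_prob, stimulant_prob = stimulant_prob,
    tv_confounder_model = tv_confounder_model,
    death_emigration_hazard = death_emigration_hazard,
    baseline_covariate_spec = baseline_covariate_spec,
    p_male = p_male, age_shape = age_shape, age_scale = age_scale,
    education_probs = education_probs, supply_probs = supply_probs,
    recurrent = recurrent,
    washout_violation_frac = washout_violation_frac,
    underage_frac = underage_frac,
    enrolment_window = enrolment_window,
    admin_end_date = admin_end_date
  ), class = "sim_config")
}

#' Canned simulation scenarios
#'
#' `"effect"` is the default confounded data-generating process with a true
#' sustained-treatment incidence rate ratio of 0.85 on the primary outcome
#' and a time-varying confounder affected by past treatment. `"null"` is a
#' sharp null: the treatment coefficient in every outcome model and in the
#' confounder dynamics is zero, so treatment has no causal pathway to the
#' outcome, while initiation and discontinuation remain confounded.
#'
#' @param scenario `"effect"` or `"null"`.
#' @param n_individuals,seed passed to [sim_config()].
#' @param ... further overrides passed to [sim_config()].
#' @return a `sim_config`.
#' @export
sim_scenario <- function(scenario = c("effect", "null"), n_individuals,
                         seed = 1L, ...) {
  scenario <- match.arg(scenario)
  if (scenario == "effect") {
    sim_config(n_individuals = n_individuals, seed = seed, ...)
  } else {
    sim_config(
      n_individuals = n_individuals, seed = seed,
      outcome_models = default_outcome_models(true_irr = 1),
      tv_confounder_model = c(intercept = -1.6, persistence = 2.2,
                              treated = 0, p_baseline = 0.3),
      ...
    )
  }
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  n = %d, seed = %d, horizon = %d months, grace = %d months\n",
              x$n_individuals, x$seed, x$horizon_months, x$grace_months))
  cat(sprintf("  outcomes: %s\n", paste(names(x$outcome_models),
                                        collapse = ", ")))
  cat(sprintf("  recurrent = %s\n", x$recurrent))
  invisible(x)
}
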