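# Shared fixtures: small handcrafted register tables and panels, plus a
# cached medium simulation reused across module tests.

D0 <- as.Date("2015-01-01")

# persons table with the columns the cohort machinery expects
hand_persons <- function(n = 1, age = 30, sex = "male",
                         index_date = D0, death_date = as.Date(NA),
                         emigration_date = as.Date(NA),
                         comorbidity = 0L, prior_event = 0L) {
  data.table::data.table(
    person_id = seq_len(n), sex = sex, age_at_index = age,
    index_date = index_date, education_level = "secondary",
    death_date = death_date, emigration_date = emigration_date,
    comorbidity = comorbidity, prior_event = prior_event
  )
}

hand_disp <- function(person_id = integer(0), day = integer(0),
                      drug_class = character(0),
                      days_supply = integer(0), index_date = D0) {
  data.table::data.table(
    person_id = person_id, date = index_date + day,
    drug_class = drug_class, days_supply = days_supply
  )
}

hand_events <- function(person_id = integer(0), day = integer(0),
                        outcome_type = character(0), index_date = D0) {
  data.table::data.table(
    person_id = person_id, date = index_date + day,
    outcome_type = outcome_type
  )
}

# minimal clone panel with metadata, for function-level weight and
# estimation tests (bypasses the register machinery)
hand_panel <- function(df, grace = 3L, horizon = 24L,
                       arms = c("initiation", "non_initiation"),
                       covariates = character(0), recurrent = FALSE) {
  dt <- data.table::as.data.table(df)
  if (!"pid" %in% names(dt)) dt[, pid := person_id]
  if (!"pt" %in% names(dt)) dt[, pt := 1 / 12]
  if (!"censored" %in% names(dt)) dt[, censored := 0L]
  if (!"in_outcome" %in% names(dt)) {
    dt[, in_outcome := as.integer(censored == 0L | event == 1L)]
  }
  meta <- list(grace = grace, horizon = horizon,
               outcome_type = "synthetic", recurrent = recurrent,
               covariates = covariates, baseline_covariates = covariates,
               arms = arms, n_persons = length(unique(dt$pid)),
               timelines = NULL)
  ccwtrial:::set_meta(dt, meta)
  dt
}

# one medium simulated register shared across tests (cheap, cached)
shared_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(1500, seed = 42)
      cache <<- list(config = cfg, tables = simulate_cohort(cfg))
    }
    cache
  }
})
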