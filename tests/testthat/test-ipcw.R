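# Censoring models and inverse probability of censoring weights.

# panel with one clone per person in one arm, explicit censoring pattern
one_arm_panel <- function(n_person, n_t, censored_at = rep(NA, n_person),
                          x = rep(0L, n_person), arm = "non_initiation") {
  rows <- lapply(seq_len(n_person), function(i) {
    tmax <- if (is.na(censored_at[i])) n_t - 1L else censored_at[i]
    data.table::data.table(
      person_id = i, pid = i, t = 0:tmax, event = 0L,
      clone_arm = arm,
      censored = as.integer(0:tmax == censored_at[i] &
                              !is.na(censored_at[i])),
      x = x[i])
  })
  hand_panel(data.table::rbindlist(rows), covariates = "x",
             arms = c("initiation", "non_initiation"))
}

test_that("an arm with zero censoring events gets probability one everywhere", {
  panel <- one_arm_panel(5, 4)
  fit <- fit_censoring_model(panel,
                             censoring_model_spec(arm = "non_initiation"))
  expect_true(all(fit$p_uncensored == 1))
  panel <- compute_ipc_weights(panel, fit)
  expect_true(all(panel$weight == 1))
})

test_that("the saturated fit reproduces empirical uncensored fractions per stratum", {
  # t = 0: x = 1 persons censored 2 of 4; x = 0 persons censored 1 of 4
  cens <- c(0, 0, NA, NA, 0, NA, NA, NA)
  x <- c(1L, 1L, 1L, 1L, 0L, 0L, 0L, 0L)
  panel <- one_arm_panel(8, 3, censored_at = cens, x = x)
  fit <- fit_censoring_model(panel,
                             censoring_model_spec(arm = "non_initiation"))
  p0 <- fit$p_uncensored[panel[clone_arm == "non_initiation", t] == 0]
  expect_equal(sort(unique(round(p0, 6))), c(0.5, 0.75))
  expect_equal(p0[x == 1L], rep(0.5, 4), tolerance = 1e-6)
  expect_equal(p0[x == 0L], rep(0.75, 4), tolerance = 1e-6)
})

test_that("missing covariates are a validation error", {
  panel <- one_arm_panel(3, 3)
  expect_error(
    fit_censoring_model(panel, censoring_model_spec(
      arm = "non_initiation", covariates = "not_there")),
    class = "ccwtrial_validation_error")
  expect_error(
    fit_censoring_model(panel, censoring_model_spec(arm = "initiation")),
    class = "ccwtrial_validation_error")
})

test_that("weights are cumulative products of inverse probabilities", {
  panel <- one_arm_panel(1, 4)
  fit <- structure(list(arm = "non_initiation", rows = 1:4,
                        p_uncensored = c(1, 0.5, 0.5, 0.5),
                        coefs = NULL, spec = NULL),
                   class = "ccw_censor_fit")
  panel <- compute_ipc_weights(panel, fit)
  expect_equal(panel$weight, c(1, 2, 4, 8))
  expect_error(
    compute_ipc_weights(panel, structure(
      list(arm = "a", rows = 1:4, p_uncensored = c(1, 0, 0.5, 0.5)),
      class = "ccw_censor_fit")),
    class = "ccwtrial_computation_error")
})

test_that("unstabilized weights are at least one and non-decreasing within a clone", {
  tabs <- shared_sim()$tables
  spec <- trial_spec("substance_misuse")
  res <- estimate_ccw(tabs$persons, tabs$dispensations, tabs$events,
                      spec, censoring_model_spec(
                        truncation_percentile = 100),
                      return_panel = TRUE)
  panel <- res$panel
  expect_true(all(panel$weight >= 1 - 1e-12))
  mono <- panel[, .(ok = !is.unsorted(weight)), by = .(pid, clone_arm)]
  expect_true(all(mono$ok))
})

test_that("stabilized weights average about one per interval", {
  tabs <- shared_sim()$tables
  spec <- trial_spec("substance_misuse")
  persons <- apply_eligibility(tabs$persons, tabs$dispensations,
                               spec$eligibility)$persons
  panel <- build_clone_panel(persons, tabs$dispensations, tabs$events,
                             spec)
  fits <- lapply(c("initiation", "non_initiation"), function(a) {
    fit_censoring_model(panel, censoring_model_spec(arm = a))
  })
  panel <- compute_ipc_weights(panel, fits, stabilized = TRUE)
  mw <- panel[censored == 0L & t <= 12L,
              .(m = mean(weight)), by = .(clone_arm, t)]
  expect_true(all(mw$m > 0.8 & mw$m < 1.25))
})

test_that("truncation threshold follows the type-7 percentile and never raises weights", {
  w <- c(rep(1, 999), 100)
  panel <- one_arm_panel(1000, 1)
  panel[, weight := w]
  out <- truncate_weights(panel, 99.5)
  thr_oracle <- unname(quantile(w, 0.995, type = 7))
  expect_equal(out$diagnostics$per_arm$non_initiation$threshold,
               thr_oracle)
  expect_lt(max(out$panel$weight), 100)
  expect_true(all(out$panel$weight <= w))
  # all-equal weights and percentile 100 are no-ops
  panel2 <- one_arm_panel(10, 2)
  panel2[, weight := 2]
  expect_true(all(truncate_weights(panel2, 99.5)$panel$weight == 2))
  panel3 <- one_arm_panel(10, 2)
  panel3[, weight := runif(nrow(panel3), 1, 5)]
  w3 <- data.table::copy(panel3)$weight
  expect_equal(truncate_weights(panel3, 100)$panel$weight, w3)
  expect_error(truncate_weights(panel3, 40),
               class = "ccwtrial_validation_error")
})

test_that("effective sample size diagnostics never exceed raw counts", {
  tabs <- shared_sim()$tables
  spec <- trial_spec("substance_misuse")
  res <- estimate_ccw(tabs$persons, tabs$dispensations, tabs$events,
                      spec, return_panel = TRUE)
  out <- truncate_weights(res$panel, 99.5)
  ess <- out$diagnostics$ess_per_interval
  expect_true(all(ess$ess <= ess$n + 1e-9))
  expect_true(all(ess$ess > 0))
})

test_that("without censoring the weighted estimate equals the unweighted one exactly", {
  set.seed(31)
  rows <- data.table::CJ(person_id = 1:200, t = 0:5)
  rows[, `:=`(pid = person_id, event = rbinom(.N, 1, 0.05),
              censored = 0L,
              clone_arm = rep(c("initiation", "non_initiation"),
                              length.out = .N))]
  panel <- hand_panel(rows)
  fits <- lapply(c("initiation", "non_initiation"), function(a) {
    fit_censoring_model(panel, censoring_model_spec(
      arm = a, covariates = character(0)))
  })
  weighted <- compute_ipc_weights(data.table::copy(panel), fits)
  est_w <- fit_outcome_model(weighted)
  est_u <- fit_outcome_model(panel)
  expect_identical(est_w$log_irr, est_u$log_irr)
})
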