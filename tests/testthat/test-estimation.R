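# Outcome models, rates, cumulative incidence, recurrent panels.

two_by_two_panel <- function(ev_a = 10L, n_a = 100L, ev_b = 5L,
                             n_b = 100L) {
  rows <- data.table::data.table(
    person_id = 1:(n_a + n_b),
    t = 0L,
    event = c(rep(1L, ev_a), rep(0L, n_a - ev_a),
              rep(1L, ev_b), rep(0L, n_b - ev_b)),
    clone_arm = c(rep("initiation", n_a), rep("non_initiation", n_b))
  )
  hand_panel(rows)
}

test_that("the saturated single-stratum fit equals the closed-form odds ratio", {
  panel <- two_by_two_panel()
  est <- fit_outcome_model(panel)
  oracle <- (10 / 90) / (5 / 95)
  expect_equal(est$irr, oracle, tolerance = 1e-6)
  expect_equal(est$log_irr, log(oracle), tolerance = 1e-6)
})

test_that("exchangeable arms give an incidence rate ratio of one", {
  panel <- two_by_two_panel(ev_a = 7L, ev_b = 7L)
  est <- fit_outcome_model(panel)
  expect_equal(est$irr, 1, tolerance = 1e-8)
})

test_that("rescaling all weights leaves the estimate unchanged", {
  panel <- two_by_two_panel()
  est1 <- fit_outcome_model(panel)
  panel[, weight := 2]
  est2 <- fit_outcome_model(panel)
  expect_equal(est1$log_irr, est2$log_irr, tolerance = 1e-10)
})

test_that("zero events in an arm is an estimation error naming the arm", {
  panel <- two_by_two_panel(ev_b = 0L)
  expect_error(fit_outcome_model(panel), "non_initiation",
               class = "ccwtrial_estimation_error")
})

test_that("weighted incidence rates follow the person-time formula", {
  # 5 events over 100 unit-weight person-months
  rows <- data.table::data.table(
    person_id = rep(1:10, each = 10), t = rep(0:9, 10),
    event = c(rep(1L, 5), rep(0L, 95)),
    clone_arm = "initiation")
  panel <- hand_panel(rows)
  expect_equal(weighted_incidence_rate(panel, "initiation"),
               5 / (100 / 12) * 1000, tolerance = 1e-12)
  panel[, weight := 3]
  expect_equal(weighted_incidence_rate(panel, "initiation"), 600,
               tolerance = 1e-12)
  panel[, event := 0L]
  expect_equal(weighted_incidence_rate(panel, "initiation"), 0)
  panel[, pt := 0]
  expect_error(weighted_incidence_rate(panel, "initiation"),
               class = "ccwtrial_computation_error")
})

test_that("cumulative incidence matches the closed-form product", {
  h <- 0.01
  rows <- data.table::rbindlist(lapply(0:23, function(tt) {
    data.table::data.table(person_id = c(1L, 2L), t = tt,
                           event = c(1L, 0L), clone_arm = "initiation",
                           weight = c(h, 1 - h))
  }))
  panel <- hand_panel(rows)
  cc <- cumulative_incidence_curve(panel, "initiation")
  expect_equal(cc$hazard, rep(h, 24), tolerance = 1e-12)
  expect_equal(cc$cum_inc[24], 1 - 0.99^24, tolerance = 1e-12)
  expect_true(all(diff(cc$cum_inc) >= 0))
  expect_true(all(cc$cum_inc >= 0 & cc$cum_inc <= 1))
})

test_that("degenerate hazards give degenerate cumulative incidence", {
  rows <- data.table::data.table(person_id = 1L, t = 0:3, event = 0L,
                                 clone_arm = "initiation")
  panel <- hand_panel(rows)
  expect_true(all(cumulative_incidence_curve(panel,
                                             "initiation")$cum_inc == 0))
  rows2 <- data.table::data.table(person_id = 1L, t = 0L, event = 1L,
                                  clone_arm = "initiation")
  panel2 <- hand_panel(rows2)
  expect_equal(cumulative_incidence_curve(panel2,
                                          "initiation")$cum_inc, 1)
})

test_that("cumulative incidence rejects recurrent panels", {
  rows <- data.table::data.table(person_id = 1L, t = 0:3, event = 0L,
                                 clone_arm = "initiation")
  panel <- hand_panel(rows, recurrent = TRUE)
  expect_error(cumulative_incidence_curve(panel, "initiation"),
               class = "ccwtrial_validation_error")
})

test_that("recurrent panels keep full person-time and cap events per interval", {
  p <- hand_persons(1)
  ev <- hand_events(rep(1L, 2), c(2L * 30L + 14L, 5L * 30L + 14L),
                    "substance_misuse")
  w <- build_followup_window(p, ev, "substance_misuse",
                             stop_at_event = FALSE)
  panel <- prepare_recurrent_panel(p, ev, w, "substance_misuse")
  expect_equal(nrow(panel), 24L)
  expect_equal(sum(panel$event), 2L)
  expect_equal(panel[event == 1L, t], c(2L, 5L))

  ev3 <- hand_events(rep(1L, 3), c(125L, 128L, 133L),
                     "substance_misuse")
  w3 <- build_followup_window(p, ev3, "substance_misuse",
                              stop_at_event = FALSE)
  panel3 <- prepare_recurrent_panel(p, ev3, w3, "substance_misuse")
  expect_equal(sum(panel3$event), 1L)
  expect_equal(panel3[event == 1L, t], 4L)
})

test_that("recurrent panels refuse windows that stop at events", {
  p <- hand_persons(1)
  ev <- hand_events(1L, 44L, "substance_misuse")
  w <- build_followup_window(p, ev, "substance_misuse")
  expect_error(prepare_recurrent_panel(p, ev, w, "substance_misuse"),
               class = "ccwtrial_validation_error")
})

test_that("no events leaves the recurrent panel identical to the first-event rows", {
  p <- hand_persons(1)
  w <- build_followup_window(p, hand_events(), "substance_misuse",
                             stop_at_event = FALSE)
  panel <- prepare_recurrent_panel(p, hand_events(), w,
                                   "substance_misuse")
  w1 <- build_followup_window(p, hand_events(), "substance_misuse")
  panel1 <- expand_person_months(p, w1, hand_events(),
                                 "substance_misuse")
  expect_equal(panel[, .(person_id, t, pt, event)],
               panel1[, .(person_id, t, pt, event)])
})

test_that("recurrent-event weighted rates are at least first-event rates", {
  # strong between-person heterogeneity makes the frailty selection that
  # drives this inequality unambiguous at moderate n
  cfg <- sim_config(
    2000, seed = 23, recurrent = TRUE,
    outcome_models = list(substance_misuse = list(
      base_hazard = 0.008, log_irr = log(0.85),
      effects = c(prior_event = 2, tv_comed = 0.5))))
  tabs <- simulate_cohort(cfg)
  ev_first <- tabs$events[order(person_id, date),
                          .SD[1L], by = .(person_id, outcome_type)]
  spec_f <- trial_spec("substance_misuse")
  spec_r <- trial_spec("substance_misuse", recurrent = TRUE)
  persons <- apply_eligibility(tabs$persons, tabs$dispensations,
                               spec_f$eligibility)$persons
  p_f <- build_clone_panel(persons, tabs$dispensations, ev_first,
                           spec_f)
  p_r <- build_clone_panel(persons, tabs$dispensations, tabs$events,
                           spec_r)
  for (a in c("initiation", "non_initiation")) {
    expect_gte(weighted_incidence_rate(p_r, a),
               weighted_incidence_rate(p_f, a) * 0.999)
  }
})
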