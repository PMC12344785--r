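# Eligibility, follow-up windows, and person-month expansion.

test_that("eligibility applies age, washout, and ordering of exclusions", {
  persons <- hand_persons(4)
  persons$age_at_index <- c(5, 30, 30, 70)
  # person 3: ADHD dispensation 12 months (360 days) before index
  disp <- hand_disp(person_id = 3L, day = -360L,
                    drug_class = "stimulant", days_supply = 30L)
  out <- apply_eligibility(persons, disp, eligibility_spec())
  expect_equal(out$persons$person_id, 2L)
  expect_equal(out$exclusions$criterion,
               c("age", "incident_diagnosis", "washout"))
  expect_equal(out$exclusions$excluded, c(2L, 0L, 1L))
})

test_that("a dispensation just outside the washout window is allowed", {
  persons <- hand_persons(1)
  disp <- hand_disp(1L, day = -(18L * 30L + 1L), drug_class = "stimulant",
                    days_supply = 30L)
  out <- apply_eligibility(persons, disp, eligibility_spec())
  expect_equal(nrow(out$persons), 1L)
  # co-medication never counts toward the washout
  disp2 <- hand_disp(1L, day = -100L, drug_class = "other_psychotropic",
                     days_supply = 30L)
  expect_equal(nrow(apply_eligibility(persons, disp2)$persons), 1L)
})

test_that("missing index date is a validation error", {
  persons <- hand_persons(1, index_date = as.Date(NA))
  expect_error(apply_eligibility(persons, hand_disp()),
               class = "ccwtrial_validation_error")
})

test_that("subcohort age bound overrides the lower age limit", {
  persons <- hand_persons(2)
  persons$age_at_index <- c(10, 20)
  out <- apply_eligibility(persons, hand_disp(),
                           eligibility_spec(subcohort_age_min = 15))
  expect_equal(out$persons$person_id, 2L)
})

test_that("follow-up windows pick the earliest terminator with the right reason", {
  p <- hand_persons(1)
  w <- build_followup_window(p, hand_events(), "substance_misuse")
  expect_equal(w$end_reason, "horizon")
  expect_equal(w$end_day, 30L * 24L - 1L)

  ev <- hand_events(1L, day = 5L * 30L + 14L, "substance_misuse")
  w2 <- build_followup_window(p, ev, "substance_misuse")
  expect_equal(w2$end_reason, "event")
  expect_equal(w2$end_day, 164L)

  w3 <- build_followup_window(p, ev, "substance_misuse",
                              stop_at_event = FALSE)
  expect_equal(w3$end_reason, "horizon")

  p_dead <- hand_persons(1, death_date = D0 + 100L)
  w4 <- build_followup_window(p_dead, ev, "substance_misuse")
  expect_equal(w4$end_reason, "death")
  expect_equal(w4$end_day, 100L)

  w5 <- build_followup_window(p, ev, "substance_misuse",
                              admin_end_date = D0 + 50L)
  expect_equal(w5$end_reason, "admin_end")
})

test_that("events of other outcome types never terminate follow-up", {
  p <- hand_persons(1)
  ev <- hand_events(1L, day = 40L, "t1d_control")
  w <- build_followup_window(p, ev, "substance_misuse")
  expect_equal(w$end_reason, "horizon")
})

test_that("expansion yields one row per interval with pro-rata person-time", {
  p <- hand_persons(1)
  w <- build_followup_window(p, hand_events(), "substance_misuse")
  panel <- expand_person_months(p, w, hand_events(), "substance_misuse")
  expect_equal(nrow(panel), 24L)
  expect_equal(sum(panel$pt), 2, tolerance = 1e-12)
  expect_true(all(panel$event == 0L))
})

test_that("a window ending mid-interval 7 at an event gives 8 rows with the event last", {
  p <- hand_persons(1)
  ev <- hand_events(1L, day = 7L * 30L + 14L, "substance_misuse")
  w <- build_followup_window(p, ev, "substance_misuse")
  panel <- expand_person_months(p, w, ev, "substance_misuse")
  expect_equal(nrow(panel), 8L)
  expect_equal(panel$event, c(rep(0L, 7L), 1L))
  # event on day 14 of the interval: 15 of 30 days contribute
  expect_equal(panel$pt[8L], 15 / 30 / 12, tolerance = 1e-12)
  # first-event mode: the single event sits in the final row
  expect_equal(which(panel$event == 1L), nrow(panel))
})

test_that("an event on an interval boundary belongs to the later interval", {
  p <- hand_persons(1)
  ev <- hand_events(1L, day = 60L, "substance_misuse")
  w <- build_followup_window(p, ev, "substance_misuse")
  panel <- expand_person_months(p, w, ev, "substance_misuse")
  expect_equal(which(panel$event == 1L) - 1L, 2L) # interval t = 2
})

test_that("covariate history attaches with a one-interval lag and no look-ahead", {
  p <- hand_persons(1)
  w <- build_followup_window(p, hand_events(), "substance_misuse")
  hist <- data.table::data.table(person_id = 1L, t = c(0L, 3L),
                                 flag = c(1, 1))
  panel <- expand_person_months(p, w, hand_events(), "substance_misuse",
                                covariate_history = hist)
  expect_equal(panel$flag[panel$t == 1L], 1)
  expect_equal(panel$flag[panel$t == 0L], 0) # nothing from t or later
  expect_equal(panel$flag[panel$t == 4L], 1)
  expect_equal(panel$flag[panel$t == 3L], 0)
})

test_that("panel person-time equals window length to pro-rata precision", {
  tabs <- shared_sim()$tables
  spec <- trial_spec("substance_misuse")
  persons <- apply_eligibility(tabs$persons, tabs$dispensations,
                               spec$eligibility)$persons
  w <- ccwtrial:::followup_windows(persons, tabs$events,
                                   "substance_misuse", 24L,
                                   as.Date("2020-12-31"))
  panel <- ccwtrial:::expand_panel(persons, w, tabs$events,
                                   tabs$dispensations, spec)
  pt_by_person <- panel[, .(pt = sum(pt)), by = pid]
  expect_equal(pt_by_person$pt, (w$end_day + 1) / 360,
               tolerance = 1e-12)
})
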