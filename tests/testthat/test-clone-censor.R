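# Cloning and protocol censoring.

build_small_panel <- function(tabs, spec = trial_spec("substance_misuse")) {
  persons <- apply_eligibility(tabs$persons, tabs$dispensations,
                               spec$eligibility)$persons
  build_clone_panel(persons, tabs$dispensations, tabs$events, spec)
}

test_that("every person appears as a clone in both arms", {
  tabs <- shared_sim()$tables
  panel <- build_small_panel(tabs)
  clones <- unique(panel[, .(person_id, clone_arm)])
  expect_equal(nrow(clones), 2L * length(unique(panel$person_id)))
  # pre-deviation rows of the two clones are identical
  shared <- panel[, .N, by = .(person_id, t)][N == 2L]
  a <- panel[clone_arm == "initiation"][shared, on = c("person_id", "t")]
  b <- panel[clone_arm == "non_initiation"][shared,
                                            on = c("person_id", "t")]
  cols <- c("t", "pt", "event", "tv_comed", "male", "comorbidity")
  expect_equal(as.data.frame(a[censored == 0 & b$censored == 0,
                               ..cols]),
               as.data.frame(b[censored == 0 & a$censored == 0, ..cols]))
})

test_that("cloning an already cloned panel is an error", {
  tabs <- shared_sim()$tables
  panel <- build_small_panel(tabs)
  expect_error(make_clones(panel), class = "ccwtrial_validation_error")
})

test_that("a person dying during grace without initiating stays in both arms", {
  p <- hand_persons(1, death_date = D0 + 40L)
  spec <- trial_spec("substance_misuse")
  panel <- build_clone_panel(p, hand_disp(), hand_events(), spec)
  expect_setequal(unique(panel$clone_arm),
                  c("initiation", "non_initiation"))
  expect_true(all(panel[, .N, by = clone_arm]$N == 2L)) # intervals 0-1
  expect_true(all(panel$censored == 0L))
})

test_that("never-initiators are censored at the end of grace in the initiation arm only", {
  p <- hand_persons(1)
  spec <- trial_spec("substance_misuse")
  panel <- build_clone_panel(p, hand_disp(), hand_events(), spec)
  init <- panel[clone_arm == "initiation"]
  expect_equal(nrow(init), 4L) # t = 0..3, censored at 3
  expect_equal(init[t == 3L, censored], 1L)
  non <- panel[clone_arm == "non_initiation"]
  expect_equal(nrow(non), 24L)
  expect_true(all(non$censored == 0L))
})

test_that("initiate month 1, discontinue month 8: initiation clone censored at 8, the other at 1", {
  disp <- hand_disp(rep(1L, 7), 30L * (1:7), "stimulant", rep(30L, 7))
  spec <- trial_spec("substance_misuse", max_gap_intervals = 0L)
  panel <- build_clone_panel(hand_persons(1), disp, hand_events(), spec)
  init <- panel[clone_arm == "initiation"]
  expect_equal(max(init$t), 8L)
  expect_equal(init[t == 8L, censored], 1L)
  non <- panel[clone_arm == "non_initiation"]
  expect_equal(max(non$t), 1L)
  expect_equal(non[t == 1L, censored], 1L)
})

test_that("discontinuation during grace censors at the end of grace, not before", {
  disp <- hand_disp(1L, 0L, "stimulant", 30L)
  spec <- trial_spec("substance_misuse", max_gap_intervals = 0L)
  panel <- build_clone_panel(hand_persons(1), disp, hand_events(), spec)
  init <- panel[clone_arm == "initiation"]
  expect_equal(max(init$t), 3L)
  expect_equal(init[t == 3L, censored], 1L)
})

test_that("switching censors only after grace and only when disallowed", {
  disp <- hand_disp(rep(1L, 8), 30L * (0:7),
                    c(rep("stimulant", 6), rep("non_stimulant", 2)),
                    rep(30L, 8))
  spec <- trial_spec("substance_misuse", max_gap_intervals = 0L)
  panel <- build_clone_panel(hand_persons(1), disp, hand_events(), spec)
  init <- panel[clone_arm == "initiation"]
  expect_equal(max(init$t), 6L) # switch covers interval 6
  expect_equal(init[t == 6L, censored], 1L)

  spec2 <- trial_spec("substance_misuse", allow_switching = TRUE,
                      max_gap_intervals = 0L)
  panel2 <- build_clone_panel(hand_persons(1), disp, hand_events(),
                              spec2)
  init2 <- panel2[clone_arm == "initiation"]
  expect_equal(max(init2$t), 8L) # runs to supply exhaustion instead
})

test_that("a switch during the grace period is non-deviating", {
  disp <- hand_disp(rep(1L, 10), 30L * (0:9),
                    c("stimulant", rep("non_stimulant", 9)),
                    rep(30L, 10))
  spec <- trial_spec("substance_misuse", max_gap_intervals = 0L)
  panel <- build_clone_panel(hand_persons(1), disp, hand_events(), spec)
  init <- panel[clone_arm == "initiation"]
  expect_equal(max(init$t), 10L) # censored at supply end, not the switch
})

test_that("allowing switches never increases the censor count", {
  tabs <- shared_sim()$tables
  p_strict <- build_small_panel(tabs, trial_spec("substance_misuse"))
  p_allow <- build_small_panel(tabs,
                               trial_spec("substance_misuse",
                                          allow_switching = TRUE))
  n_strict <- p_strict[clone_arm == "initiation", sum(censored)]
  n_allow <- p_allow[clone_arm == "initiation", sum(censored)]
  expect_lte(n_allow, n_strict)
})

test_that("censoring is monotone: no rows beyond the censoring interval", {
  tabs <- shared_sim()$tables
  panel <- build_small_panel(tabs)
  chk <- panel[, .(last = max(t), cens_at = suppressWarnings(
    as.numeric(min(t[censored == 1L])))), by = .(person_id, clone_arm)]
  chk <- chk[is.finite(cens_at)]
  expect_true(all(chk$last == chk$cens_at))
})

test_that("with certain immediate initiation and no discontinuation no initiation clone is censored", {
  cfg <- sim_config(
    300, seed = 17,
    initiation_model = c(intercept = 20, male = 0, young = 0,
                         comorbidity = 0, prior_event = 0, tv_comed = 0),
    discontinuation_model = c(intercept = -20, male = 0, young = 0,
                              comorbidity = 0, prior_event = 0,
                              tv_comed = 0),
    switch_prob = 0)
  tabs <- simulate_cohort(cfg)
  panel <- build_small_panel(tabs)
  expect_equal(panel[clone_arm == "initiation", sum(censored)], 0L)
})

test_that("exactly one clone of a treated person survives past the grace period", {
  tabs <- shared_sim()$tables
  panel <- build_small_panel(tabs)
  grace <- 3L
  post <- panel[t > grace & censored == 0L,
                .(arms = data.table::uniqueN(clone_arm)),
                by = person_id]
  expect_true(all(post$arms == 1L))
})

test_that("protocol censoring validates its inputs", {
  tabs <- shared_sim()$tables
  spec <- trial_spec("substance_misuse")
  persons <- apply_eligibility(tabs$persons, tabs$dispensations,
                               spec$eligibility)$persons[1:5]
  w <- ccwtrial:::followup_windows(persons, tabs$events,
                                   "substance_misuse", 24L,
                                   as.Date("2020-12-31"))
  panel <- ccwtrial:::expand_panel(persons, w, tabs$events,
                                   tabs$dispensations, spec)
  ccwtrial:::set_meta(panel, list(grace = 3L, horizon = 24L,
                                  arms = c("initiation",
                                           "non_initiation")))
  # uncloned panel cannot be censored
  tl <- data.table::data.table(person_id = persons$person_id,
                               initiation_interval = NA_integer_,
                               discontinuation_interval = NA_integer_,
                               switch_interval = NA_integer_)
  expect_error(apply_protocol_censoring(panel, tl, spec),
               class = "ccwtrial_validation_error")
  cloned <- make_clones(panel)
  expect_error(apply_protocol_censoring(cloned, tl[1:2], spec),
               class = "ccwtrial_validation_error")
})
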