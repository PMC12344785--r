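# Synthetic register generator.
#
# Randomness discipline: a single master seed generates one fixed-width
# block of uniforms per individual (person-major), so individual i's data
# depend only on the seed and i -- growing n_individuals never perturbs
# earlier individuals. All monthly processes consume slots from that block.

# slot layout inside a person's uniform block
.slot_base <- function(n_bcov, n_out) {
  list(
    sex = 1L, age = 2L, edu = 3L, u_baseline = 4L, washout = 5L,
    underage = 6L, init_class = 7L, index = 8L,
    bcov = 8L + seq_len(n_bcov),
    fixed = 8L + n_bcov,
    # per-month block width: initiation, U-transition, discontinuation,
    # supply, switch, death, death-vs-emigration, one per outcome
    month_width = 7L + n_out
  )
}

.linpred <- function(coefs, X, tv = NULL) {
  eta <- rep(unname(coefs[["intercept"]]), nrow(X))
  for (nm in setdiff(names(coefs), c("intercept", "tv_comed"))) {
    if (nm %in% colnames(X)) eta <- eta + coefs[[nm]] * X[, nm]
  }
  if (!is.null(tv) && "tv_comed" %in% names(coefs)) {
    eta <- eta + coefs[["tv_comed"]] * tv
  }
  eta
}

.draw_baseline <- function(config, U) {
  n <- nrow(U)
  bspec <- config$baseline_covariate_spec
  slots <- .slot_base(length(bspec), length(config$outcome_models))
  sex <- ifelse(U[, slots$sex] < config$p_male, "male", "female")
  # gamma ages truncated at 64 via the quantile transform (exact truncation)
  pmax_u <- pgamma(64 - 6, shape = config$age_shape, scale = config$age_scale)
  age <- 6 + qgamma(U[, slots$age] * pmax_u, shape = config$age_shape,
                    scale = config$age_scale)
  if (config$underage_frac > 0) {
    under <- U[, slots$underage] < config$underage_frac
    age[under] <- 3 + 2 * U[under, slots$age]
  }
  cp <- cumsum(config$education_probs)
  edu <- names(config$education_probs)[
    findInterval(U[, slots$edu], c(0, head(cp, -1)))
  ]
  bcov <- list()
  for (k in seq_along(bspec)) {
    nm <- names(bspec)[k]
    sp <- bspec[[k]]
    u <- U[, slots$bcov[k]]
    bcov[[nm]] <- switch(
      sp$dist,
      bernoulli = as.integer(u < sp$p),
      poisson = stats::qpois(u, lambda = sp$lambda),
      stop_validation("unknown baseline covariate distribution '%s'", sp$dist)
    )
  }
  X <- cbind(male = as.integer(sex == "male"),
             young = as.integer(age < 25))
  for (nm in names(bcov)) {
    if (bspec[[nm]]$dist == "bernoulli") X <- cbind(X, bcov[[nm]])
  }
  colnames(X) <- c("male", "young",
                   names(bcov)[vapply(bspec, function(s) s$dist, "") ==
                                 "bernoulli"])
  list(sex = sex, age = age, edu = edu, bcov = bcov, X = X, slots = slots)
}

#' Simulate pseudo-register tables
#'
#' Generates the three long-format register tables (persons, drug
#' dispensations, outcome events) from the data-generating process in a
#' [sim_config()]. Dispensations include both ADHD drug classes
#' (`stimulant`, `non_stimulant`) and `other_psychotropic` co-medication;
#' the latter carries the binary time-varying confounder into the observed
#' data (a dispensation in interval *t* means the confounder was active in
#' *t*). Events carry one dated row per outcome occurrence; when
#' `config$recurrent` is `FALSE` only the first event per type is emitted,
#' otherwise at most one event per outcome type per 30-day interval.
#'
#' @param config a [sim_config()].
#' @return list with data.tables `persons`, `dispensations`, `events`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_individuals
  H <- config$horizon_months
  grace <- config$grace_months
  n_out <- length(config$outcome_models)
  n_bcov <- length(config$baseline_covariate_spec)
  slots <- .slot_base(n_bcov, n_out)
  K <- slots$fixed + H * slots$month_width

  set.seed(config$seed)
  U <- matrix(stats::runif(as.numeric(n) * K), nrow = n, byrow = TRUE)

  bl <- .draw_baseline(config, U)
  X <- bl$X

  win_days <- as.integer(config$enrolment_window[2] -
                           config$enrolment_window[1])
  index_date <- config$enrolment_window[1] +
    floor(U[, slots$index] * (win_days + 1))

  eta_init <- .linpred(config$initiation_model, X)
  eta_disc <- .linpred(config$discontinuation_model, X)
  tvm <- config$tv_confounder_model
  supplies <- c(30L, 60L, 90L)
  cum_supply <- cumsum(config$supply_probs)

  # state
  U_prev <- as.integer(U[, slots$u_baseline] < tvm[["p_baseline"]])
  treated_prev <- rep(0L, n)
  initiated <- rep(FALSE, n)
  init_t <- rep(NA_integer_, n)
  discontinued <- rep(FALSE, n)
  covered_until <- rep(-1L, n)
  cur_class <- rep(NA_integer_, n) # 1 stimulant, 2 non_stimulant
  alive <- rep(TRUE, n)
  death_t <- rep(NA_integer_, n)
  is_death <- rep(NA, n)

  disp_pid <- list(); disp_day <- list(); disp_cls <- list()
  disp_sup <- list()
  comed_pid <- list(); comed_day <- list()
  ev <- lapply(config$outcome_models, function(...) list(pid = list(),
                                                          t = list()))

  # baseline confounder state emitted as co-medication in interval -1
  base_on <- which(U_prev == 1L)
  comed_pid[[length(comed_pid) + 1L]] <- base_on
  comed_day[[length(comed_day) + 1L]] <- rep(-23L, length(base_on))

  mslot <- function(t, k) slots$fixed + t * slots$month_width + k

  for (t in 0:(H - 1L)) {
    u_init <- U[, mslot(t, 1L)]
    u_utr  <- U[, mslot(t, 2L)]
    u_disc <- U[, mslot(t, 3L)]
    u_sup  <- U[, mslot(t, 4L)]
    u_swi  <- U[, mslot(t, 5L)]
    u_dth  <- U[, mslot(t, 6L)]
    u_dsp  <- U[, mslot(t, 7L)]

    # 1. initiation during grace
    if (t < grace) {
      can <- alive & !initiated
      p <- plogis(eta_init + tvm_coef(config$initiation_model) * U_prev)
      start <- can & (u_init < p)
      if (any(start)) {
        idx <- which(start)
        initiated[idx] <- TRUE
        init_t[idx] <- t
        cur_class[idx] <- ifelse(U[idx, slots$init_class] <
                                   config$stimulant_prob, 1L, 2L)
        s <- supplies[findInterval(u_sup[idx], c(0, head(cum_supply, -1)))]
        covered_until[idx] <- t + s %/% 30L - 1L
        disp_pid[[length(disp_pid) + 1L]] <- idx
        disp_day[[length(disp_day) + 1L]] <- rep(30L * t, length(idx))
        disp_cls[[length(disp_cls) + 1L]] <- cur_class[idx]
        disp_sup[[length(disp_sup) + 1L]] <- s
      }
    }

    # 2. refill or discontinue when coverage ran out last interval
    due <- alive & initiated & !discontinued & covered_until == t - 1L &
      (is.na(init_t) | init_t != t)
    if (any(due)) {
      p_disc <- plogis(eta_disc + tvm_coef(config$discontinuation_model) *
                         U_prev)
      stops <- due & (u_disc < p_disc)
      discontinued[stops] <- TRUE
      refill <- which(due & !stops)
      if (length(refill)) {
        sw <- u_swi[refill] < config$switch_prob
        cur_class[refill[sw]] <- 3L - cur_class[refill[sw]]
        s <- supplies[findInterval(u_sup[refill],
                                   c(0, head(cum_supply, -1)))]
        covered_until[refill] <- t + s %/% 30L - 1L
        disp_pid[[length(disp_pid) + 1L]] <- refill
        disp_day[[length(disp_day) + 1L]] <- rep(30L * t, length(refill))
        disp_cls[[length(disp_cls) + 1L]] <- cur_class[refill]
        disp_sup[[length(disp_sup) + 1L]] <- s
      }
    }

    treated_t <- as.integer(alive & initiated & covered_until >= t)

    # 3. outcome events (event day 14 of the interval precedes the death
    #    day 20, so events may occur in the death interval)
    for (k in seq_len(n_out)) {
      om <- config$outcome_models[[k]]
      h <- om$base_hazard *
        exp(.effects_eta(om$effects, X, U_prev) + om$log_irr * treated_t)
      h <- pmin(h, 0.99)
      hit <- which(alive & (U[, mslot(t, 7L + k)] < h))
      if (length(hit)) {
        ev[[k]]$pid[[length(ev[[k]]$pid) + 1L]] <- hit
        ev[[k]]$t[[length(ev[[k]]$t) + 1L]] <- rep(t, length(hit))
      }
    }

    # 4. death / emigration
    dies <- alive & (u_dth < config$death_emigration_hazard)
    if (any(dies)) {
      idx <- which(dies)
      death_t[idx] <- t
      is_death[idx] <- u_dsp[idx] < 0.8
    }

    # 5. time-varying confounder transition (depends on previous month's
    #    state and treatment), emitted as co-medication in interval t
    p_u <- plogis(tvm[["intercept"]] + tvm[["persistence"]] * U_prev +
                    tvm[["treated"]] * treated_prev)
    U_now <- as.integer(alive & (u_utr < p_u))
    on <- which(U_now == 1L)
    if (length(on)) {
      comed_pid[[length(comed_pid) + 1L]] <- on
      comed_day[[length(comed_day) + 1L]] <- rep(30L * t + 7L, length(on))
    }

    alive <- alive & !dies
    U_prev <- U_now
    treated_prev <- treated_t
  }

  persons <- data.table::data.table(
    person_id = seq_len(n),
    sex = bl$sex,
    age_at_index = round(bl$age, 2),
    index_date = index_date,
    education_level = bl$edu,
    death_date = data.table::fifelse(
      !is.na(death_t) & is_death, index_date + 30L * death_t + 20L,
      as.Date(NA)),
    emigration_date = data.table::fifelse(
      !is.na(death_t) & !is_death, index_date + 30L * death_t + 20L,
      as.Date(NA))
  )
  for (nm in names(bl$bcov)) persons[[nm]] <- bl$bcov[[nm]]

  # ADHD dispensations + washout violations + co-medication
  dp <- unlist(disp_pid); dd <- unlist(disp_day)
  dc <- unlist(disp_cls); ds <- unlist(disp_sup)
  if (config$washout_violation_frac > 0) {
    viol <- which(U[, slots$washout] < config$washout_violation_frac)
    dp <- c(dp, viol); dd <- c(dd, rep(-200L, length(viol)))
    dc <- c(dc, rep(1L, length(viol))); ds <- c(ds, rep(30L, length(viol)))
  }
  cp_ <- unlist(comed_pid); cd_ <- unlist(comed_day)
  dispensations <- data.table::data.table(
    person_id = c(dp, cp_),
    date = c(index_date[dp] + dd, index_date[cp_] + cd_),
    drug_class = c(c("stimulant", "non_stimulant")[dc],
                   rep("other_psychotropic", length(cp_))),
    days_supply = c(ds, rep(30L, length(cp_)))
  )
  data.table::setorder(dispensations, person_id, date, drug_class)

  ev_list <- lapply(seq_len(n_out), function(k) {
    pid <- unlist(ev[[k]]$pid)
    tt <- unlist(ev[[k]]$t)
    if (is.null(pid)) pid <- integer(0)
    if (is.null(tt)) tt <- integer(0)
    data.table::data.table(person_id = pid, t = tt,
                           outcome_type = names(config$outcome_models)[k])
  })
  events <- data.table::rbindlist(ev_list)
  if (!config$recurrent && nrow(events)) {
    data.table::setorder(events, person_id, outcome_type, t)
    events <- events[, .SD[1L], by = .(person_id, outcome_type)]
  }
  if (nrow(events)) {
    # no events after death/emigration: the death day (20) follows the
    # event day (14) within an interval, so same-interval events stand
    end_t <- rep(NA_integer_, n); end_t[!is.na(death_t)] <-
      death_t[!is.na(death_t)]
    keep <- is.na(end_t[events$person_id]) | events$t <=
      end_t[events$person_id]
    events <- events[keep]
    events[, date := persons$index_date[person_id] + 30L * t + 14L]
    events <- events[, .(person_id, date, outcome_type)]
    data.table::setorder(events, person_id, date, outcome_type)
  } else {
    events <- data.table::data.table(person_id = integer(0),
                                     date = as.Date(character(0)),
                                     outcome_type = character(0))
  }
  list(persons = persons[], dispensations = dispensations[],
       events = events[])
}

tvm_coef <- function(model) {
  if ("tv_comed" %in% names(model)) model[["tv_comed"]] else 0
}

.effects_eta <- function(effects, X, U_prev) {
  eta <- rep(0, nrow(X))
  for (nm in setdiff(names(effects), "tv_comed")) {
    if (nm %in% colnames(X)) eta <- eta + effects[[nm]] * X[, nm]
  }
  if ("tv_comed" %in% names(effects)) {
    eta <- eta + effects[["tv_comed"]] * U_prev
  }
  eta
}

#' True marginal incidence rate ratio by counterfactual simulation
#'
#' Simulates each of `n_mc` synthetic individuals under two forced
#' regimes -- (A) initiate during the grace period following the natural
#' initiation process, forcing initiation in the last grace month for
#' those still untreated, then sustain treatment for the rest of
#' follow-up; (B) never initiate -- and accumulates *expected* events and
#' person-time by propagating the discrete hazards along each simulated
#' confounder path (the only Monte-Carlo noise is in the covariate and
#' confounder paths, not in event draws). The ratio of marginal event
#' rates per person-time is the oracle against which pipeline estimates
#' are compared. Common random numbers are used for the confounder
#' transitions of the two regimes.
#'
#' @param config a [sim_config()].
#' @param n_mc number of Monte-Carlo individuals.
#' @param outcome_type outcome to evaluate (default: first configured).
#' @return list of class `ccw_truth`: `irr`, `log_irr`, `mc_se` (delta-method
#'   standard error of `log_irr` over individuals), `rate_initiation`,
#'   `rate_non_initiation` (per 1000 person-years), `n_mc`.
#' @export
simulate_counterfactual_truth <- function(config, n_mc = 100000L,
                                          outcome_type = NULL) {
  stopifnot(inherits(config, "sim_config"))
  n_mc <- check_positive_int(n_mc, "n_mc")
  if (is.null(outcome_type)) outcome_type <- names(config$outcome_models)[1]
  if (!outcome_type %in% names(config$outcome_models)) {
    stop_validation("outcome_type '%s' not in config", outcome_type)
  }
  om <- config$outcome_models[[outcome_type]]
  H <- config$horizon_months
  grace <- config$grace_months
  tvm <- config$tv_confounder_model
  p_dem <- config$death_emigration_hazard

  set.seed(derive_seed(config$seed, 7L))
  n <- n_mc
  # baseline draws follow the same distributions as simulate_cohort
  Ub <- matrix(stats::runif(as.numeric(n) *
                              (8L + length(config$baseline_covariate_spec))),
               nrow = n, byrow = TRUE)
  bl <- .draw_baseline(config, Ub)
  X <- bl$X
  eta_init <- .linpred(config$initiation_model, X)
  eta_out <- .effects_eta(om$effects, X, 0) # tv part added per month

  u_base <- as.integer(Ub[, 4L] < tvm[["p_baseline"]])
  UA <- u_base; UB <- u_base
  treatedA_prev <- rep(0L, n)
  initiated <- rep(FALSE, n)

  SA <- rep(1, n); SB <- rep(1, n) # event-free-and-alive probability
  evA <- rep(0, n); evB <- rep(0, n)
  ptA <- rep(0, n); ptB <- rep(0, n)
  tv_eff <- if ("tv_comed" %in% names(om$effects)) om$effects[["tv_comed"]]
            else 0
  first_event <- !config$recurrent

  for (t in 0:(H - 1L)) {
    # regime A natural initiation during grace, forced in last grace month
    if (t < grace) {
      p <- plogis(eta_init + tvm_coef(config$initiation_model) * UA)
      start <- !initiated & (stats::runif(n) < p)
      if (t == grace - 1L) start <- start | !initiated
      initiated <- initiated | start
    }
    treatedA <- as.integer(initiated)

    hA <- pmin(om$base_hazard * exp(eta_out + tv_eff * UA +
                                      om$log_irr * treatedA), 0.99)
    hB <- pmin(om$base_hazard * exp(eta_out + tv_eff * UB), 0.99)

    if (first_event) {
      evA <- evA + SA * hA
      evB <- evB + SB * hB
      ptA <- ptA + SA * (hA * 15 / 30 +
                           (1 - hA) * (p_dem * 21 / 30 + (1 - p_dem))) / 12
      ptB <- ptB + SB * (hB * 15 / 30 +
                           (1 - hB) * (p_dem * 21 / 30 + (1 - p_dem))) / 12
      SA <- SA * (1 - hA) * (1 - p_dem)
      SB <- SB * (1 - hB) * (1 - p_dem)
    } else {
      evA <- evA + SA * hA
      evB <- evB + SB * hB
      ptA <- ptA + SA * (p_dem * 21 / 30 + (1 - p_dem)) / 12
      ptB <- ptB + SB * (p_dem * 21 / 30 + (1 - p_dem)) / 12
      SA <- SA * (1 - p_dem)
      SB <- SB * (1 - p_dem)
    }

    # shared uniform for both regimes' confounder transitions
    u <- stats::runif(n)
    UA <- as.integer(u < plogis(tvm[["intercept"]] +
                                  tvm[["persistence"]] * UA +
                                  tvm[["treated"]] * treatedA_prev))
    UB <- as.integer(u < plogis(tvm[["intercept"]] +
                                  tvm[["persistence"]] * UB))
    treatedA_prev <- treatedA
  }

  EA <- sum(evA); EB <- sum(evB); PA <- sum(ptA); PB <- sum(ptB)
  rate_a <- EA / PA; rate_b <- EB / PB
  irr <- rate_a / rate_b
  # delta-method influence function of log irr over individuals
  infl <- evA / EA - ptA / PA - evB / EB + ptB / PB
  mc_se <- sqrt(sum(infl^2))
  structure(list(
    irr = irr, log_irr = log(irr), mc_se = mc_se,
    rate_initiation = 1000 * rate_a, rate_non_initiation = 1000 * rate_b,
    outcome_type = outcome_type, n_mc = n_mc
  ), class = "ccw_truth")
}

#' @export
print.ccw_truth <- function(x, ...) {
  cat(sprintf(
    "<ccw_truth> %s: true IRR %.4f (log %.4f, MC SE %.4f), rates %.1f vs %.1f /1000py, n_mc=%d\n",
    x$outcome_type, x$irr, x$log_irr, x$mc_se,
    x$rate_initiation, x$rate_non_initiation, x$n_mc))
  invisible(x)
}
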