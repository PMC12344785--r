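---
title: "Emulating per-protocol target trials with clone-censor-weight"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Emulating per-protocol target trials with clone-censor-weight}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The estimation problem

Registry cohorts of newly diagnosed patients are the natural place to ask
what *sustained* drug treatment does to clinical outcomes, but a naive
comparison of people who started treatment with people who did not is
broken in two ways. First, treatment start is not randomised: starters
differ from non-starters in severity, comorbidity, and history of the
outcome. Second, whenever "ever treated during follow-up" is used as the
exposure, the waiting time between cohort entry and the first dispensation
is *immortal* — a person must remain event-free to be observed starting —
and the resulting bias favours treatment even under a true null.

`ccwtrial` implements the clone-censor-weight (CCW) answer to both
problems for a per-protocol contrast of two strategies anchored at
diagnosis (time zero):

* **initiation** — start drug treatment within a grace period (default
  three 30-day intervals) and remain on the initial drug;
* **non-initiation** — never start during follow-up.

Every eligible person is duplicated into one clone per strategy, so
baseline confounding and immortal time are removed by construction: both
clones share the person's baseline data and time zero. A clone is
artificially censored the first time the person's observed dispensation
record deviates from the clone's assigned strategy — failure to initiate
by the end of grace, discontinuation, or a class switch for the
initiation clone; any dispensation for the non-initiation clone. Because
this censoring depends on evolving prognosis, it induces selection, which
is removed by time-varying inverse probability of censoring weights
(IPCW) estimated from pooled logistic models. The weighted outcome model
is again pooled logistic,

$$\operatorname{logit}\, h_{it} = \alpha_t + \beta \cdot \text{arm}_i ,$$

whose arm coefficient approximates the log incidence rate ratio (IRR)
while per-interval risks stay small; the synthetic data keep monthly
hazards below about 0.05 so that odds, risks and rates are
interchangeable to well within the reported precision.

Confidence intervals come from a nonparametric bootstrap that re-samples
*persons* with replacement and repeats the whole pipeline — censoring,
weight estimation, truncation, outcome fit — in every resample (500
resamples by default, percentile intervals on the log scale).

## Time grid and bookkeeping conventions

Follow-up is partitioned into consecutive 30-day intervals from the index
date; interval $t$ is the half-open day range $[30t, 30(t+1))$ and a full
interval contributes $1/12$ person-year. These conventions are load-bearing
and tested:

* An event on an interval boundary belongs to the later interval.
* The final partial interval contributes person-time pro-rata; follow-up
  ends at the earliest of first event (first-event analyses only), death,
  emigration, the two-year horizon, or the administrative end of registry
  data, with ties resolved in that order.
* Exposure is reconstructed from dispensed days' supply with carryover of
  overlapping supplies. A refill gap counts as continuous treatment only
  when coverage *resumes* within `max_gap_intervals` (default one
  interval); a terminal gap is discontinuation at its first uncovered
  interval. This retrospective reading is the standard episode
  construction in pharmacoepidemiology; bridging terminal gaps would
  credit every discontinuer with an extra, systematically different,
  exposed interval.
* Deviation is dated: the grace deadline at day $30 \cdot
  \text{grace}$, discontinuation at the start of the first uncovered
  interval, initiation (for the non-initiation clone) at the dispensation
  date. An event in the censoring interval is counted if and only if it
  is dated on or before the deviation, with date ties favouring the
  event. Counting *all* same-interval events while censoring removes
  event-free clones would inflate every censoring interval's hazard;
  the date comparison keeps numerator and risk set consistent.
* Switches during the grace period are treated as non-deviating; only
  post-grace switches censor (and not at all under the
  `allow_switching` sensitivity analysis).

## Censoring models and weights

Weights are unstabilized by default,
$w_{it} = \prod_{k \le t} 1/\hat p_{ik}$ with $\hat p_{ik}$ the fitted
conditional probability of remaining uncensored, truncated at the 99.5th
percentile computed *within arm* over all person-interval weights
(type-7 quantile, i.e. linear interpolation between order statistics,
stated here so results are bit-reproducible). A stabilized variant
multiplies by the analogous cumulative marginal probabilities and is
available via `censoring_model_spec(stabilized = TRUE)`.

Two genuinely open design points were resolved as follows:

* **Per-phase models.** The initiation arm faces two different censoring
  mechanisms: failure-to-initiate, which strikes exactly once at the end
  of grace and depends on covariates through the initiation process, and
  discontinuation/switching afterwards, which depends on covariates
  through persistence. A single pooled model with shared covariate
  coefficients is misspecified for both, so the default fits them
  separately (`per_phase = TRUE`); the composite single-model behaviour
  remains available.
* **Time as interval dummies.** With 24 intervals, saturated-in-time is
  the least-assumption default. An interval with no censoring events has
  censoring probability exactly zero under the saturated maximum
  likelihood solution, and the implementation returns exactly that
  rather than chasing a divergent coefficient; a low-order polynomial in
  time is available as a fallback for sparse panels.

Truncation trades bias for variance: capping the largest weights pulls
the estimate slightly toward its unweighted counterpart. Under the
strongly confounded null scenario this shows up as a small downward
shift of the point estimate relative to the untruncated fit, which is
visibly noisier. The 99.5th-percentile cap is the design's stated
choice and is kept as the default.

## The synthetic register and its oracle

Individual-level register data of the kind this design is used on cannot
be shared, so the package carries a generator
(`simulate_cohort()`) whose output mimics the register *structure* —
persons with demographics and baseline flags, dated drug dispensations
with days' supply, dated outcome events — while every causal quantity is
known. The data-generating process:

* Baseline covariates: sex (58.7% male), age from a truncated gamma
  (median around 17–19 years, range 6–64), education, binary comorbidity
  and outcome-history flags, a healthcare-use count.
* A binary time-varying confounder $U_t$ with first-order dynamics,
  affected by the previous month's treatment and affecting
  discontinuation and the outcome. It is surfaced to the analysis side
  as monthly `other_psychotropic` co-medication dispensations, the way
  registry analyses observe psychotropic co-medication, and enters
  models with a one-interval lag.
* Confounded initiation during grace (about 57% initiate, matching the
  scale seen in incident-diagnosis cohorts), monthly refills with supply
  drawn from {30, 60, 90} days, discontinuation decided at refill time,
  class switching, and death/emigration.
* Outcome hazards: monthly baseline hazard 0.006 for the primary
  synthetic outcome with log-rate terms for the covariates and a true
  log-IRR of $\log 0.85$ applied while treatment coverage is sustained
  — the magnitude of a typical protective association in this
  literature. The severity gradient is aligned (sicker individuals
  initiate less, discontinue more, and have higher outcome rates) so
  that the unweighted per-protocol estimate is visibly biased downward
  while IPCW is consistent; this is precisely the structure the design
  exists to handle. A rare control outcome (`t1d_control`, monthly
  hazard 0.002) is generated independently of treatment and of all
  confounders for negative-control analyses.
* The baseline hazard sits at the upper end of registry outcome rates
  so that cohorts of 5 000–20 000 individuals — the sizes used
  throughout the test suite — carry enough events for stable estimates.

Randomness is pre-drawn in a fixed-width block per individual from one
master seed, so identical configurations reproduce byte-identical tables
and growing the cohort never perturbs earlier individuals.

**The oracle.** `simulate_counterfactual_truth()` propagates each
simulated individual's covariate path under two forced regimes — (A)
initiate during grace following the natural initiation process, with
initiation forced in the last grace month for those still untreated,
then sustain; (B) never initiate — and accumulates *expected* events and
person-time from the discrete hazards, so the only Monte-Carlo noise is
in covariate paths. The ratio of marginal rates is the target against
which pipeline estimates are compared, with a delta-method Monte-Carlo
standard error. Regime A's forced tail is a deliberate simplification:
the CCW estimand implicitly mixes over compliers' natural initiation
times, which differs from forcing at the last grace month by at most a
month or two of exposure for a minority, a second-order discrepancy
relative to the tolerances used anywhere in the package.

What the generator does **not** emulate: real diagnosis/procedure coding
(ICD/ATC dictionaries are out of scope), calendar-time trends, family
structure, dose or duration effects, re-entry after emigration, and
measurement error in dispensation records. Consequently, passing tests
demonstrate that the *machinery* is correct under a known process with
the intended confounding structure — not that any particular real-world
association is causal.

## Balance diagnostics

`balance_table()` reports standardized mean differences
$(m_a - m_b)/\sqrt{(v_a + v_b)/2}$ — weighted means, weighted
population-style variances, sign arm A minus arm B — among clones still
at risk at the end of grace, with the conventional $|SMD| < 0.10$
adequacy flag. The default covariate set is the *baseline* (time-fixed)
covariates: the lagged co-medication indicator is measured after time
zero and is causally affected by treatment in the effect scenario, so an
arm difference in it at the end of grace is an expected consequence of
the contrast, not a weighting failure. It can still be inspected by
passing it explicitly.

## Bootstrap implementation

Cloning and censoring are deterministic functions of a person's data, so
a resample of persons drawn with replacement yields a panel identical to
the original panel with per-person multiplicities. The bootstrap
therefore folds multiplicities into every aggregated model fit and into
the truncation quantile (computed on the expanded multiset) instead of
materialising duplicated rows. This is exactly equivalent to rebuilding
the panel per resample and makes 100 full resamples of a 5 000-person
cohort a matter of seconds, which is what allows the coverage check in
the test suite (100 simulation replicates at n = 5 000 with 100
resamples each) to be run routinely rather than as an occasional audit.
All pooled logistic fits run on events/trials tables aggregated over
(interval, covariate pattern) cells — identical likelihood, much smaller
matrices.

Failed resamples (for example, a resample losing all events in one arm)
are excluded and counted; more than 10% failures aborts with an error.

## Numerical and degenerate-input choices

* Quantiles everywhere are type 7; probabilities are clamped away from
  zero only by the model structure itself (a fitted logistic cannot
  reach 0 or 1), and a genuinely zero probability raises an error
  rather than an infinite weight.
* An arm with no censoring events yields weights identically one, and
  the weighted estimate then equals the unweighted estimate exactly.
* Aliased columns in saturated fits (for example a covariate constant
  within the fitted stratum) are dropped by the QR pivot and their
  coefficients treated as zero; predictions are unaffected.
* Estimation refuses to proceed when an arm has zero weighted events,
  naming the arm; rate computation refuses zero person-time.
* Bias of the weighted and unweighted estimators is measured in the
  acceptance suite as the mean over independent simulation replicates,
  because a single realization's deviation from truth is dominated by
  Monte-Carlo noise.

## Subgroups, sensitivity analyses, and variants

`run_trial()` / `run_trial_suite()` orchestrate the pipeline from YAML
or in-memory configurations: grace period six months, allowing switches,
recurrent events (follow-up not censored at outcomes, at most one event
counted per interval), negative-control outcomes, subgroup restrictions
(e.g. by outcome history) with Wald contrasts between subgroup log-IRRs
using bootstrap standard errors, and a head-to-head variant comparing
initiators of one drug class against the other with time zero at
initiation. Each run writes results JSON, balance and cumulative-
incidence CSVs, an exclusion log, and a manifest (configuration, seed,
versions) sufficient to reproduce outputs byte-identically.

## Known limitations

* The IRR approximation through pooled logistic regression degrades if
  per-interval risks grow beyond a few percent; the generator keeps
  hazards low on purpose, but user data are not checked for this.
* IPCW corrects only censoring explainable by the modelled covariates;
  the package offers no doubly robust or machine-learned censoring
  models, mirroring the design it implements.
* Death is handled as a censoring event, not a competing risk
  decomposition.
* Within-person correlation in recurrent-event analyses is addressed by
  the person-level bootstrap only.
* Weight truncation introduces a small, documented bias toward the
  unweighted estimate in exchange for variance control.
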