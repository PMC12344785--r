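# ccwtrial

Clone-censor-weight emulation of per-protocol target trials from
registry-style longitudinal data, with a synthetic-register generator
and a counterfactual oracle so that every stage of the pipeline can be
validated against known ground truth.

## The problem and who this is for

Pharmacoepidemiologists working with administrative registers (incident
diagnoses, drug dispensations, outcome events) often need the effect of
*starting treatment promptly and staying on it* versus never starting —
a per-protocol contrast that naive treated-vs-untreated comparisons get
wrong twice over: treatment start is confounded by prognosis, and
classifying people by treatment observed during follow-up makes their
pre-treatment waiting time immortal, biasing results toward benefit
even under a true null.

The clone-censor-weight design fixes both. Each eligible person is
duplicated into one clone per strategy at time zero (diagnosis), so
both arms share identical baseline data; a clone is artificially
censored the first time the observed dispensation record deviates from
its assigned strategy (no initiation by the end of a grace period,
discontinuation, or switching for the initiation clone; any
dispensation for the non-initiation clone); and the selection induced
by that censoring is removed with time-varying inverse probability of
censoring weights from pooled logistic models. The weighted outcome
model

```
logit h_it = alpha_t + beta * arm_i
```

is fitted on stacked person–interval rows; `exp(beta)` approximates the
incidence rate ratio (IRR) while per-interval risks are small. Weights
are truncated at the 99.5th within-arm percentile; confidence intervals
come from a nonparametric bootstrap of individuals in which the entire
pipeline (censoring, weight fitting, truncation, outcome fit) is
re-run per resample.

Because the individual-level registers such analyses run on cannot be
shared, the package includes `simulate_cohort()`, a register generator
with a known data-generating process — confounded initiation during the
grace period, refill/discontinuation dynamics driven by a binary
time-varying confounder that is itself affected by treatment, class
switching, five-ish outcome processes with configurable true effects,
death/emigration — and `simulate_counterfactual_truth()`, which computes
the true marginal IRR of the emulated contrast by forced-regime
simulation. See the methods vignette
(`vignettes/clone-censor-weight.Rmd`) for the model, assumptions, and
design decisions.

## Worked example

```r
library(ccwtrial)

cfg    <- sim_config(n_individuals = 5000, seed = 42)
tables <- simulate_cohort(cfg)

# what the answer should be, by counterfactual simulation
simulate_counterfactual_truth(cfg, n_mc = 50000)
#> <ccw_truth> substance_misuse: true IRR 0.7297 (log -0.3152, MC SE 0.0005),
#>             rates 118.3 vs 162.2 /1000py, n_mc=50000

# the full clone-censor-weight pipeline with bootstrap CI
est <- bootstrap_ci(tables, trial_spec("substance_misuse"),
                    boot_spec(n_boot = 200, seed = 42))
est
#> <ccw_estimate> IRR 0.773 (95% CI 0.658 to 0.891)
#>   initiation: 1111.9 weighted events / 8534.4 person-years = 130.3 per 1000 py
#>   non_initiation: 1406.2 weighted events / 8364.8 person-years = 168.1 per 1000 py

# covariate balance at the end of the grace period
res <- estimate_ccw(tables$persons, tables$dispensations, tables$events,
                    trial_spec("substance_misuse"), return_panel = TRUE)
balance_table(res$panel)
#>      covariate smd_unweighted smd_weighted flag_unweighted flag_weighted
#> 1:        male     0.06158695 -0.002470097           FALSE         FALSE
#> 2:       young     0.17164432 -0.001278899            TRUE         FALSE
#> 3: comorbidity    -0.29108874  0.007796450            TRUE         FALSE
#> 4: prior_event    -0.27464996  0.001101519            TRUE         FALSE
```

Reading this: the generator's true sustained-treatment IRR for the
primary outcome is 0.85 directly, 0.73 marginally once the treatment's
effect on the time-varying confounder (and hence on later hazard) is
included; the pipeline estimate 0.773 (0.658–0.891) covers that truth.
Before weighting, initiators are visibly healthier (|SMD| up to 0.29);
after weighting all baseline covariates are balanced to |SMD| < 0.01.
The weighted incidence rates per arm are reported per 1000
person-years, the conventional registry scale.

Orchestrated runs — sensitivity analyses (six-month grace, allowing
switches), recurrent events, subgroups with Wald contrasts, negative
controls, head-to-head drug-class comparisons — go through
`run_trial()` / `run_trial_suite()` with YAML configurations; a thin
command-line wrapper lives in `inst/scripts/ccw_run.R`.

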