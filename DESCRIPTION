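Package: ccwtrial
Title: Clone-Censor-Weight Emulation of Target Trials from Register Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Emulates per-protocol target trials from registry-style
    longitudinal tables using the clone-censor-weight design: eligible
    individuals are duplicated into one clone per treatment strategy,
    clones are artificially censored when their observed data deviate
    from the assigned strategy, and time-varying inverse probability of
    censoring weights from pooled logistic regressions remove the
    selection bias this censoring induces. Weighted pooled logistic
    outcome models approximate incidence rate ratios; confidence
    intervals come from person-level nonparametric bootstrap. Includes a
    synthetic register generator with a known data-generating process
    and a counterfactual-simulation oracle for the true marginal effect,
    covariate balance diagnostics (standardized mean differences),
    negative-control-outcome and immortal-time-bias harnesses, and
    first-event as well as recurrent-event analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    data.table (>= 1.14),
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
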