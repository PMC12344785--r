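# Person-level nonparametric bootstrap and Wald contrasts.

#' Bootstrap specification
#'
#' @param n_boot number of full re-samples of individuals (default 500).
#' @param seed bootstrap seed.
#' @param ci_method `"percentile"` (default) or `"normal"`.
#' @param level confidence level (default 0.95).
#' @return object of class `boot_spec`.
#' @export
boot_spec <- function(n_boot = 500L, seed = 1L,
                      ci_method = c("percentile", "normal"),
                      level = 0.95) {
  ci_method <- match.arg(ci_method)
  n_boot <- check_positive_int(n_boot, "n_boot")
  if (n_boot < 2L) stop_validation("n_boot must be >= 2")
  structure(list(n_boot = n_boot, seed = as.integer(seed),
                 ci_method = ci_method, level = level),
            class = "boot_spec")
}

#' Confidence interval from a bootstrap distribution of log IRRs
#'
#' Percentile intervals are computed on the log scale and
#' back-transformed (hence equivariant under the exp transform); the
#' normal method uses the bootstrap standard error around the point
#' estimate.
#'
#' @param log_irrs bootstrap replicates of the log incidence rate ratio.
#' @param method `"percentile"` or `"normal"`.
#' @param level confidence level.
#' @param center point estimate of the log IRR (needed for `"normal"`).
#' @return named numeric `c(low, high)` on the IRR (ratio) scale.
#' @export
bootstrap_interval <- function(log_irrs, method = c("percentile",
                                                    "normal"),
                               level = 0.95, center = NULL) {
  method <- match.arg(method)
  alpha <- (1 - level) / 2
  if (method == "percentile") {
    ci <- exp(quantile_type7(log_irrs, c(alpha, 1 - alpha)))
  } else {
    if (is.null(center)) center <- mean(log_irrs)
    z <- stats::qnorm(1 - alpha)
    s <- stats::sd(log_irrs)
    ci <- exp(c(center - z * s, center + z * s))
  }
  stats::setNames(ci, c("low", "high"))
}

#' Full clone-censor-weight pipeline with bootstrap confidence interval
#'
#' Runs the complete pipeline (eligibility, cloning, censoring, weight
#' fitting, outcome fitting) on the original register tables, then
#' repeats the estimation for `n_boot` re-samples of individuals drawn
#' with replacement at the original cohort size. Each resample refits
#' the censoring models, recomputes and re-truncates the weights, and
#' refits the outcome model; because cloning and censoring are
#' deterministic per person, the resampled panel is represented by
#' per-person frequency multiplicities, which is exactly equivalent to
#' materialising the duplicated rows. Failed resamples (e.g. zero
#' events in an arm) are logged and excluded; more than 10% failures is
#' an error.
#'
#' @param tables list with `persons`, `dispensations`, `events`.
#' @param spec a [trial_spec()].
#' @param boot a [boot_spec()].
#' @param cens_spec a [censoring_model_spec()].
#' @param weighting `"ipcw"` (default) or `"none"` (unweighted
#'   per-protocol estimate, for bias diagnostics).
#' @param keep_distribution keep the vector of bootstrap log IRRs in the
#'   result (for audit export).
#' @return `ccw_estimate` with `ci_low`, `ci_high`, `se_log_irr`
#'   (bootstrap SE of the log IRR), `n_boot_failed`, and optionally
#'   `boot_log_irrs`.
#' @export
bootstrap_ci <- function(tables, spec, boot = boot_spec(),
                         cens_spec = censoring_model_spec(),
                         weighting = c("ipcw", "none"),
                         keep_distribution = FALSE) {
  weighting <- match.arg(weighting)
  stopifnot(inherits(spec, "trial_spec"), inherits(boot, "boot_spec"))
  elig <- apply_eligibility(tables$persons, tables$dispensations,
                            spec$eligibility)
  panel <- build_clone_panel(elig$persons, tables$dispensations,
                             tables$events, spec)
  prep <- ccw_engine_prep(panel, cens_spec)
  point <- ccw_engine_fit(prep, NULL, weighting)
  n <- prep$meta$n_persons
  set.seed(boot$seed)
  log_irrs <- rep(NA_real_, boot$n_boot)
  for (b in seq_len(boot$n_boot)) {
    counts <- tabulate(sample.int(n, n, replace = TRUE), nbins = n)
    log_irrs[b] <- tryCatch(
      ccw_engine_fit(prep, counts, weighting)$log_irr,
      ccwtrial_error = function(e) NA_real_)
  }
  failed <- sum(is.na(log_irrs))
  if (failed > 0.1 * boot$n_boot) {
    stop_ccw("%d of %d bootstrap resamples failed", failed, boot$n_boot,
             class = "ccwtrial_inference_error")
  }
  ok <- log_irrs[!is.na(log_irrs)]
  ci <- bootstrap_interval(ok, boot$ci_method, boot$level,
                           center = point$log_irr)
  new_ccw_estimate(
    log_irr = point$log_irr, arms = prep$meta$arms,
    events = point$weighted_events, py = point$weighted_person_years,
    model_meta = list(time_form = cens_spec$time_form,
                      n_rows = point$n_rows,
                      converged = point$converged,
                      weighting = weighting),
    ci_low = ci[["low"]], ci_high = ci[["high"]],
    se_log_irr = stats::sd(ok),
    extra = c(list(n_boot = boot$n_boot, n_boot_failed = failed,
                   person_ids = elig$persons$person_id,
                   weight_diagnostics = point$weight_diagnostics),
              if (keep_distribution) list(boot_log_irrs = log_irrs)))
}

#' Wald comparison of two incidence rate ratios
#'
#' `z = (log_irr_a - log_irr_b) / sqrt(se_a^2 + se_b^2)` with a
#' two-sided p value from the standard normal; intended for estimates
#' from independent (non-overlapping) subgroups with bootstrap standard
#' errors.
#'
#' @param result_a,result_b `ccw_estimate` objects carrying
#'   `se_log_irr`.
#' @return list `z`, `p_value`, `diff_log_irr`.
#' @export
wald_compare <- function(result_a, result_b) {
  for (r in list(result_a, result_b)) {
    if (!inherits(r, "ccw_estimate") || is.na(r$se_log_irr)) {
      stop_validation(
        "both results must carry a bootstrap SE of the log IRR")
    }
  }
  if (!is.null(result_a$person_ids) && !is.null(result_b$person_ids) &&
      length(intersect(result_a$person_ids, result_b$person_ids))) {
    stop_validation(
      "subgroups overlap: Wald comparison requires independent subgroups")
  }
  d <- result_a$log_irr - result_b$log_irr
  z <- d / sqrt(result_a$se_log_irr^2 + result_b$se_log_irr^2)
  list(z = z, p_value = 2 * stats::pnorm(-abs(z)), diff_log_irr = d)
}
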