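# Inverse probability of censoring weights.

#' Censoring model specification
#'
#' Pooled logistic models for remaining uncensored, fitted on
#' person-interval rows at risk of censoring (rows up to and including
#' the first censored interval of each clone). By default the initiation
#' arm is modelled in two phases with separate covariate coefficients --
#' the grace phase, where the only deviation is failure to initiate and
#' censoring happens at the end of grace, and the post-grace phase, where
#' deviation is discontinuation or switching -- because the two censoring
#' mechanisms depend on covariates differently. Set `per_phase = FALSE`
#' for a single composite model per arm.
#'
#' @param arm which clone arm the model applies to (`NULL` = all arms,
#'   fitted separately).
#' @param covariates character vector of panel columns (baseline plus
#'   lag-1 time-varying); `NULL` uses the panel's default modelled set.
#' @param time_form `"dummies"` (saturated interval indicators; intervals
#'   with no censoring events get censoring probability exactly zero, the
#'   saturated maximum-likelihood solution) or `"polynomial"`.
#' @param poly_degree degree for `time_form = "polynomial"`.
#' @param truncation_percentile weights above this within-arm percentile
#'   are capped (default 99.5; quantiles use linear interpolation between
#'   order statistics, type 7).
#' @param stabilized multiply by the cumulative marginal (covariate-free)
#'   uncensoring probabilities (default `FALSE`).
#' @param per_phase separate grace/post-grace models in the initiation
#'   arm (default `TRUE`).
#' @return object of class `censoring_model_spec`.
#' @export
censoring_model_spec <- function(arm = NULL, covariates = NULL,
                                 time_form = c("dummies", "polynomial"),
                                 poly_degree = 3L,
                                 truncation_percentile = 99.5,
                                 stabilized = FALSE, per_phase = TRUE) {
  time_form <- match.arg(time_form)
  if (truncation_percentile <= 50 || truncation_percentile > 100) {
    stop_validation("truncation_percentile must be in (50, 100]")
  }
  structure(list(arm = arm, covariates = covariates,
                 time_form = time_form,
                 poly_degree = as.integer(poly_degree),
                 truncation_percentile = truncation_percentile,
                 stabilized = stabilized, per_phase = per_phase),
            class = "censoring_model_spec")
}

#' Fit the pooled logistic censoring model(s) for one arm
#'
#' Fits by maximum likelihood on the person-intervals at risk of
#' censoring and returns the predicted conditional probability of
#' remaining uncensored for every row of the arm. An arm with no
#' censoring events gets probability 1 everywhere (the degenerate
#' intercept-only fit).
#'
#' @param panel censored clone panel from [build_clone_panel()].
#' @param spec a [censoring_model_spec()]; `spec$arm` selects the arm
#'   (required here).
#' @return object of class `ccw_censor_fit`: `arm`, `rows` (panel row
#'   indices), `p_uncensored` (aligned with `rows`), `coefs`.
#' @export
fit_censoring_model <- function(panel, spec) {
  stopifnot(inherits(spec, "censoring_model_spec"))
  meta <- get_meta(panel)
  if (is.null(meta)) stop_validation("panel lacks ccw metadata")
  if (is.null(spec$arm)) stop_validation("spec$arm must name a clone arm")
  if (!spec$arm %in% panel$clone_arm) {
    stop_validation("empty arm: %s", spec$arm)
  }
  covs <- spec$covariates %||% meta$covariates
  miss <- setdiff(covs, names(panel))
  if (length(miss)) {
    stop_validation("covariate(s) missing from panel: %s",
                    paste(miss, collapse = ", "))
  }
  rows_a <- which(panel$clone_arm == spec$arm)
  if (isTRUE(spec$per_phase) && spec$arm == "initiation") {
    phases <- list(grace = rows_a[panel$t[rows_a] <= meta$grace],
                   post = rows_a[panel$t[rows_a] > meta$grace])
  } else {
    phases <- list(all = rows_a)
  }
  p_all <- rep(NA_real_, length(rows_a))
  coefs <- list()
  for (ph in names(phases)) {
    rows <- phases[[ph]]
    if (!length(rows)) next
    covmat <- as.matrix(panel[rows, covs, with = FALSE])
    u <- build_censor_unit(rows, panel$t[rows], covmat)
    f <- fit_censor_unit(u, panel$censored[rows], rep(1, length(rows)),
                         spec$time_form, spec$poly_degree)
    p_all[match(rows, rows_a)] <- f$p
    coefs[[ph]] <- f$coef
  }
  structure(list(arm = spec$arm, rows = rows_a, p_uncensored = p_all,
                 coefs = coefs, spec = spec),
            class = "ccw_censor_fit")
}

#' Compute inverse probability of censoring weights
#'
#' The unstabilized weight at interval t is the cumulative product of
#' `1 / p_uncensored` over the clone's intervals up to and including t;
#' the stabilized variant multiplies by the analogous cumulative product
#' of marginal (covariate-free) uncensoring probabilities. Weights are
#' defined for rows contributing outcome information (`in_outcome = 1`).
#'
#' @param panel censored clone panel.
#' @param fits a `ccw_censor_fit` or list of them covering the arms.
#' @param stabilized compute stabilized weights.
#' @return the panel with columns `p_uncensored`, `weight_raw` (and the
#'   working column `weight`, equal to `weight_raw` until truncation).
#' @export
compute_ipc_weights <- function(panel, fits, stabilized = FALSE) {
  meta <- get_meta(panel)
  if (inherits(fits, "ccw_censor_fit")) fits <- list(fits)
  p_row <- rep(1, nrow(panel))
  for (f in fits) {
    if (any(f$p_uncensored <= 0, na.rm = TRUE)) {
      stop_ccw("censoring probability reached 0",
               class = "ccwtrial_computation_error")
    }
    p_row[f$rows] <- data.table::fcoalesce(f$p_uncensored, 1)
  }
  n_row <- nrow(panel)
  newg <- c(TRUE, panel$clone_arm[-1L] != panel$clone_arm[-n_row] |
              panel$pid[-1L] != panel$pid[-n_row])
  group_id <- cumsum(newg)
  group_first <- which(newg)
  w <- grouped_cumprod(1 / p_row, group_first, group_id)
  if (stabilized) {
    m_row <- rep(1, n_row)
    for (a in unique(panel$clone_arm)) {
      rows_a <- which(panel$clone_arm == a)
      u <- build_censor_unit(rows_a, panel$t[rows_a],
                             matrix(numeric(0), length(rows_a), 0))
      f <- fit_censor_unit(u, panel$censored[rows_a],
                           rep(1, length(rows_a)), "dummies", 3L)
      m_row[rows_a] <- f$p
    }
    w <- w * grouped_cumprod(m_row, group_first, group_id)
  }
  panel[, p_uncensored := p_row]
  panel[, weight_raw := w]
  panel[, weight := w]
  set_meta(panel, meta)
}

#' Truncate weights at a within-arm percentile
#'
#' The threshold is the stated percentile (type-7, linear interpolation)
#' of the person-interval weights within each arm; weights above it are
#' set to the threshold. Truncation never increases a weight.
#'
#' @param panel panel with a `weight` column.
#' @param percentile truncation percentile in (50, 100].
#' @return list with the modified `panel` and `diagnostics` (class
#'   `ccw_weight_diagnostics`): per arm the threshold, mean and max
#'   before/after truncation, and effective sample size per interval.
#' @export
truncate_weights <- function(panel, percentile = 99.5) {
  if (percentile <= 50 || percentile > 100) {
    stop_validation("percentile must be in (50, 100]")
  }
  meta <- get_meta(panel)
  if (!"weight" %in% names(panel)) {
    stop_validation("panel has no weight column")
  }
  arms <- unique(panel$clone_arm)
  per_arm <- list()
  for (a in arms) {
    rows_a <- which(panel$clone_arm == a & panel$in_outcome == 1L)
    wa <- panel$weight[rows_a]
    thr <- quantile_type7(wa, percentile / 100)
    stats_a <- list(arm = a, threshold = thr,
                    mean_before = mean(wa), max_before = max(wa))
    all_a <- which(panel$clone_arm == a)
    data.table::set(panel, all_a, "weight",
                    pmin(panel$weight[all_a], thr))
    wa2 <- panel$weight[rows_a]
    stats_a$mean_after <- mean(wa2)
    stats_a$max_after <- max(wa2)
    per_arm[[a]] <- stats_a
  }
  ess <- panel[in_outcome == 1L,
               .(ess = sum(weight)^2 / sum(weight^2), n = .N),
               by = .(clone_arm, t)]
  data.table::setorder(ess, clone_arm, t)
  set_meta(panel, meta)
  diagnostics <- structure(list(per_arm = per_arm, ess_per_interval = ess,
                                percentile = percentile),
                           class = "ccw_weight_diagnostics")
  list(panel = panel, diagnostics = diagnostics)
}

#' @export
print.ccw_weight_diagnostics <- function(x, ...) {
  cat(sprintf("<ccw_weight_diagnostics> truncation at percentile %.1f\n",
              x$percentile))
  for (a in x$per_arm) {
    cat(sprintf(
      "  %s: threshold %.3f, mean %.3f -> %.3f, max %.3f -> %.3f\n",
      a$arm, a$threshold, a$mean_before, a$mean_after, a$max_before,
      a$max_after))
  }
  invisible(x)
}
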