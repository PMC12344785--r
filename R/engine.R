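# Shared computational core for weighting and estimation.
#
# All pooled logistic fits run on events/trials tables aggregated over
# (interval, covariate pattern) cells, which is exactly equivalent to the
# row-level fit but orders of magnitude faster on clone panels, and lets
# person-level bootstrap resamples be expressed as frequency-weight
# multiplicities without rebuilding the panel (cloning and censoring are
# deterministic per person, so a resample's panel is the original panel
# with per-person multiplicities).

`%||%` <- function(a, b) if (is.null(a)) b else a

build_censor_unit <- function(rows, tt, covmat) {
  if (ncol(covmat) == 0L) {
    pat <- rep(1L, length(rows))
    Xpat <- matrix(numeric(0), 1L, 0L)
  } else {
    pat_str <- do.call(paste, c(as.data.frame(covmat), sep = "\r"))
    first <- !duplicated(pat_str)
    pat <- match(pat_str, pat_str[first])
    Xpat <- covmat[first, , drop = FALSE]
  }
  key_str <- paste(tt, pat)
  kfirst <- !duplicated(key_str)
  key_idx <- match(key_str, key_str[kfirst])
  list(rows = rows, pat = pat, Xpat = Xpat, key_idx = key_idx,
       key_t = tt[kfirst], key_pat = pat[kfirst], n_key = sum(kfirst))
}

# rowsum over group ids 1..ng where every id occurs in g
rowsum_vec <- function(x, g) {
  rowsum(x, g)[, 1L]
}

# intercept + indicator columns for all but the first level
time_dummies <- function(t, levels) {
  X <- matrix(1, length(t), 1L, dimnames = list(NULL, "(Intercept)"))
  if (length(levels) > 1L) {
    D <- outer(t, levels[-1L], `==`) + 0
    colnames(D) <- paste0("t", levels[-1L])
    X <- cbind(X, D)
  }
  X
}

# fit one censoring unit; returns P(remain uncensored) per unit row and
# the coefficient vector (for inspection)
fit_censor_unit <- function(unit, censored, cnt, time_form = "dummies",
                            poly_degree = 3L) {
  trials <- rowsum_vec(cnt, unit$key_idx)
  events <- rowsum_vec(cnt * censored, unit$key_idx)
  q <- numeric(unit$n_key)
  coefs <- NULL
  if (sum(events) > 0) {
    if (time_form == "dummies") {
      # saturated in time; intervals with no censoring events have
      # censoring probability exactly zero (the saturated MLE)
      ev_t <- rowsum(events, unit$key_t)
      keep_t <- as.numeric(rownames(ev_t))[ev_t[, 1L] > 0]
      sel <- unit$key_t %in% keep_t
      Tm <- time_dummies(unit$key_t[sel], keep_t)
      X <- cbind(Tm, unit$Xpat[unit$key_pat[sel], , drop = FALSE])
      fit <- fit_binomial_agg(X, events[sel], trials[sel])
      q[sel] <- plogis(drop(X %*% fit$coef))
      coefs <- fit$coef
    } else {
      ts <- unit$key_t / max(unit$key_t, 1)
      X <- cbind(1, stats::poly(ts, degree = min(poly_degree,
                                                 length(unique(ts)) - 1L),
                                raw = TRUE),
                 unit$Xpat[unit$key_pat, , drop = FALSE])
      fit <- fit_binomial_agg(X, events, trials)
      q <- plogis(drop(X %*% fit$coef))
      coefs <- fit$coef
    }
  }
  list(p = (1 - q)[unit$key_idx], coef = coefs)
}

# precompute everything reusable across bootstrap resamples
ccw_engine_prep <- function(panel, cens_spec = NULL) {
  meta <- get_meta(panel)
  if (is.null(meta)) stop_validation("panel lacks ccw metadata")
  if (is.null(cens_spec)) cens_spec <- censoring_model_spec()
  covs <- cens_spec$covariates %||% meta$covariates
  miss <- setdiff(covs, names(panel))
  if (length(miss)) {
    stop_validation("covariate(s) missing from panel: %s",
                    paste(miss, collapse = ", "))
  }
  n_row <- nrow(panel)
  arm <- panel$clone_arm
  newg <- c(TRUE, arm[-1L] != arm[-n_row] |
              panel$pid[-1L] != panel$pid[-n_row])
  group_id <- cumsum(newg)
  group_first <- which(newg)
  units <- list()
  for (a in meta$arms) {
    rows_a <- which(arm == a)
    if (!length(rows_a)) stop_validation("empty arm: %s", a)
    if (isTRUE(cens_spec$per_phase) && a == "initiation") {
      ph <- list(grace = rows_a[panel$t[rows_a] <= meta$grace],
                 post = rows_a[panel$t[rows_a] > meta$grace])
    } else {
      ph <- list(all = rows_a)
    }
    for (p in names(ph)) {
      rows <- ph[[p]]
      if (!length(rows)) next
      covmat <- as.matrix(panel[rows, covs, with = FALSE])
      u <- build_censor_unit(rows, panel$t[rows], covmat)
      u$arm <- a
      u$phase <- p
      units[[paste(a, p, sep = ".")]] <- u
    }
  }
  # marginal (covariate-free) units per arm, for stabilized weights
  marg_units <- lapply(meta$arms, function(a) {
    rows_a <- which(arm == a)
    u <- build_censor_unit(rows_a, panel$t[rows_a],
                           matrix(numeric(0), length(rows_a), 0))
    u$arm <- a
    u
  })
  names(marg_units) <- meta$arms

  out_rows <- which(panel$in_outcome == 1L)
  arm_idx <- match(arm, meta$arms)
  out_key <- (arm_idx[out_rows] - 1L) * meta$horizon +
    panel$t[out_rows] + 1L
  ukeys <- sort(unique(out_key))
  out_key_idx <- match(out_key, ukeys)
  list(panel = panel, meta = meta, covs = covs, cens_spec = cens_spec,
       group_id = group_id, group_first = group_first, units = units,
       marg_units = marg_units,
       out_rows = out_rows, out_key_idx = out_key_idx,
       out_t = (ukeys - 1L) %% meta$horizon,
       out_arm = (ukeys - 1L) %/% meta$horizon + 1L,
       pid = panel$pid, event = panel$event, censored = panel$censored,
       pt = panel$pt, arm_of_row = arm_idx, n_row = n_row)
}

# run weighting + outcome estimation for given per-person multiplicities
ccw_engine_fit <- function(prep, counts = NULL,
                           weighting = c("ipcw", "none")) {
  weighting <- match.arg(weighting)
  cs <- prep$cens_spec
  cnt <- if (is.null(counts)) rep(1, prep$n_row) else counts[prep$pid]
  w <- rep(1, prep$n_row)
  diag <- NULL
  if (weighting == "ipcw") {
    p_row <- rep(1, prep$n_row)
    for (u in prep$units) {
      f <- fit_censor_unit(u, prep$censored[u$rows], cnt[u$rows],
                           cs$time_form, cs$poly_degree)
      if (any(f$p <= 0)) stop_ccw("censoring probability reached 0")
      p_row[u$rows] <- f$p
    }
    w <- grouped_cumprod(1 / p_row, prep$group_first, prep$group_id)
    if (isTRUE(cs$stabilized)) {
      m_row <- rep(1, prep$n_row)
      for (u in prep$marg_units) {
        f <- fit_censor_unit(u, prep$censored[u$rows], cnt[u$rows],
                             cs$time_form, cs$poly_degree)
        m_row[u$rows] <- f$p
      }
      w <- w * grouped_cumprod(m_row, prep$group_first, prep$group_id)
    }
    # percentile truncation within arm over the person-interval weights
    # actually contributing outcome information, counting multiplicities
    diag <- list()
    for (ai in seq_along(prep$meta$arms)) {
      rows_a <- prep$out_rows[prep$arm_of_row[prep$out_rows] == ai]
      wa <- rep(w[rows_a], cnt[rows_a])
      if (!length(wa)) next
      thr <- quantile_type7(wa, cs$truncation_percentile / 100)
      pre_max <- max(wa)
      in_a <- prep$arm_of_row == ai
      w[in_a] <- pmin(w[in_a], thr)
      diag[[prep$meta$arms[ai]]] <- list(
        threshold = thr, max_before = pre_max,
        max_after = min(pre_max, thr), mean_before = mean(wa))
    }
  }
  or_ <- prep$out_rows
  wk <- (w * cnt)[or_]
  ev_k <- rowsum_vec(wk * prep$event[or_], prep$out_key_idx)
  tr_k <- rowsum_vec(wk, prep$out_key_idx)
  n_arms <- length(prep$meta$arms)
  sum_by_arm <- function(x, g) {
    out <- numeric(n_arms)
    r <- rowsum(x, g)
    out[as.integer(rownames(r))] <- r[, 1L]
    out
  }
  ev_by_arm <- sum_by_arm(ev_k, prep$out_arm)
  py_by_arm <- sum_by_arm(wk * prep$pt[or_], prep$arm_of_row[or_])
  if (any(ev_by_arm == 0)) {
    stop_ccw("zero events in arm '%s'",
             prep$meta$arms[which(ev_by_arm == 0)[1L]],
             class = "ccwtrial_estimation_error")
  }
  # pooled logistic: event ~ treatment + interval dummies (intervals with
  # zero events contribute nothing to the treatment contrast)
  ev_t <- rowsum(ev_k, prep$out_t)
  keep_t <- as.numeric(rownames(ev_t))[ev_t[, 1L] > 0]
  sel <- prep$out_t %in% keep_t
  X <- cbind(time_dummies(prep$out_t[sel], keep_t),
             treat = as.integer(prep$out_arm[sel] == 1L))
  fit <- fit_binomial_agg(X, ev_k[sel], tr_k[sel])
  log_irr <- fit$coef[length(fit$coef)]
  names(ev_by_arm) <- names(py_by_arm) <- prep$meta$arms
  list(log_irr = log_irr, irr = exp(log_irr),
       weighted_events = ev_by_arm, weighted_person_years = py_by_arm,
       weighted_rate_per_1000py = 1000 * ev_by_arm / py_by_arm,
       converged = fit$converged, weight_diagnostics = diag,
       weights = w, n_rows = prep$n_row)
}
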