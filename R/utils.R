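# Internal helpers: validation, quantiles, and small fitting utilities.

stop_ccw <- function(fmt, ..., class = "ccwtrial_error") {
  msg <- sprintf(fmt, ...)
  cond <- structure(
    class = c(class, "ccwtrial_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  )
  stop(cond)
}

stop_validation <- function(fmt, ...) {
  stop_ccw(fmt, ..., class = "ccwtrial_validation_error")
}

check_prob <- function(x, what) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    stop_validation("%s must be a probability in [0, 1]", what)
  }
  invisible(x)
}

check_positive_int <- function(x, what) {
  if (length(x) != 1L || !is.finite(x) || x <= 0 || x != as.integer(x)) {
    stop_validation("%s must be a positive integer", what)
  }
  as.integer(x)
}

check_columns <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    stop_validation("%s is missing column(s): %s", what,
                    paste(miss, collapse = ", "))
  }
  invisible(df)
}

# Type-7 (linear interpolation between order statistics) quantile; stated
# explicitly so weight truncation is bit-reproducible.
quantile_type7 <- function(x, p) {
  unname(stats::quantile(x, probs = p, type = 7, names = FALSE))
}

# Weighted logistic fit on an aggregated events/trials table.
# X: model matrix; events, trials: nonnegative (possibly non-integer) totals.
# Returns coefficients and fitted censor/event probabilities.
fit_binomial_agg <- function(X, events, trials) {
  keep <- trials > 0
  if (!any(keep)) stop_ccw("no usable rows in aggregated binomial fit")
  Xk <- X[keep, , drop = FALSE]
  # drop constant (all-zero) columns except intercept to avoid rank issues
  ok <- c(TRUE, colSums(abs(Xk[, -1, drop = FALSE])) > 0)
  fit <- suppressWarnings(stats::glm.fit(
    x = Xk[, ok, drop = FALSE],
    y = events[keep] / trials[keep],
    weights = trials[keep],
    family = stats::quasibinomial()
  ))
  if (!fit$converged) {
    # boundary fits (e.g. empty strata) still yield usable probabilities;
    # flag rather than fail
    attr(fit, "ccw_converged") <- FALSE
  } else {
    attr(fit, "ccw_converged") <- TRUE
  }
  beta <- rep(0, ncol(X))
  beta[ok] <- fit$coefficients
  beta[is.na(beta)] <- 0
  list(coef = beta, converged = isTRUE(attr(fit, "ccw_converged")))
}

# deterministic integer sub-seed derived from a master seed (kept < 2^31)
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 48271 + offset * 1009) %% 2147483629)
}

# cumulative product within consecutive groups, given sorted group ids;
# pure vector ops so it stays cheap inside the bootstrap loop
grouped_cumprod <- function(x, group_first_idx, group_id) {
  lx <- log(x)
  cs <- cumsum(lx)
  base <- (cs - lx)[group_first_idx]
  exp(cs - base[group_id])
}
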