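# One-shot pipeline and run orchestration.

#' Clone-censor-weight point estimate from register tables
#'
#' Applies eligibility, builds the censored clone panel, fits the
#' censoring models, computes truncated inverse probability of
#' censoring weights, and fits the weighted pooled logistic outcome
#' model. Returns the point estimate; see [bootstrap_ci()] for
#' confidence intervals.
#'
#' @param persons,dispensations,events register tables.
#' @param spec a [trial_spec()].
#' @param cens_spec a [censoring_model_spec()].
#' @param weighting `"ipcw"` (default) or `"none"` for the unweighted
#'   per-protocol estimate.
#' @param return_panel also return the weighted panel (for balance
#'   tables and curves).
#' @return `ccw_estimate`; with `return_panel = TRUE`, a list
#'   `estimate`, `panel`, `exclusions`.
#' @export
estimate_ccw <- function(persons, dispensations, events, spec,
                         cens_spec = censoring_model_spec(),
                         weighting = c("ipcw", "none"),
                         return_panel = FALSE) {
  weighting <- match.arg(weighting)
  elig <- apply_eligibility(persons, dispensations, spec$eligibility)
  panel <- build_clone_panel(elig$persons, dispensations, events, spec)
  prep <- ccw_engine_prep(panel, cens_spec)
  fit <- ccw_engine_fit(prep, NULL, weighting)
  est <- new_ccw_estimate(
    log_irr = fit$log_irr, arms = prep$meta$arms,
    events = fit$weighted_events, py = fit$weighted_person_years,
    model_meta = list(time_form = cens_spec$time_form,
                      n_rows = fit$n_rows, converged = fit$converged,
                      weighting = weighting),
    extra = list(weight_diagnostics = fit$weight_diagnostics,
                 person_ids = elig$persons$person_id))
  if (!return_panel) return(est)
  panel[, weight := fit$weights]
  panel[, p_uncensored := NA_real_] # filled only by the modular path
  set_meta(panel, prep$meta)
  list(estimate = est, panel = panel, exclusions = elig$exclusions)
}

#' Read a run configuration from YAML
#'
#' A run configuration either names an input directory with register
#' CSVs or embeds a simulation block, plus trial, censoring and
#' bootstrap blocks mirroring [trial_spec()], [censoring_model_spec()]
#' and [boot_spec()] fields.
#'
#' @param path YAML file path.
#' @return `run_config` list.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  as_run_config(cfg)
}

#' @rdname read_run_config
#' @param cfg a plain list with the same structure as the YAML file.
#' @export
as_run_config <- function(cfg) {
  if (is.null(cfg$trial) || is.null(cfg$trial$outcome_type)) {
    stop_validation("run config must declare trial$outcome_type")
  }
  has_input <- !is.null(cfg$input_dir)
  has_sim <- !is.null(cfg$simulation)
  if (has_input == has_sim) {
    stop_validation(
      "exactly one of input_dir or simulation must be present")
  }
  if (is.null(cfg$seed)) cfg$seed <- 1L
  structure(cfg, class = "run_config")
}

resolve_tables <- function(config) {
  if (!is.null(config$input_dir)) {
    read_register_tables(config$input_dir)
  } else {
    sim_args <- config$simulation
    scenario <- sim_args$scenario
    sim_args$scenario <- NULL
    sim_args$seed <- derive_seed(config$seed, 1L)
    cfg <- if (!is.null(scenario)) {
      do.call(sim_scenario, c(list(scenario = scenario), sim_args))
    } else {
      do.call(sim_config, sim_args)
    }
    simulate_cohort(cfg)
  }
}

build_specs <- function(config) {
  tr <- config$trial
  el_args <- tr$eligibility
  tr$eligibility <- NULL
  elig <- if (is.null(el_args)) eligibility_spec()
          else do.call(eligibility_spec, el_args)
  spec <- do.call(trial_spec, c(tr, list(eligibility = elig)))
  cens <- if (is.null(config$censoring)) censoring_model_spec()
          else do.call(censoring_model_spec, config$censoring)
  boot <- if (is.null(config$bootstrap)) NULL
          else do.call(boot_spec, c(config$bootstrap,
                                    list(seed = derive_seed(config$seed,
                                                            2L))))
  list(trial = spec, cens = cens, boot = boot)
}

#' Run one emulated trial end to end
#'
#' Deterministic given the configuration and its master seed (split
#' into simulator and bootstrap sub-seeds). Writes, when `out_dir` is
#' set: `results.json`, `balance.csv`, `curves.csv` (first-event
#' analyses), `exclusions.csv`, and a `manifest.json` with the
#' configuration, seed and package version.
#'
#' @param config a `run_config` (see [read_run_config()] /
#'   [as_run_config()]).
#' @return result bundle: `estimate`, `balance`, `exclusions`,
#'   `weight_diagnostics`, `config`.
#' @export
run_trial <- function(config) {
  if (!inherits(config, "run_config")) config <- as_run_config(config)
  tables <- resolve_tables(config)
  if (!is.null(config$subgroup)) {
    sg <- config$subgroup
    keep <- tables$persons[[sg$column]] == sg$value
    tables$persons <- tables$persons[keep]
  }
  specs <- build_specs(config)
  if (!specs$trial$outcome_type %in% unique(tables$events$outcome_type)) {
    stop_validation("outcome type '%s' not present in events",
                    specs$trial$outcome_type)
  }
  res <- estimate_ccw(tables$persons, tables$dispensations,
                      tables$events, specs$trial, specs$cens,
                      return_panel = TRUE)
  est <- res$estimate
  if (!is.null(specs$boot)) {
    est <- bootstrap_ci(tables, specs$trial, specs$boot, specs$cens)
  }
  bal <- balance_table(res$panel)
  curves <- NULL
  if (!specs$trial$recurrent) {
    meta <- get_meta(res$panel)
    curves <- data.table::rbindlist(lapply(meta$arms, function(a) {
      cc <- cumulative_incidence_curve(res$panel, a)
      cc[, clone_arm := a]
      cc
    }))
  }
  bundle <- list(estimate = est, balance = bal, curves = curves,
                 exclusions = res$exclusions,
                 weight_diagnostics = est$weight_diagnostics,
                 config = config)
  if (!is.null(config$out_dir)) {
    write_bundle(bundle, config$out_dir)
  }
  bundle
}

write_bundle <- function(bundle, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  est <- bundle$estimate
  res_json <- list(
    outcome = bundle$config$trial$outcome_type,
    irr = est$irr, log_irr = est$log_irr,
    ci_low = est$ci_low, ci_high = est$ci_high,
    se_log_irr = est$se_log_irr,
    weighted_events = as.list(est$weighted_events),
    weighted_person_years = as.list(est$weighted_person_years),
    weighted_rate_per_1000py = as.list(est$weighted_rate_per_1000py),
    model_meta = est$model_meta
  )
  jsonlite::write_json(res_json, file.path(out_dir, "results.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  data.table::fwrite(bundle$balance, file.path(out_dir, "balance.csv"))
  if (!is.null(bundle$curves)) {
    data.table::fwrite(bundle$curves, file.path(out_dir, "curves.csv"))
  }
  data.table::fwrite(bundle$exclusions,
                     file.path(out_dir, "exclusions.csv"))
  cfg_file <- tempfile(fileext = ".yaml")
  yaml::write_yaml(unclass(bundle$config), cfg_file)
  manifest <- list(
    config = unclass(bundle$config),
    config_md5 = unname(tools::md5sum(cfg_file)),
    seed = bundle$config$seed,
    package_version = as.character(utils::packageVersion("ccwtrial")),
    r_version = paste(R.version$major, R.version$minor, sep = ".")
  )
  unlink(cfg_file)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}

#' Run a suite of trial configurations
#'
#' All configurations must share the same input data (identical
#' `input_dir`, or identical simulation block and master seed). Returns
#' one comparison row per configuration; declared subgroup pairs get a
#' Wald contrast appended.
#'
#' @param configs non-empty list of run configurations.
#' @param wald_pairs optional list of length-2 integer vectors indexing
#'   `configs` pairs to contrast (requires bootstrap blocks).
#' @return list with `table` (one row per config: label, outcome, IRR,
#'   CI, per-arm rates) and `wald` (one row per declared pair).
#' @export
run_trial_suite <- function(configs, wald_pairs = NULL) {
  if (!length(configs)) stop_validation("empty config list")
  configs <- lapply(configs, function(cfg) {
    if (!inherits(cfg, "run_config")) as_run_config(cfg) else cfg
  })
  key <- function(cfg) {
    paste(deparse(list(cfg$input_dir, cfg$simulation, cfg$seed)),
          collapse = "")
  }
  keys <- vapply(configs, key, "")
  if (length(unique(keys)) != 1L) {
    stop_validation("all configs in a suite must share input data")
  }
  bundles <- lapply(configs, run_trial)
  rows <- lapply(seq_along(bundles), function(i) {
    est <- bundles[[i]]$estimate
    lab <- configs[[i]]$label %||% sprintf("config_%d", i)
    data.table::data.table(
      label = lab, outcome = configs[[i]]$trial$outcome_type,
      recurrent = isTRUE(configs[[i]]$trial$recurrent),
      irr = est$irr, ci_low = est$ci_low, ci_high = est$ci_high,
      rate_arm1 = est$weighted_rate_per_1000py[[1L]],
      rate_arm2 = est$weighted_rate_per_1000py[[2L]]
    )
  })
  tab <- data.table::rbindlist(rows)
  wald <- NULL
  if (!is.null(wald_pairs)) {
    wald <- data.table::rbindlist(lapply(wald_pairs, function(pr) {
      wc <- wald_compare(bundles[[pr[1L]]]$estimate,
                         bundles[[pr[2L]]]$estimate)
      data.table::data.table(a = tab$label[pr[1L]], b = tab$label[pr[2L]],
                             z = wc$z, p_value = wc$p_value)
    }))
  }
  list(table = tab, wald = wald, bundles = bundles)
}
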