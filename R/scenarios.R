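#' Scenario specification
#'
#' A named bundle of overrides applied on top of a base configuration:
#' the pemigatinib price multiplier, the effectiveness measure, the
#' adverse-event duration window, the nonmedication conversion factor,
#' alternative survival laws, horizon and discount rate.
#'
#' @param name Scenario label.
#' @param price_multiplier Multiplier in `[0, 1]` on the intervention arm's
#'   annual medication cost; its uniform PSA bounds are scaled by the same
#'   multiplier.
#' @param effect_measure `"qaly"` or `"ly"`.
#' @param ae_duration_mode Optional override of the adverse-event window.
#' @param conversion_factor Optional nonmedication conversion factor; when
#'   set, the conversion-factor parameter also samples `uniform(0.8, 1)` in
#'   the PSA (its published distribution).
#' @param survival_overrides Optional named list
#'   `list(<arm> = list(os = surv_dist, pfs = surv_dist))` replacing
#'   survival laws per arm/endpoint (e.g. second-best fitting families).
#' @param horizon_years,discount_rate Optional setting overrides.
#' @return A `scenario_spec` list.
#' @export
scenario_spec <- function(name, price_multiplier = 1,
                          effect_measure = c("qaly", "ly"),
                          ae_duration_mode = NULL, conversion_factor = NULL,
                          survival_overrides = NULL, horizon_years = NULL,
                          discount_rate = NULL) {
  effect_measure <- match.arg(effect_measure)
  stopifnot(is.character(name), length(name) == 1,
            price_multiplier >= 0, price_multiplier <= 1)
  if (!is.null(ae_duration_mode)) {
    ae_duration_mode <- match.arg(ae_duration_mode,
      c("first_cycle", "first_six_months", "whole_horizon"))
  }
  structure(list(name = name, price_multiplier = price_multiplier,
                 effect_measure = effect_measure,
                 ae_duration_mode = ae_duration_mode,
                 conversion_factor = conversion_factor,
                 survival_overrides = survival_overrides,
                 horizon_years = horizon_years,
                 discount_rate = discount_rate),
            class = "scenario_spec")
}

# apply a scenario's overrides to a configuration
apply_scenario <- function(config, spec) {
  stopifnot(inherits(config, "analysis_config"),
            inherits(spec, "scenario_spec"))
  int_key <- intervention_key(config)
  if (spec$price_multiplier != 1) {
    m <- spec$price_multiplier
    config$arms[[int_key]]$medication_cost_per_year <-
      m * config$arms[[int_key]]$medication_cost_per_year
    ps <- config$parameters[["cost_med_pem"]]
    if (!is.null(ps)) {
      ps$base <- m * ps$base; ps$low <- m * ps$low; ps$high <- m * ps$high
      if (ps$dist == "uniform") ps$args <- m * ps$args
      config$parameters[["cost_med_pem"]] <- ps
    }
  }
  if (!is.null(spec$ae_duration_mode)) {
    config$utilities$ae_duration_mode <- spec$ae_duration_mode
  }
  if (!is.null(spec$conversion_factor)) {
    config$costs$nonmedication_conversion_factor <- spec$conversion_factor
    config$parameters[["conversion_factor"]] <-
      param_spec("conversion_factor", spec$conversion_factor,
                 low = 0.8, high = 1, dist = "uniform", args = c(0.8, 1))
  }
  if (!is.null(spec$horizon_years)) {
    config$settings$horizon_years <- spec$horizon_years
  }
  if (!is.null(spec$discount_rate)) {
    config$settings$annual_discount_rate <- spec$discount_rate
  }
  if (!is.null(spec$survival_overrides)) {
    for (arm in names(spec$survival_overrides)) {
      if (!arm %in% names(config$arms)) {
        stop("survival override for unknown arm: ", arm, call. = FALSE)
      }
      ov <- spec$survival_overrides[[arm]]
      extra <- setdiff(names(ov), c("os", "pfs"))
      if (length(extra)) {
        stop("unknown survival override keys: ",
             paste(extra, collapse = ", "), call. = FALSE)
      }
      for (ep in names(ov)) {
        d <- ov[[ep]]
        stopifnot(inherits(d, "surv_dist"))
        config$arms[[arm]][[ep]] <- list(family = d$family, params = d$params)
      }
    }
  }
  config$settings <- do.call(model_settings,
    config$settings[c("horizon_years", "cycles_per_year",
                      "annual_discount_rate", "wtp_per_qaly",
                      "half_cycle_correction")])
  config
}

#' Run one scenario (deterministic, optionally with PSA)
#'
#' Applies the scenario overrides, reruns the deterministic base case and,
#' when `psa_n > 0`, a probabilistic sensitivity analysis. Incremental
#' results use the scenario's effectiveness measure.
#'
#' @param config Base `analysis_config`.
#' @param spec A [scenario_spec()].
#' @param psa_n PSA draws (0 to skip the PSA).
#' @param seed PSA master seed.
#' @return A `scenario_result`: `name`, `base_case`, `incremental` (one row
#'   per comparator with the scenario's effect measure), and `psa_summary`
#'   (`NULL` when skipped).
#' @export
run_scenario <- function(config, spec, psa_n = 0, seed = config$seed) {
  cfg <- apply_scenario(config, spec)
  bc <- run_base_case(cfg)
  em <- spec$effect_measure
  inc <- data.frame(
    scenario = spec$name, comparator = bc$incremental$comparator,
    effect_measure = em, delta_cost = bc$incremental$delta_cost,
    delta_effect = bc$incremental[[paste0("delta_", em)]],
    icer = bc$incremental[[paste0("icer_", em)]],
    inmb = bc$incremental[[paste0("inmb_", em)]])
  psa_summary <- NULL
  if (psa_n > 0) {
    psa <- run_psa(cfg, n = psa_n, seed = seed)
    wtp <- cfg$settings$wtp_per_qaly
    psa_summary <- psa$summary
    if (em == "ly") {
      # probability of cost-effectiveness on the life-year scale
      psa_summary$p_ce <- vapply(psa$comparators, function(cm) {
        mean(wtp * psa$draws[[paste0("d_ly_", cm)]] -
               psa$draws[[paste0("d_cost_", cm)]] > 0)
      }, numeric(1))
      psa_summary$evpi <- vapply(psa$comparators, function(cm) {
        evpi_from_nmb(cbind(0, wtp * psa$draws[[paste0("d_ly_", cm)]] -
                              psa$draws[[paste0("d_cost_", cm)]]))
      }, numeric(1))
    }
    psa_summary$scenario <- spec$name
  }
  structure(list(name = spec$name, base_case = bc, incremental = inc,
                 psa_summary = psa_summary, config = cfg),
            class = "scenario_result")
}

#' Pemigatinib price-reduction grid
#'
#' Reruns the model with the intervention arm's annual medication cost (and
#' its uniform PSA sampling bounds) scaled by `1 - reduction` for each
#' reduction on the grid, reporting deterministic ICER and INMB and, when
#' `psa_n > 0`, the probability of cost-effectiveness at the configured
#' willingness-to-pay threshold.
#'
#' @param config Base `analysis_config`.
#' @param reductions Price reductions in `[0, 1]` (default 0 to 60% in 10%
#'   steps).
#' @param psa_n PSA draws per grid point (0 to skip).
#' @param seed PSA master seed (same seed per point: common random numbers).
#' @return Data frame, one row per reduction x comparator: `reduction`,
#'   `comparator`, `delta_cost`, `delta_qaly`, `icer_qaly`, `inmb_qaly`,
#'   `p_ce`, `evpi`.
#' @export
price_reduction_grid <- function(config, reductions = seq(0, 0.6, by = 0.1),
                                 psa_n = 0, seed = config$seed) {
  stopifnot(all(reductions >= 0), all(reductions <= 1))
  rows <- lapply(reductions, function(r) {
    sp <- scenario_spec(sprintf("price_reduction_%.0f%%", 100 * r),
                        price_multiplier = 1 - r)
    sr <- run_scenario(config, sp, psa_n = psa_n, seed = seed)
    out <- data.frame(reduction = r,
                      comparator = sr$incremental$comparator,
                      delta_cost = sr$incremental$delta_cost,
                      delta_qaly = sr$incremental$delta_effect,
                      icer_qaly = sr$incremental$icer,
                      inmb_qaly = sr$incremental$inmb)
    if (!is.null(sr$psa_summary)) {
      out$p_ce <- sr$psa_summary$p_ce
      out$evpi <- sr$psa_summary$evpi
    }
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' The standard scenario battery
#'
#' The set of structural scenarios evaluated alongside the price grid:
#' life-year effectiveness, adverse events accruing every cycle over the
#' first six months and over the whole horizon, and the 0.9 nonmedication
#' conversion factor.
#'
#' @return Named list of [scenario_spec()] objects.
#' @export
standard_scenarios <- function() {
  list(
    base = scenario_spec("base"),
    life_years = scenario_spec("life_years", effect_measure = "ly"),
    ae_first_six_months = scenario_spec("ae_first_six_months",
                                        ae_duration_mode = "first_six_months"),
    ae_whole_horizon = scenario_spec("ae_whole_horizon",
                                     ae_duration_mode = "whole_horizon"),
    conversion_factor_0.9 = scenario_spec("conversion_factor_0.9",
                                          conversion_factor = 0.9))
}

#' Run the full scenario battery
#'
#' @param config Base `analysis_config`.
#' @param scenarios List of [scenario_spec()]s (default
#'   [standard_scenarios()]).
#' @param psa_n PSA draws per scenario (0 to skip).
#' @param seed Master seed.
#' @return Data frame, one row per scenario x comparator, combining the
#'   deterministic increments with the PSA probability of
#'   cost-effectiveness and EVPI when run.
#' @export
run_all_scenarios <- function(config, scenarios = standard_scenarios(),
                              psa_n = 0, seed = config$seed) {
  rows <- lapply(scenarios, function(sp) {
    sr <- run_scenario(config, sp, psa_n = psa_n, seed = seed)
    out <- sr$incremental
    if (!is.null(sr$psa_summary)) {
      out$p_ce <- sr$psa_summary$p_ce
      out$evpi <- sr$psa_summary$evpi
    }
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
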