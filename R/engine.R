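#' Model settings for the partitioned survival cohort simulation
#'
#' Defaults reproduce the reference evaluation: a 5-year horizon, monthly
#' cycles, 3% annual discounting of both costs and health outcomes, and a
#' willingness-to-pay threshold of three times Taiwan's forecast 2022 GDP
#' per capita (NT$2,928,570 per QALY).
#'
#' @param horizon_years Model horizon in years, `> 0`.
#' @param cycles_per_year Number of cycles per year (12 = monthly).
#' @param annual_discount_rate Annual discount rate in `[0, 1)`, applied in
#'   continuous time as `(1 + r)^(-t)`.
#' @param wtp_per_qaly Willingness-to-pay threshold, NT$ per QALY.
#' @param half_cycle_correction If `TRUE` (default) state occupancy is
#'   evaluated at cycle midpoints (trapezoid-style correction); if `FALSE`
#'   at cycle ends.
#' @return A `model_settings` list.
#' @export
model_settings <- function(horizon_years = 5, cycles_per_year = 12,
                           annual_discount_rate = 0.03,
                           wtp_per_qaly = 2928570,
                           half_cycle_correction = TRUE) {
  stopifnot(horizon_years > 0, cycles_per_year >= 1,
            annual_discount_rate >= 0, annual_discount_rate < 1,
            wtp_per_qaly >= 0, is.logical(half_cycle_correction))
  structure(list(horizon_years = horizon_years,
                 cycles_per_year = cycles_per_year,
                 cycle_length_years = 1 / cycles_per_year,
                 annual_discount_rate = annual_discount_rate,
                 wtp_per_qaly = wtp_per_qaly,
                 half_cycle_correction = half_cycle_correction),
            class = "model_settings")
}

#' Health-state utilities and disutilities
#'
#' @param u_pf Utility of the progression-free state (default 0.76).
#' @param u_pd Utility of the progressed-disease state (default 0.68).
#' @param disutility_ae Disutility of a grade >= 3 adverse event (0.16),
#'   applied to the affected proportion of the cohort.
#' @param disutility_iv Disutility of intravenous/subcutaneous
#'   administration (0.025), applied to the PF state of IV arms.
#' @param ae_duration_mode When the adverse-event decrement accrues:
#'   `"first_cycle"` (default; a one-off decrement of one cycle length at
#'   model start), `"first_six_months"` or `"whole_horizon"` (per-cycle
#'   decrement weighted by the proportion still alive).
#' @return A `utility_inputs` list.
#' @export
utility_inputs <- function(u_pf = 0.76, u_pd = 0.68, disutility_ae = 0.16,
                           disutility_iv = 0.025,
                           ae_duration_mode = c("first_cycle",
                                                "first_six_months",
                                                "whole_horizon")) {
  ae_duration_mode <- match.arg(ae_duration_mode)
  for (v in c(u_pf, u_pd, disutility_ae, disutility_iv)) {
    if (v < 0 || v > 1) {
      stop("utilities and disutilities must lie in [0, 1]", call. = FALSE)
    }
  }
  structure(list(u_pf = u_pf, u_pd = u_pd, disutility_ae = disutility_ae,
                 disutility_iv = disutility_iv,
                 ae_duration_mode = ae_duration_mode),
            class = "utility_inputs")
}

#' Shared cost inputs (2022 NT$)
#'
#' Arm-specific medication and nonmedication rates live on the
#' [strategy_arm()]; this object carries the costs shared across arms.
#'
#' @param supportive_care_per_year Annual supportive-care cost accrued in the
#'   progressed-disease state (NT$497,710).
#' @param genetic_testing_fee One-off FGFR2 genetic testing fee at model
#'   start (NT$30,000).
#' @param testing_policy Which arms incur the testing fee: `"none"`,
#'   `"intervention_only"` (default; reconciles the reference cost table) or
#'   `"all_arms"`.
#' @param nonmedication_conversion_factor Multiplier in `(0, 1]` applied to
#'   nonmedication rates (scenario value 0.9; base case 1).
#' @return A `cost_inputs` list.
#' @export
cost_inputs <- function(supportive_care_per_year = 497710,
                        genetic_testing_fee = 30000,
                        testing_policy = c("intervention_only", "none",
                                           "all_arms"),
                        nonmedication_conversion_factor = 1) {
  testing_policy <- match.arg(testing_policy)
  stopifnot(supportive_care_per_year >= 0, genetic_testing_fee >= 0,
            nonmedication_conversion_factor > 0,
            nonmedication_conversion_factor <= 1)
  structure(list(supportive_care_per_year = supportive_care_per_year,
                 genetic_testing_fee = genetic_testing_fee,
                 testing_policy = testing_policy,
                 nonmedication_conversion_factor =
                   nonmedication_conversion_factor),
            class = "cost_inputs")
}

#' One treatment strategy arm
#'
#' @param name Arm label.
#' @param os,pfs Survival curves (a [surv_dist()], [km_estimate()] curve or
#'   [build_hybrid()] object) for overall and progression-free survival.
#' @param medication_cost_per_year Annual second-line medication cost (NT$)
#'   accrued while progression-free.
#' @param nonmedication_cost_per_year Annual nonmedication expenditure (NT$)
#'   accrued while progression-free.
#' @param ae_grade3_proportion Proportion of patients with a grade >= 3
#'   adverse event, in `[0, 1]`.
#' @param iv_administered `TRUE` for intravenously administered regimens
#'   (the administration-route disutility applies).
#' @param is_intervention `TRUE` for the intervention arm (governs the
#'   genetic-testing fee under policy `"intervention_only"`).
#' @return A `strategy_arm` list.
#' @export
strategy_arm <- function(name, os, pfs, medication_cost_per_year,
                         nonmedication_cost_per_year, ae_grade3_proportion,
                         iv_administered, is_intervention = FALSE) {
  stopifnot(is.character(name), length(name) == 1,
            medication_cost_per_year >= 0, nonmedication_cost_per_year >= 0,
            ae_grade3_proportion >= 0, ae_grade3_proportion <= 1,
            is.logical(iv_administered), is.logical(is_intervention))
  for (curve in list(os, pfs)) {
    if (!inherits(curve, c("surv_dist", "km_curve", "hybrid_surv"))) {
      stop("os and pfs must be survival curve objects", call. = FALSE)
    }
  }
  structure(list(name = name, os = os, pfs = pfs,
                 medication_cost_per_year = medication_cost_per_year,
                 nonmedication_cost_per_year = nonmedication_cost_per_year,
                 ae_grade3_proportion = ae_grade3_proportion,
                 iv_administered = iv_administered,
                 is_intervention = is_intervention),
            class = "strategy_arm")
}

#' @export
print.strategy_arm <- function(x, ...) {
  cat(sprintf("<strategy_arm> %s%s: med %s/yr, nonmed %s/yr, AE %.0f%%, %s\n",
              x$name, if (x$is_intervention) " (intervention)" else "",
              format(x$medication_cost_per_year, big.mark = ","),
              format(x$nonmedication_cost_per_year, big.mark = ","),
              100 * x$ae_grade3_proportion,
              if (x$iv_administered) "IV" else "oral"))
  invisible(x)
}

#' Per-cycle state occupancy of the partitioned survival model
#'
#' Health-state membership is read directly off the survival curves:
#' progression-free `pf(t) = min(PFS(t), OS(t))` (clipping guarantees
#' non-negative progressed occupancy), progressed `pd(t) = OS(t) - pf(t)`,
#' dead `1 - OS(t)`. Occupancy is evaluated at cycle midpoints when the
#' half-cycle correction is on, otherwise at cycle ends, together with the
#' continuous-time discount factor at the same time point.
#'
#' @param os,pfs Survival curve objects (months time scale).
#' @param settings A [model_settings()] object.
#' @return A `cohort_trace` data frame: `cycle`, `t_months` (evaluation
#'   time), `pf`, `pd`, `dead`, `v` (discount factor), plus attributes
#'   carrying the settings.
#' @export
state_occupancy <- function(os, pfs, settings = model_settings()) {
  stopifnot(inherits(settings, "model_settings"))
  n_cycles <- round(settings$horizon_years * settings$cycles_per_year)
  dt_m <- 12 / settings$cycles_per_year        # cycle length, months
  t_end <- seq_len(n_cycles) * dt_m
  t_eval <- if (settings$half_cycle_correction) t_end - dt_m / 2 else t_end
  s_os <- surv_prob(os, t_eval)
  s_pf <- pmin(surv_prob(pfs, t_eval), s_os)
  trace <- data.frame(cycle = seq_len(n_cycles), t_months = t_eval,
                      pf = s_pf, pd = s_os - s_pf, dead = 1 - s_os,
                      v = (1 + settings$annual_discount_rate)^(-t_eval / 12))
  class(trace) <- c("cohort_trace", "data.frame")
  attr(trace, "settings") <- settings
  trace
}

#' Accrue discounted costs, life-years and QALYs over a cohort trace
#'
#' Per cycle of length `dt` years with discount factor `v`:
#' * life-years `+= (pf + pd) * dt * v`
#' * QALYs `+= [pf * (u_pf - iv * disutility_iv) + pd * u_pd] * dt * v`
#' * costs `+= pf * (med_rate + conv * nonmed_rate) * dt * v`
#'   `+ pd * supportive_rate * dt * v`
#'
#' The adverse-event QALY decrement `ae_proportion * disutility_ae` is a
#' one-off loss of one cycle length applied undiscounted at model start
#' (default `"first_cycle"` mode), or a per-cycle loss weighted by the
#' proportion alive over the first six months / the whole horizon. The
#' genetic testing fee is charged undiscounted at `t = 0` per policy.
#'
#' @param trace A [state_occupancy()] trace.
#' @param arm A [strategy_arm()].
#' @param costs A [cost_inputs()].
#' @param utilities A [utility_inputs()].
#' @param settings The same [model_settings()] used for the trace.
#' @return An `arm_outcomes` list of discounted totals: `ly_pf`, `ly_total`,
#'   `qaly_pf`, `qaly_total`, `cost_medication`, `cost_nonmedication`,
#'   `cost_pd_supportive`, `cost_testing`, `cost_total`.
#' @export
accrue <- function(trace, arm, costs, utilities,
                   settings = attr(trace, "settings")) {
  stopifnot(inherits(trace, "cohort_trace"), inherits(arm, "strategy_arm"),
            inherits(costs, "cost_inputs"),
            inherits(utilities, "utility_inputs"),
            inherits(settings, "model_settings"))
  dt <- settings$cycle_length_years
  pf <- trace$pf; pd <- trace$pd; v <- trace$v

  ly_pf <- sum(pf * v) * dt
  ly_total <- sum((pf + pd) * v) * dt
  u_pf_eff <- utilities$u_pf -
    (if (arm$iv_administered) utilities$disutility_iv else 0)
  qaly_pf <- sum(pf * v) * dt * u_pf_eff
  qaly_pd <- sum(pd * v) * dt * utilities$u_pd

  ae_rate <- arm$ae_grade3_proportion * utilities$disutility_ae
  ae_loss <- switch(utilities$ae_duration_mode,
    first_cycle = ae_rate * dt,
    first_six_months = {
      idx <- trace$t_months <= 6
      ae_rate * sum((pf + pd)[idx] * v[idx]) * dt
    },
    whole_horizon = ae_rate * sum((pf + pd) * v) * dt)

  qaly_pf <- qaly_pf - ae_loss
  conv <- costs$nonmedication_conversion_factor
  cost_med <- ly_pf * arm$medication_cost_per_year
  cost_nonmed <- ly_pf * conv * arm$nonmedication_cost_per_year
  cost_pd <- (ly_total - ly_pf) * costs$supportive_care_per_year
  cost_testing <- switch(costs$testing_policy,
    none = 0,
    intervention_only = if (arm$is_intervention) costs$genetic_testing_fee else 0,
    all_arms = costs$genetic_testing_fee)

  structure(list(
    arm = arm$name,
    ly_pf = ly_pf, ly_total = ly_total,
    qaly_pf = qaly_pf, qaly_total = qaly_pf + qaly_pd,
    cost_medication = cost_med, cost_nonmedication = cost_nonmed,
    cost_pd_supportive = cost_pd, cost_testing = cost_testing,
    cost_total = cost_med + cost_nonmed + cost_pd + cost_testing),
    class = "arm_outcomes")
}

#' @export
print.arm_outcomes <- function(x, ...) {
  cat(sprintf(paste0("<arm_outcomes> %s: LY %.3f (PF %.3f), QALY %.3f ",
                     "(PF %.3f), cost NT$%s\n"),
              x$arm, x$ly_total, x$ly_pf, x$qaly_total, x$qaly_pf,
              format(round(x$cost_total), big.mark = ",")))
  invisible(x)
}

#' Run one strategy arm end to end
#'
#' Convenience composition of [state_occupancy()] and [accrue()].
#'
#' @inheritParams accrue
#' @param arm A [strategy_arm()].
#' @param settings A [model_settings()].
#' @return An `arm_outcomes` list.
#' @export
run_arm <- function(arm, costs, utilities, settings = model_settings()) {
  trace <- state_occupancy(arm$os, arm$pfs, settings)
  accrue(trace, arm, costs, utilities, settings)
}
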