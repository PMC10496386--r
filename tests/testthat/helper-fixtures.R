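# shared fixtures built in code

base_cfg <- function() default_config()

# hand-built arm outcomes for incremental-metric tests
fake_outcomes <- function(arm, cost, qaly, ly = qaly) {
  structure(list(arm = arm, cost_total = cost, qaly_total = qaly,
                 ly_total = ly), class = "arm_outcomes")
}

# minimal psa_result carrying per-draw increments for one comparison
fake_psa <- function(d_cost, d_effect, wtp = 2928570, comparator = "comp") {
  draws <- data.frame(a = d_cost, b = d_effect)
  names(draws) <- paste0(c("d_cost_", "d_effect_"), comparator)
  structure(list(draws = draws, wtp = wtp, comparators = comparator,
                 n = length(d_cost), seed = 0), class = "psa_result")
}

# independent continuous-time oracle for the accrual quantities: adaptive
# quadrature on the survival curves, never the cycle engine
integrate_arm_oracle <- function(arm, costs, utilities, settings) {
  r <- settings$annual_discount_rate
  h <- settings$horizon_years * 12
  v <- function(t) (1 + r)^(-t / 12)
  s_os <- function(t) surv_prob(arm$os, t)
  s_pf <- function(t) pmin(surv_prob(arm$pfs, t), s_os(t))
  int <- function(f) stats::integrate(f, 0, h, subdivisions = 2000L,
                                      rel.tol = 1e-10)$value / 12
  ly_pf <- int(function(t) s_pf(t) * v(t))
  ly_total <- int(function(t) s_os(t) * v(t))
  u_pf <- utilities$u_pf - if (arm$iv_administered) utilities$disutility_iv else 0
  ae_loss <- arm$ae_grade3_proportion * utilities$disutility_ae *
    settings$cycle_length_years
  qaly_total <- ly_pf * u_pf + (ly_total - ly_pf) * utilities$u_pd - ae_loss
  conv <- costs$nonmedication_conversion_factor
  testing <- switch(costs$testing_policy,
    none = 0,
    intervention_only = if (arm$is_intervention) costs$genetic_testing_fee else 0,
    all_arms = costs$genetic_testing_fee)
  cost_total <- ly_pf * (arm$medication_cost_per_year +
                           conv * arm$nonmedication_cost_per_year) +
    (ly_total - ly_pf) * costs$supportive_care_per_year + testing
  list(ly_pf = ly_pf, ly_total = ly_total, qaly_total = qaly_total,
       cost_total = cost_total)
}
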