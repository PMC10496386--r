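cfg <- base_cfg()
arms <- build_arms(cfg)

test_that("state occupancy conserves the cohort and respects the curves", {
  for (arm in arms) {
    tr <- state_occupancy(arm$os, arm$pfs, cfg$settings)
    expect_true(all(abs(tr$pf + tr$pd + tr$dead - 1) < 1e-10))
    expect_true(all(tr$pf >= 0 & tr$pf <= 1))
    expect_true(all(tr$pd >= 0 & tr$pd <= 1))
    expect_true(all(diff(tr$pf) <= 1e-12))  # proper PFS law: non-increasing
  }
  # everyone starts progression-free and alive
  expect_equal(surv_prob(arms[[1]]$os, 0), 1)
  expect_equal(surv_prob(arms[[1]]$pfs, 0), 1)
})

test_that("identical OS and PFS curves leave nobody in the progressed state", {
  os <- surv_dist("weibull", c(22.065, 1.536))
  tr <- state_occupancy(os, os, cfg$settings)
  expect_true(all(tr$pd == 0))
})

test_that("accrual is linear: zero rates give zero costs and QALYs", {
  zero_cost <- cost_inputs(supportive_care_per_year = 0,
                           genetic_testing_fee = 0, testing_policy = "none")
  zero_util <- utility_inputs(u_pf = 0, u_pd = 0, disutility_ae = 0,
                              disutility_iv = 0)
  arm <- arms$pemigatinib
  arm$medication_cost_per_year <- 0
  arm$nonmedication_cost_per_year <- 0
  out <- run_arm(arm, zero_cost, zero_util, cfg$settings)
  expect_equal(out$cost_total, 0)
  expect_equal(out$qaly_total, 0)
  expect_gt(out$ly_total, 0)
})

test_that("with utilities 1 and disutilities 0, QALYs equal life-years", {
  perfect <- utility_inputs(u_pf = 1, u_pd = 1, disutility_ae = 0,
                            disutility_iv = 0)
  for (arm in arms) {
    out <- run_arm(arm, cfg$costs, perfect, cfg$settings)
    expect_equal(out$qaly_total, out$ly_total, tolerance = 1e-12)
    expect_equal(out$qaly_pf, out$ly_pf, tolerance = 1e-12)
  }
})

test_that("cycle-sum accrual agrees with adaptive quadrature within 0.2%", {
  for (arm in arms) {
    out <- run_arm(arm, cfg$costs, cfg$utilities, cfg$settings)
    oracle <- integrate_arm_oracle(arm, cfg$costs, cfg$utilities, cfg$settings)
    for (f in names(oracle)) {
      expect_equal(out[[f]], oracle[[f]], tolerance = 0.002,
                   label = sprintf("%s / %s", arm$name, f))
    }
  }
})

test_that("halving the cycle length moves totals by less than 0.1%", {
  fine <- cfg$settings
  fine$cycles_per_year <- 24
  fine$cycle_length_years <- 1 / 24
  for (arm in arms) {
    coarse_out <- run_arm(arm, cfg$costs, cfg$utilities, cfg$settings)
    fine_out <- run_arm(arm, cfg$costs, cfg$utilities, fine)
    # the one-off AE decrement is one cycle long by definition, so compare
    # quantities that are invariant to the cycle convention
    expect_equal(fine_out$ly_total, coarse_out$ly_total, tolerance = 1e-3)
    expect_equal(fine_out$cost_total, coarse_out$cost_total, tolerance = 1e-3)
    qaly_coarse <- coarse_out$qaly_total +
      arm$ae_grade3_proportion * cfg$utilities$disutility_ae / 12
    qaly_fine <- fine_out$qaly_total +
      arm$ae_grade3_proportion * cfg$utilities$disutility_ae / 24
    expect_equal(qaly_fine, qaly_coarse, tolerance = 1e-3)
  }
})

test_that("cost components equal annual rates times discounted state-years", {
  out <- run_arm(arms$mfolfox, cfg$costs, cfg$utilities, cfg$settings)
  expect_equal(out$cost_medication,
               out$ly_pf * arms$mfolfox$medication_cost_per_year)
  expect_equal(out$cost_pd_supportive,
               (out$ly_total - out$ly_pf) * cfg$costs$supportive_care_per_year)
  expect_equal(out$cost_total,
               out$cost_medication + out$cost_nonmedication +
                 out$cost_pd_supportive + out$cost_testing)
  expect_lte(out$qaly_total, out$ly_total)
  expect_lte(out$ly_pf, out$ly_total)
})

test_that("removing discounting increases every accrued quantity", {
  undisc <- cfg$settings
  undisc$annual_discount_rate <- 0
  for (arm in arms) {
    disc_out <- run_arm(arm, cfg$costs, cfg$utilities, cfg$settings)
    undisc_out <- run_arm(arm, cfg$costs, cfg$utilities, undisc)
    for (f in c("ly_total", "qaly_total", "cost_total")) {
      expect_gt(undisc_out[[f]], disc_out[[f]])
    }
  }
})

test_that("the genetic testing fee follows the arm policy", {
  run_tot <- function(policy, arm) {
    run_arm(arm, cost_inputs(testing_policy = policy), cfg$utilities,
            cfg$settings)$cost_testing
  }
  expect_equal(run_tot("none", arms$pemigatinib), 0)
  expect_equal(run_tot("intervention_only", arms$pemigatinib), 30000)
  expect_equal(run_tot("intervention_only", arms$mfolfox), 0)
  expect_equal(run_tot("all_arms", arms$fu), 30000)
})

test_that("adverse-event windows order QALYs: one cycle < six months < horizon", {
  qaly_mode <- function(mode) {
    u <- utility_inputs(ae_duration_mode = mode)
    run_arm(arms$mfolfox, cfg$costs, u, cfg$settings)$qaly_total
  }
  expect_gt(qaly_mode("first_cycle"), qaly_mode("first_six_months"))
  expect_gt(qaly_mode("first_six_months"), qaly_mode("whole_horizon"))
})
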