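cfg <- base_cfg()

test_that("a zero price reduction reproduces the base case exactly", {
  bc <- run_base_case(cfg)
  sr <- run_scenario(cfg, scenario_spec("null", price_multiplier = 1))
  expect_equal(sr$incremental$delta_cost, bc$incremental$delta_cost)
  expect_equal(sr$incremental$icer, bc$incremental$icer_qaly)
})

test_that("INMB rises strictly and linearly with the price reduction", {
  grid <- price_reduction_grid(cfg, reductions = seq(0, 0.6, 0.1), psa_n = 0)
  for (cm in unique(grid$comparator)) {
    v <- grid$inmb_qaly[grid$comparator == cm]
    expect_true(all(diff(v) > 0))
    # linear in the price multiplier: constant second differences
    expect_lt(max(abs(diff(diff(v)))), 1e-6)
    # effects are untouched by a pure price change
    expect_equal(sd(grid$delta_qaly[grid$comparator == cm]), 0)
  }
})

test_that("price reductions rescale the uniform PSA bounds of the drug cost", {
  cfg50 <- psmcea:::apply_scenario(cfg, scenario_spec("half",
                                                      price_multiplier = 0.5))
  sp <- cfg50$parameters$cost_med_pem
  expect_equal(sp$args, 0.5 * c(3252150, 5420250))
  expect_equal(sp$base, 0.5 * 4336200)
  expect_equal(cfg50$arms$pemigatinib$medication_cost_per_year,
               0.5 * 4336200)
})

test_that("life-year ICERs are below QALY ICERs for both comparators", {
  bc <- run_base_case(cfg)
  expect_true(all(bc$incremental$icer_ly < bc$incremental$icer_qaly))
  expect_true(all(bc$incremental$delta_ly > bc$incremental$delta_qaly))
  sr <- run_scenario(cfg, scenario_spec("ly", effect_measure = "ly"))
  expect_equal(sr$incremental$icer, bc$incremental$icer_ly)
})

test_that("scenario overrides apply and invalid overrides fail loudly", {
  sr <- run_scenario(cfg, scenario_spec("conv", conversion_factor = 0.9))
  bc <- run_base_case(cfg)
  # cheaper comparator nonmedication costs widen the incremental cost
  expect_true(all(sr$incremental$delta_cost > bc$incremental$delta_cost))

  alt <- scenario_spec("alt-surv", survival_overrides = list(
    mfolfox = list(os = surv_dist("weibull", c(9, 1.2)))))
  sr2 <- run_scenario(cfg, alt)
  expect_false(isTRUE(all.equal(sr2$incremental$delta_qaly,
                                bc$incremental$delta_qaly)))

  expect_error(run_scenario(cfg, scenario_spec("bad", survival_overrides =
    list(nosucharm = list(os = surv_dist("weibull", c(9, 1.2)))))),
    "unknown arm")
  expect_error(run_scenario(cfg, scenario_spec("bad2", survival_overrides =
    list(mfolfox = list(ttp = surv_dist("weibull", c(9, 1.2)))))),
    "unknown survival override keys")
  expect_error(scenario_spec("neg", price_multiplier = -0.1))
})

test_that("the scenario battery returns one row per scenario and comparator", {
  res <- run_all_scenarios(cfg, psa_n = 0)
  expect_equal(nrow(res), length(standard_scenarios()) * 2)
  expect_setequal(unique(res$scenario), names(standard_scenarios()))
  # adverse events accruing longer can only lower the incremental QALY edge
  base_dq <- res$delta_effect[res$scenario == "base" &
                                res$comparator == "mFOLFOX"]
  ae6_dq <- res$delta_effect[res$scenario == "ae_first_six_months" &
                               res$comparator == "mFOLFOX"]
  expect_false(isTRUE(all.equal(base_dq, ae6_dq)))
})
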