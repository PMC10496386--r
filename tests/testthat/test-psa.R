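cfg <- base_cfg()

test_that("PSA draws reproduce the configured distribution means", {
  n <- 1e5
  specs <- cfg$parameters[c("u_pf", "u_pd", "disutility_ae",
                            "cost_med_mfolfox", "cost_supportive",
                            "cost_med_pem", "genetic_testing_fee")]
  draws <- sample_params(specs, n, seed = 7)
  expect_equal(mean(draws$u_pf), 4.7 / (4.7 + 1.5), tolerance = 0.01)
  expect_equal(mean(draws$u_pd), 29 / (29 + 13.6), tolerance = 0.01)
  expect_equal(mean(draws$disutility_ae), 36 / (36 + 193), tolerance = 0.01)
  # gamma descriptors are (mean, sd): moment-matched draws recover the mean
  expect_equal(mean(draws$cost_med_mfolfox), 412087, tolerance = 0.01)
  expect_equal(mean(draws$cost_supportive), 497710, tolerance = 0.01)
  expect_equal(sd(draws$cost_med_mfolfox), 617747, tolerance = 0.02)
  expect_true(all(draws$cost_med_pem >= 3252150 &
                    draws$cost_med_pem <= 5420250))
  expect_true(all(draws$genetic_testing_fee >= 22500 &
                    draws$genetic_testing_fee <= 37500))
})

test_that("strictly positive parameters are truncated, never negative", {
  sp <- param_spec("os_pem_shape", 0.2, 0.1, 0.4, dist = "normal",
                   args = c(0.2, 2))  # heavy mass below zero before truncation
  x <- sample_params(list(sp), 2000, seed = 5)$os_pem_shape
  expect_true(all(x > 0))
})

test_that("per-parameter substreams make draws stable under spec changes", {
  full <- sample_params(cfg$parameters, 50, seed = 3)
  subset <- sample_params(cfg$parameters[c("u_pf", "cost_med_pem")], 50,
                          seed = 3)
  expect_identical(full$u_pf, subset$u_pf)
  expect_identical(full$cost_med_pem, subset$cost_med_pem)
})

test_that("the PSA is bit-reproducible for a fixed seed", {
  a <- run_psa(cfg, n = 40, seed = 9)
  b <- run_psa(cfg, n = 40, seed = 9)
  expect_identical(a$draws, b$draws)
  expect_identical(a$summary, b$summary)
  c <- run_psa(cfg, n = 40, seed = 10)
  expect_false(identical(a$draws, c$draws))
  # every sampled value within its distribution's support
  expect_true(all(a$draws$u_pf > 0 & a$draws$u_pf < 1))
  expect_true(all(a$draws$os_pem_scale > 0))
})

test_that("PSA mean increments stay near the deterministic base case", {
  psa <- run_psa(cfg, n = 5000, seed = 1)
  bc <- run_base_case(cfg)
  expect_equal(psa$summary$mean_d_qaly[psa$summary$comparator_key == "mfolfox"],
               bc$incremental$delta_qaly[bc$incremental$comparator == "mFOLFOX"],
               tolerance = 0.15)
  expect_equal(psa$summary$mean_d_cost[psa$summary$comparator_key == "fu"],
               bc$incremental$delta_cost[bc$incremental$comparator == "5-FU"],
               tolerance = 0.15)
})

test_that("tornado bounds at the base value reproduce the base case", {
  cfg2 <- cfg
  cfg2$parameters <- lapply(cfg$parameters, function(sp) {
    sp$low <- sp$base; sp$high <- sp$base; sp
  })
  tor <- one_way_dsa(cfg2, comparison = "mfolfox")
  expect_true(all(abs(tor$output_low - tor$output_base) < 1e-9))
  expect_true(all(abs(tor$output_high - tor$output_base) < 1e-9))
  expect_true(all(tor$swing < 1e-9))
})

test_that("a parameter with no model influence has zero tornado swing", {
  cfg2 <- cfg
  cfg2$costs$testing_policy <- "none"
  tor <- one_way_dsa(cfg2, comparison = "mfolfox")
  expect_equal(tor$swing[tor$parameter == "genetic_testing_fee"], 0)
})

test_that("tornado rows are sorted by swing with the known top drivers", {
  tor <- one_way_dsa(cfg, comparison = "mfolfox")
  expect_true(all(diff(tor$swing) <= 0))
  top8 <- tor$parameter[1:8]
  expect_true("cost_med_pem" %in% tor$parameter[1:3])
  expect_true(all(c("u_pf", "u_pd") %in% top8))
  expect_true(any(c("os_pem_scale", "os_pem_shape") %in% top8))
})

test_that("a zero discount bound yields more QALYs than the 5% bound", {
  qaly_at <- function(r) {
    out <- run_model(apply_params(cfg, c(discount_rate = r)))
    vapply(out, `[[`, numeric(1), "qaly_total")
  }
  expect_true(all(qaly_at(0) > qaly_at(0.05)))
})
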