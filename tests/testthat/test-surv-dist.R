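test_that("survivor functions match their closed forms and start at 1", {
  wb <- surv_dist("weibull", c(22.065, 1.536))
  ln <- surv_dist("lognormal", c(1.834, 0.873))
  expect_equal(surv_prob(wb, 0), 1)
  expect_equal(surv_prob(ln, 0), 1)
  # t = scale puts the Weibull exponent at -1
  expect_equal(surv_prob(wb, 22.065), exp(-1), tolerance = 1e-12)
  # the log-normal median is exp(meanlog)
  expect_equal(surv_prob(ln, exp(1.834)), 0.5, tolerance = 1e-12)
})

test_that("generalized gamma reduces to Weibull (Q = 1) and log-normal (Q = 0)", {
  grid <- c(0.5, 1, 5, 10, 25, 60, 120)
  wb <- surv_dist("weibull", c(22.065, 1.536))
  gg_wb <- surv_dist("gengamma", c(log(22.065), 1 / 1.536, 1))
  expect_equal(surv_prob(gg_wb, grid), surv_prob(wb, grid), tolerance = 1e-10)
  ln <- surv_dist("lognormal", c(1.962, 0.971))
  gg_ln <- surv_dist("gengamma", c(1.962, 0.971, 0))
  expect_equal(surv_prob(gg_ln, grid), surv_prob(ln, grid), tolerance = 1e-10)
})

test_that("invalid parameters are rejected at construction", {
  expect_error(surv_dist("weibull", c(-1, 1.5)), "invalid parameters")
  expect_error(surv_dist("lognormal", c(1.8, 0)), "invalid parameters")
  expect_error(surv_dist("weibull", 22), "requires 2 parameters")
  expect_error(surv_dist("gengamma", c(1, -0.5, 0)), "invalid parameters")
})

test_that("S is non-increasing in [0, 1] on a dense grid for every family", {
  grid <- seq(0, 240, length.out = 1000)
  cases <- list(
    surv_dist("weibull", c(22.065, 1.536)),
    surv_dist("weibull", c(5, 0.6)),
    surv_dist("lognormal", c(1.834, 0.873)),
    surv_dist("lognormal", c(0.8, 1.067)),
    surv_dist("gengamma", c(1.9, 0.8, 1.4)),
    surv_dist("gengamma", c(1.2, 1.1, -0.7)))
  for (d in cases) {
    s <- surv_prob(d, grid)
    expect_true(all(s >= 0 & s <= 1))
    expect_true(all(diff(s) <= 1e-12))
    expect_equal(s[1], 1)
  }
})

test_that("median survival matches closed forms and inverts S", {
  expect_equal(median_surv(surv_dist("lognormal", c(1.834, 0.873))),
               exp(1.834), tolerance = 1e-10)
  expect_equal(median_surv(surv_dist("lognormal", c(1.962, 0.971))),
               exp(1.962), tolerance = 1e-10)
  expect_equal(median_surv(surv_dist("weibull", c(22.065, 1.536))),
               22.065 * log(2)^(1 / 1.536), tolerance = 1e-10)
  gg <- surv_dist("gengamma", c(1.9, 0.8, 1.4))
  expect_equal(surv_prob(gg, median_surv(gg)), 0.5, tolerance = 1e-8)
})

test_that("discounted restricted mean agrees with a fine trapezoid oracle", {
  trap <- function(d, h, r, n = 40001L) {
    g <- seq(0, h, length.out = n)
    s <- surv_prob(d, g) * (1 + r)^(-g / 12)
    sum((s[-1] + s[-n]) / 2) * (g[2] - g[1]) / 12
  }
  cases <- list(surv_dist("weibull", c(22.065, 1.536)),
                surv_dist("lognormal", c(1.834, 0.873)),
                surv_dist("lognormal", c(0.8, 1.067)))
  for (d in cases) {
    expect_equal(disc_rmst(d, 60, 0), trap(d, 60, 0), tolerance = 1e-4)
    expect_equal(disc_rmst(d, 60, 0.03), trap(d, 60, 0.03), tolerance = 1e-4)
    # discounting shrinks, and the mean is bounded by the horizon
    expect_lt(disc_rmst(d, 60, 0.03), disc_rmst(d, 60, 0))
    expect_lte(disc_rmst(d, 60, 0), 5)
  }
})

test_that("inverse-CDF sampling is reproducible and converges to the law", {
  ln <- surv_dist("lognormal", c(1.834, 0.873))
  expect_error(sample_times(ln, 0), "positive count")
  set.seed(11); a <- sample_times(ln, 1000)
  set.seed(11); b <- sample_times(ln, 1000)
  expect_identical(a, b)
  set.seed(12); big <- sample_times(ln, 1e5)
  expect_equal(median(big), exp(1.834), tolerance = 0.2 / exp(1.834))
  # Kolmogorov-Smirnov distance against the true CDF
  set.seed(13); x <- sort(sample_times(ln, 1e4))
  cdf <- 1 - surv_prob(ln, x)
  ks <- max(pmax(abs(cdf - seq_along(x) / 1e4),
                 abs(cdf - (seq_along(x) - 1) / 1e4)))
  expect_lt(ks, 0.02)
})
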