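test_that("monomorphic metrics match deterministic extremes", {
  cfg <- crd_config()
  m4 <- monomorphic_metrics(strategy_spec("always-4", "execution"), cfg,
                            epsilon = 0, nsim = 5, seed = 1)
  expect_equal(m4$eta, 1)
  expect_equal(m4$C, 120)
  m0 <- monomorphic_metrics(strategy_spec("always-0", "delegate"), cfg,
                            epsilon = 0, nsim = 5, seed = 1)
  expect_equal(m0$eta, 0)
  expect_equal(m0$C, 0)
  expect_equal(m0$mean_payoff, 4)
  # noisy fair play is genuinely stochastic
  m2 <- monomorphic_metrics(strategy_spec("always-2", "execution"), cfg,
                            epsilon = 0.5, nsim = 4000, seed = 2)
  expect_gt(m2$eta, 0)
  expect_lt(m2$eta, 1)
})

test_that("free-riders rarely succeed and altruists rarely fail", {
  cfg <- crd_config()
  for (mode in c("execution", "program", "delegate")) {
    for (eps in c(0.1, 0.3, 0.5)) {
      m0 <- monomorphic_metrics(strategy_spec("always-0", mode), cfg, eps,
                                nsim = 400, seed = 3)
      m4 <- monomorphic_metrics(strategy_spec("always-4", mode), cfg, eps,
                                nsim = 400, seed = 3)
      # one-shot profile errors erode the extremes slightly at large epsilon
      expect_lt(m0$eta, 0.25)
      expect_gt(m4$eta, 0.8)
      expect_gt(m4$eta, m0$eta)
    }
  }
})

test_that("population averages are convex combinations", {
  expect_equal(success_rate(c(1, 0), c(1, 0.2)), 1)
  expect_equal(success_rate(c(0.5, 0.5), c(1, 0)), 0.5)
  expect_equal(avg_public_account(c(1, 0), c(120, 3)), 120)
  expect_equal(avg_public_account(c(0.5, 0.5), c(120, 0)), 60)
  set.seed(9)
  for (i in 1:20) {
    sigma <- runif(5)
    sigma <- sigma / sum(sigma)
    eta <- runif(5)
    expect_gte(success_rate(sigma, eta), min(eta))
    expect_lte(success_rate(sigma, eta), max(eta))
  }
  expect_error(success_rate(c(0.6, 0.6), c(1, 0)), "normalized")
  expect_error(success_rate(c(0.5, 0.5), c(1, 0, 1)))
})

test_that("delegation rate is the mass on delegation modes", {
  roster <- build_population("hybrid-program")
  sigma <- rep(0.1, 10)
  expect_equal(delegation_rate(sigma, roster), 0.5)
  sigma <- c(rep(0, 5), rep(0.2, 5))
  expect_equal(delegation_rate(sigma, roster), 1)
  # complement identity
  sigma <- runif(10)
  sigma <- sigma / sum(sigma)
  expect_equal(delegation_rate(sigma, roster) + sum(sigma[1:5]), 1)
  expect_warning(
    out <- delegation_rate(rep(0.2, 5), build_population("execution-only")),
    "undefined")
  expect_true(is.na(out))
})

test_that("actual error rate equals epsilon for execution, zero without errors", {
  cfg <- crd_config()
  for (mode in c("execution", "program", "delegate")) {
    expect_equal(actual_error_rate(strategy_spec("reciprocal", mode), cfg,
                                   epsilon = 0, nsim = 50, seed = 1), 0)
  }
  nsim <- 2000
  rate <- actual_error_rate(strategy_spec("compensatory", "execution"), cfg,
                            epsilon = 0.3, nsim = nsim, seed = 2)
  # about nsim * N * r per-round draws; allow a generous 3 SE band
  expect_lt(abs(rate - 0.3), 3 * sqrt(0.3 * 0.7 / (nsim * 60)) * 5)
  # delegate errors on a fair strategy deviate less often than epsilon:
  # half of the mispicks behave identically in a mostly-fair group
  rate_d <- actual_error_rate(strategy_spec("always-2", "delegate"), cfg,
                              epsilon = 0.3, nsim = nsim, seed = 3)
  expect_lt(rate_d, 0.25)
})

test_that("population metrics assemble sigma, eta and C coherently", {
  cfg <- crd_config()
  pm <- population_metrics("execution-only", cfg, evolution_config(),
                           epsilon = 0.1, nsim = 300, seed = 5)
  expect_equal(sum(pm$strategies$sigma), 1)
  expect_gte(pm$summary$success_rate, min(pm$strategies$eta))
  expect_lte(pm$summary$success_rate, max(pm$strategies$eta))
  expect_gte(pm$summary$avg_public_account, min(pm$strategies$C))
  expect_lte(pm$summary$avg_public_account, max(pm$strategies$C))
  expect_true(is.na(pm$summary$delegation_rate))
  expect_equal(pm$summary$success_rate,
               sum(pm$strategies$sigma * pm$strategies$eta))
})
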