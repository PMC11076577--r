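test_that("error-free tables reproduce deterministic playouts exactly", {
  cfg <- crd_config()
  # reciprocal vs always-2: every mix plays constant-2 games, payoff 20
  tab <- estimate_pair_payoffs(strategy_spec("reciprocal", "execution"),
                               strategy_spec("always-2", "execution"),
                               cfg, epsilon = 0, nsim = 3, seed = 1)
  expect_equal(tab$pi_a, rep(20, 6))
  expect_equal(tab$pi_b, rep(20, 6))
  # altruists vs free-riders at the 3/3 composition
  tab <- estimate_pair_payoffs(strategy_spec("always-4", "program"),
                               strategy_spec("always-0", "program"),
                               cfg, epsilon = 0, nsim = 2, seed = 1)
  expect_equal(tab$pi_a[3], 0)   # j = 2 co-players: 3 altruists in the group
  expect_equal(tab$pi_b[4], 40)  # j = 3 altruists seen by a free-rider
  # zero-variance case: any nsim gives the same table
  tab2 <- estimate_pair_payoffs(strategy_spec("always-4", "program"),
                                strategy_spec("always-0", "program"),
                                cfg, epsilon = 0, nsim = 17, seed = 99)
  # equal up to summation rounding across different nsim
  expect_equal(tab$pi_a, tab2$pi_a, tolerance = 1e-12)
  expect_equal(tab$pi_b, tab2$pi_b, tolerance = 1e-12)
})

test_that("Monte-Carlo estimates agree with exhaustive enumeration", {
  tiny <- tiny_config()
  nsim <- 20000
  # payoffs lie in [0, 8]; SD <= 4, so 3 Monte-Carlo SEs <= 0.085
  tol <- 3 * 4 / sqrt(nsim)
  cases <- list(
    list(a = strategy_spec("reciprocal", "execution"),
         b = strategy_spec("always-0", "execution"), eps = 0.3),
    list(a = strategy_spec("always-2", "delegate"),
         b = strategy_spec("compensatory", "delegate"), eps = 0.4),
    list(a = strategy_spec("reciprocal", "program"),
         b = strategy_spec("always-4", "program"), eps = 0.25)
  )
  for (cs in cases) {
    oracle <- enumerate_pair_payoffs_oracle(cs$a, cs$b, tiny, cs$eps)
    mc <- estimate_pair_payoffs(cs$a, cs$b, tiny, cs$eps, nsim = nsim,
                                seed = 5)
    expect_true(all(abs(mc$pi_a - oracle$pi_a) < tol))
    expect_true(all(abs(mc$pi_b - oracle$pi_b) < tol))
  }
})

test_that("the oracle refuses state spaces above its cap", {
  expect_error(
    enumerate_pair_payoffs_oracle(strategy_spec("reciprocal", "execution"),
                                  strategy_spec("always-2", "execution"),
                                  crd_config(), epsilon = 0.1),
    "max_leaves")
})

test_that("tables are symmetric under argument reflection", {
  cfg <- crd_config()
  a <- strategy_spec("compensatory", "execution")
  b <- strategy_spec("always-0", "delegate")
  ab <- estimate_pair_payoffs(a, b, cfg, epsilon = 0.2, nsim = 500, seed = 3)
  ba <- estimate_pair_payoffs(b, a, cfg, epsilon = 0.2, nsim = 500, seed = 3)
  expect_equal(ab$pi_a, rev(ba$pi_b))
  expect_equal(ab$pi_b, rev(ba$pi_a))
})

test_that("the three error modes give identical tables at epsilon = 0", {
  cfg <- crd_config()
  tabs <- lapply(c("execution", "program", "delegate"), function(mode) {
    tab <- estimate_pair_payoffs(strategy_spec("compensatory", mode),
                                 strategy_spec("always-4", mode),
                                 cfg, epsilon = 0, nsim = 5, seed = 11)
    unclass(cbind(tab$pi_a, tab$pi_b))
  })
  expect_identical(tabs[[1]], tabs[[2]])
  expect_identical(tabs[[1]], tabs[[3]])
})

test_that("roster table sets cover every pair and stay within bounds", {
  cfg <- crd_config()
  roster <- build_population("execution-only")
  tabs <- pair_payoff_tables(roster, cfg, epsilon = 0.1, nsim = 100, seed = 2)
  for (i in 1:5) {
    for (j in 1:5) {
      if (i == j) {
        expect_null(tabs[[i, j]])
      } else {
        tab <- tabs[[i, j]]
        expect_true(all(tab$pi_a >= 0 & tab$pi_a <= cfg$E))
        expect_true(all(tab$pi_b >= 0 & tab$pi_b <= cfg$E))
        # orientation consistency with the mirrored entry
        expect_equal(tab$pi_a, rev(tabs[[j, i]]$pi_b))
      }
    }
  }
  expect_error(pair_payoff_tables(list(roster[[1]], roster[[1]]), cfg),
               "distinct")
})
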