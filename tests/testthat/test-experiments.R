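test_that("population builders give canonical rosters", {
  ex <- build_population("execution-only")
  expect_length(ex, 5)
  expect_true(all(vapply(ex, function(s) s$mode, character(1)) == "execution"))
  expect_equal(vapply(ex, function(s) s$label, character(1)),
               paste0(c("always-0", "always-2", "always-4", "reciprocal",
                        "compensatory"), " (execution)"))
  hp <- build_population("hybrid-program")
  expect_length(hp, 10)
  expect_equal(vapply(hp, function(s) s$mode, character(1)),
               rep(c("execution", "program"), each = 5))
  hd <- build_population("hybrid-delegate")
  expect_equal(vapply(hd, function(s) s$mode, character(1)),
               rep(c("execution", "delegate"), each = 5))
  expect_error(build_population("mixed-up"), "valid kinds")
})

test_that("crossing detection matches analytic intersections", {
  x <- seq(0, 1, 0.25)
  out <- find_crossing(x, 1 - x, x)
  expect_equal(out$status, "crossing")
  expect_equal(out$x_cross, 0.5)
  # identical curves are reported distinctly from non-crossing ones
  expect_equal(find_crossing(x, x, x)$status, "identical")
  expect_equal(find_crossing(x, x + 1, x)$status, "none")
  # a leading tie (both curves equal at the first point) is not a crossing
  f <- c(0.5, 0.8, 0.6, 0.4, 0.2)
  out <- find_crossing(x, f, rep(0.5, 5))
  expect_equal(out$x_cross, 0.5 + 0.25 * 0.1 / 0.2)
  expect_equal(out$x_lo, 0.5)
  # random affine curves with a bracketed intersection
  set.seed(11)
  for (i in 1:20) {
    a <- runif(2, -2, 2)
    b <- runif(2, -2, 2)
    if (abs(a[2] - b[2]) < 1e-3) next
    xs <- seq(-5, 5, 0.5)
    xstar <- (b[1] - a[1]) / (a[2] - b[2])
    if (xstar <= min(xs) || xstar >= max(xs)) next
    out <- find_crossing(xs, a[1] + a[2] * xs, b[1] + b[2] * xs)
    expect_equal(out$x_cross, xstar, tolerance = 1e-10)
  }
})

test_that("sweeps are reproducible and mode-equivalent at epsilon = 0", {
  cfg <- crd_config()
  evo <- evolution_config()
  grid <- c(0, 0.25)
  s1 <- sweep_epsilon("execution-only", grid, cfg, evo, nsim = 60, seed = 8)
  s2 <- sweep_epsilon("execution-only", grid, cfg, evo, nsim = 60, seed = 8)
  expect_identical(s1$summary, s2$summary)
  expect_identical(s1$strategies, s2$strategies)
  expect_equal(nrow(s1$summary), length(grid))
  expect_equal(nrow(s1$strategies), length(grid) * 5)
  # the first row (epsilon = 0) is identical across the three error modes
  sp <- sweep_epsilon("program-only", grid, cfg, evo, nsim = 60, seed = 8)
  sd <- sweep_epsilon("delegate-only", grid, cfg, evo, nsim = 60, seed = 8)
  cols <- c("success_rate", "avg_public_account")
  expect_equal(as.data.frame(s1$summary[1, cols]),
               as.data.frame(sp$summary[1, cols]))
  expect_equal(as.data.frame(s1$summary[1, cols]),
               as.data.frame(sd$summary[1, cols]))
  expect_equal(s1$strategies$sigma[s1$strategies$epsilon == 0],
               sp$strategies$sigma[sp$strategies$epsilon == 0])
})

test_that("sweep accessors, tidiers and plots expose the results", {
  cfg <- crd_config()
  sw <- sweep_epsilon("hybrid-program", c(0, 0.3), cfg, evolution_config(),
                      nsim = 40, seed = 13)
  expect_s3_class(tidy(sw), "tbl_df")
  expect_equal(nrow(tidy(sw, "strategy")), 20)
  expect_equal(glance(sw)$S, 10)
  expect_false(any(is.na(sw$summary$delegation_rate)))
  expect_s3_class(autoplot(sw), "ggplot")
  expect_s3_class(autoplot(sw, "sigma"), "ggplot")
  expect_s3_class(plot_sweep_comparison(list(sw), "success_rate"), "ggplot")
  dc <- dominance_crossing(sw, "always-0 (program)", triad_labels("program"))
  expect_true(dc$status %in% c("crossing", "none"))
  st <- population_metrics("execution-only", cfg, evolution_config(),
                           epsilon = 0, nsim = 2, seed = 1)$stationary
  expect_s3_class(tidy(st), "tbl_df")
  expect_equal(glance(st)$S, 5)
  expect_s3_class(autoplot(st), "ggplot")
})
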