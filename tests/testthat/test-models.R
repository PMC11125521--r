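test_that("propensities enumerate each model's reaction channels", {
  # telegraph, active state with 3 copies: switch off (1), synthesis (10),
  # decay (3)
  pr <- propensities(tm_ref(), c(1, 3))
  expect_setequal(pr$reaction, c("synthesis", "decay", "deactivate"))
  expect_equal(pr$rate[pr$reaction == "synthesis"], 10)
  expect_equal(pr$rate[pr$reaction == "decay"], 3)
  expect_equal(pr$rate[pr$reaction == "deactivate"], 1)

  # positive feedback: activation is lam + mu * n
  pfm <- complex_model_params("PFM", rho = 10, lam = 2, gam = 1, mu = 0.5)
  pr <- propensities(pfm, c(0, 4))
  expect_equal(pr$rate[pr$reaction == "activate"], 2 + 0.5 * 4)

  # negative feedback: inactivation is gam + nu * n
  nfm <- complex_model_params("NFM", rho = 10, lam = 1, gam = 1, nu = 0.1)
  pr <- propensities(nfm, c(1, 10))
  expect_equal(pr$rate[pr$reaction == "deactivate"], 1 + 0.1 * 10)

  # CPM deactivation branches with probabilities q1, q2
  pr <- propensities(cpm_ref(), c(2, 5))
  expect_equal(pr$rate[pr$reaction == "deactivate_weak"], 0.5)
  expect_equal(pr$rate[pr$reaction == "deactivate_strong"], 0.5)

  expect_error(propensities(tm_ref(), c(1, -2)), "negative")
  expect_error(propensities(tm_ref(), c(5, 2)), "invalid gene state")
})

test_that("feedback models reduce to the telegraph scheme at zero strength", {
  tm <- telegraph_params(1.3, 0.8, 12, 1)
  pfm0 <- complex_model_params("PFM", rho = 12, lam = 1.3, gam = 0.8, mu = 0)
  nfm0 <- complex_model_params("NFM", rho = 12, lam = 1.3, gam = 0.8, nu = 0)
  for (g in 0:1) for (n in c(0L, 1L, 5L, 20L)) {
    ref <- propensities(tm, c(g, n))
    for (m in list(pfm0, nfm0)) {
      pr <- propensities(m, c(g, n))
      expect_equal(sort(pr$rate), sort(ref$rate))
    }
  }
})

test_that("holding times match the closed forms and the flux-balance oracle", {
  # three-state: T_off is the sum of the two sequential step times
  ht <- mean_holding_times(complex_model_params("TSM", rho = 10, lam1 = 2,
                                                lam2 = 2, gam = 1))
  expect_equal(ht$T_on, 1)
  expect_equal(ht$T_off, 1)

  # cross-talk: hyperexponential mixture mean q1/lam1 + q2/lam2
  cpm <- complex_model_params("CPM", rho = 10, lam1 = 0.2, lam2 = 2,
                              gam = 1, q1 = 0.5)
  ht <- mean_holding_times(cpm)
  expect_equal(ht$T_on, 1)
  expect_equal(ht$T_off, 0.5 / 0.2 + 0.5 / 2)

  # stationary flux balance on the CME reproduces the closed forms
  for (p in list(tsm_ref(), cpm, tm_ref())) {
    cf <- mean_holding_times(p)
    fx <- holding_times_flux(p)
    expect_equal(fx$T_on, cf$T_on, tolerance = 1e-3)
    expect_equal(fx$T_off, cf$T_off, tolerance = 1e-3)
  }

  expect_error(mean_holding_times(
    complex_model_params("TSM", rho = 10, lam1 = 0, lam2 = 1, gam = 1)),
    "zero switching rate")
})

test_that("feedback holding times agree with SSA dwell-time means", {
  for (p in list(pfm_ref(), nfm_ref())) {
    ht <- mean_holding_times(p) # flux-balance route
    tr <- ssa_trajectory(p, t_end = 6000, seed = 42)
    dw <- telegraphfit:::dwell_times(tr, on_index = 1L)
    for (state in c(TRUE, FALSE)) {
      d <- dw$duration[dw$on == state]
      ref <- if (state) ht$T_on else ht$T_off
      se <- sd(d) / sqrt(length(d))
      expect_lt(abs(mean(d) - ref), 3.5 * se)
    }
  }
})

test_that("cross-talk off dwell times follow the hyperexponential mixture", {
  cpm <- complex_model_params("CPM", rho = 5, lam1 = 0.2, lam2 = 2,
                              gam = 1, q1 = 0.5)
  tr <- ssa_trajectory(cpm, t_end = 8000, seed = 7)
  dw <- telegraphfit:::dwell_times(tr, on_index = 2L)
  off <- dw$duration[!dw$on]
  se <- sd(off) / sqrt(length(off))
  expect_lt(abs(mean(off) - 2.75), 3.5 * se)
})

test_that("cooperative positive feedback fixed points and stability", {
  # bistable worked example: three fixed points, stable-unstable-stable
  fp <- deterministic_fixed_points(
    complex_model_params("PFM", rho = 50, lam = 2, gam = 160, mu = 0.5,
                         cooperativity = 2))
  expect_length(fp$roots, 3)
  expect_equal(fp$stable, c(TRUE, FALSE, TRUE))

  # vanishing feedback recovers the telegraph mean-field fixed point
  fp0 <- deterministic_fixed_points(
    complex_model_params("PFM", rho = 10, lam = 1, gam = 1, mu = 1e-9,
                         cooperativity = 2))
  expect_equal(fp0$roots[which.max(fp0$roots)], 5, tolerance = 1e-4)

  # brute-force sign-change scan as an independent root oracle
  pars <- complex_model_params("PFM", rho = 50, lam = 2, gam = 10, mu = 0.5,
                               cooperativity = 2)
  g <- function(x) 50 * (2 + 0.5 * x^2) / (2 + 10 + 0.5 * x^2) - x
  xs <- seq(0, 50, by = 1e-4)
  sgn <- sign(g(xs))
  flips <- which(diff(sgn) != 0)
  brute <- (xs[flips] + xs[flips + 1]) / 2
  fp <- deterministic_fixed_points(pars)
  expect_length(fp$roots, length(brute))
  expect_equal(fp$roots, brute, tolerance = 1e-3)
})
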