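test_that("generator columns conserve probability", {
  A <- generator_matrix(tm_ref(), 40)
  cs <- Matrix::colSums(A)
  # only the boundary synthesis column leaks (FSP sink): on state at n_max
  leak <- which(abs(cs) > 1e-12)
  expect_length(leak, 1)
  expect_equal(cs[leak], -10)

  # rho = 0, n_max = 1: four-state chain, stationary Bernoulli on the gene
  A0 <- generator_matrix(telegraph_params(2, 1, 0, 1), 1)
  expect_equal(dim(A0), c(4L, 4L))
  p <- telegraphfit:::null_solve(A0)
  expect_equal(p, c(1 / 3, 2 / 3, 0, 0), tolerance = 1e-12)
})

test_that("analytic telegraph pmf equals the null-space stationary vector", {
  sets <- list(c(1, 1, 10), c(0.2, 0.2, 20), c(5, 80, 300), c(0.36, 0.18, 12.5))
  for (s in sets) {
    tm <- telegraph_params(s[1], s[2], s[3], 1)
    joint <- steady_state_pmf(tm, tol = 1e-12)
    pn <- marginal_pmf(joint)
    pa <- telegraph_pmf_analytic(tm, joint$n_max)
    expect_lt(max(abs(pa - pn)), 1e-8)
    expect_lt(abs(pmf_mean(pa) - s[3] * s[1] / (s[1] + s[2])), 1e-6)
  }
  # degenerate limits
  expect_equal(telegraph_pmf_analytic(telegraph_params(1, 1, 0, 1), 5),
               c(1, 0, 0, 0, 0, 0))
  poiss <- telegraph_pmf_analytic(telegraph_params(1, 1e-12, 10, 1), 60)
  expect_lt(hellinger(poiss, dpois(0:60, 10)), 1e-3)
})

test_that("steady-state solves respect model reductions and flux identities", {
  pfm0 <- complex_model_params("PFM", rho = 10, lam = 1, gam = 1, mu = 0)
  m1 <- marginal_pmf(steady_state_pmf(pfm0))
  m2 <- telegraph_pmf_analytic(tm_ref(), length(m1) - 1)
  expect_lt(max(abs(m1 - m2)), 1e-8)

  j <- steady_state_pmf(tsm_ref())
  expect_equal(sum(j$P[3, ]), 0.5, tolerance = 1e-6) # P_on from renewal
})

test_that("conditionals reconstruct the marginal mixture exactly", {
  j <- steady_state_pmf(cpm_ref())
  cd <- conditional_pmfs(j)
  recon <- (1 - cd$p_off) * cd$pn_on + cd$p_off * cd$pn_off
  expect_lt(max(abs(recon - cd$marginal)), 1e-12)

  # fast switching: conditioning on the gene state barely matters
  fast <- conditional_pmfs(steady_state_pmf(telegraph_params(50, 50, 10, 1)))
  expect_lt(hellinger(fast$pn_off, fast$pn_on), 0.05)
})

test_that("FSP transients match moment-ODE and stiff-integrator oracles", {
  tg <- seq(0.1, 8, by = 0.1)
  fs <- fsp_transient(tm_ref(), tg, tol = 1e-10)
  expect_lt(max(fs$loss), 1e-10)
  expect_lt(abs(sum(fs$marginal[1, ]) - 1), 1e-9)

  # two-ODE moment oracle: dp_on = lam (1 - p_on) - gam p_on,
  #                        dM = rho p_on - d M
  sol <- deSolve::ode(c(p_on = 0, M = 0), c(0, tg),
                      function(t, y, p) list(c(1 - 2 * y[1], 10 * y[1] - y[2])),
                      NULL, rtol = 1e-10, atol = 1e-12)
  expect_lt(max(abs(fs$mean - sol[-1, "M"])), 1e-6)

  # full-distribution cross-check against a stiff ODE solve of the same
  # truncated generator (independent integrator route)
  p <- cpm_ref()
  n_max <- 60L
  A <- as.matrix(generator_matrix(p, n_max))
  y0 <- numeric(nrow(A)); y0[1] <- 0.5; y0[2] <- 0.5
  ts <- c(0.5, 2, 6)
  ode_sol <- deSolve::ode(y0, c(0, ts), function(t, y, pp) list(A %*% y),
                          NULL, rtol = 1e-10, atol = 1e-12, method = "lsoda")
  fs2 <- fsp_transient(p, ts, n_max = n_max, tol = 1e-10)
  for (l in seq_along(ts)) {
    ode_marg <- colSums(matrix(ode_sol[l + 1, -1], nrow = 3))
    expect_lt(max(abs(fs2$marginal[l, ] - ode_marg)), 1e-6)
  }

  # t = 0 returns the initial distribution exactly
  fs0 <- fsp_transient(tm_ref(), c(0, 1))
  expect_equal(fs0$marginal[1, 1], 1)
  expect_equal(fs0$mean[1], 0)

  # long horizon converges to the stationary law
  fs_inf <- fsp_transient(tm_ref(), 60)
  expect_lt(hellinger(fs_inf$marginal[1, ],
                      marginal_pmf(steady_state_pmf(tm_ref()))), 1e-4)
})

test_that("response times interpolate the first half-rise crossing", {
  # analytic half-rise of M(t) = M_inf (1 - exp(-t)) is log(2)
  tt <- seq(0, 10, by = 0.01)
  cv <- structure(data.frame(t = tt, M = 7 * (1 - exp(-tt))), m_inf = 7,
                  class = c("mean_curve", "data.frame"))
  expect_equal(response_time(cv), log(2), tolerance = 1e-4)

  # overshooting curve: first crossing wins
  cv2 <- structure(data.frame(t = 0:10, M = c(0, 6, 9, 7, 5, 5, 5, 5, 5, 5, 5)),
                   m_inf = 10, class = c("mean_curve", "data.frame"))
  expect_lt(response_time(cv2), 1.01)

  expect_equal(response_time_gap(cv, cv, d = 2)$G, 0)
  expect_error(response_time(structure(data.frame(t = 0:2, M = c(0, 0.1, 0.2)),
                                       m_inf = 10)), "does not reach")

  # FSP response time matches the moment-ODE oracle
  cv3 <- mean_curve(tm_ref(), 8, n_points = 400)
  sol <- deSolve::ode(c(0, 0), seq(0, 8, length.out = 3201),
                      function(t, y, p) list(c(1 - 2 * y[1], 10 * y[1] - y[2])),
                      NULL, rtol = 1e-10, atol = 1e-12)
  ode_curve <- structure(data.frame(t = sol[, 1], M = sol[, 3]), m_inf = 5,
                         class = c("mean_curve", "data.frame"))
  expect_equal(response_time(cv3), response_time(ode_curve), tolerance = 1e-3)
})
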