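make_series <- function(times, counts_mat, model = "TM") {
  structure(list(times = times, counts = counts_mat, states = NULL,
                 n_cells = nrow(counts_mat), model = model),
            class = "snapshot_series")
}

test_that("one late snapshot reduces to the steady-state likelihood", {
  sn <- sample_snapshots(tm_ref(), 60, 2000, seed = 71)
  ll_tc <- loglik_timecourse(tm_ref(), sn)
  tab <- tabulate(sn$counts[, 1] + 1L, nbins = max(sn$counts) + 1L)
  pss <- telegraph_pmf_analytic(tm_ref(), max(sn$counts))
  ll_ss <- sum(tab[tab > 0] * log(pss[tab > 0]))
  expect_equal(ll_tc, ll_ss, tolerance = 1e-6)
})

test_that("the all-zero snapshot at t = 0 contributes nothing", {
  sn1 <- sample_snapshots(tm_ref(), c(0, 1), 500, seed = 72)
  sn2 <- make_series(1, sn1$counts[, 2, drop = FALSE])
  expect_equal(loglik_timecourse(tm_ref(), sn1),
               loglik_timecourse(tm_ref(), sn2))
})

test_that("the generating parameters dominate random perturbations", {
  truth <- cpm_ref()
  sn <- sample_snapshots(truth, c(0.5, 1, 2, 4, 8), 2000, seed = 73)
  ll_star <- loglik_timecourse(truth, sn)
  set.seed(74)
  for (i in 1:50) {
    p <- truth
    p$lam2 <- truth$lam2 * exp(rnorm(1, 0, 0.4))
    p$gam <- truth$gam * exp(rnorm(1, 0, 0.4))
    p$rho <- truth$rho * exp(rnorm(1, 0, 0.4))
    expect_gte(ll_star, loglik_timecourse(p, sn))
  }
})

test_that("optimization transforms round-trip and stay in range", {
  cpm <- cpm_ref()
  nm <- telegraphfit:::timecourse_free_params(cpm)
  th <- telegraphfit:::free_params_to_theta_any(cpm, nm)
  back <- telegraphfit:::set_free_params_any(cpm, nm, th)
  for (f in nm) expect_equal(back[[f]], cpm[[f]], tolerance = 1e-12)

  tm <- tm_ref()
  nm_tm <- telegraphfit:::timecourse_free_params(tm)
  th_tm <- telegraphfit:::free_params_to_theta_any(tm, nm_tm)
  back_tm <- telegraphfit:::set_free_params_any(tm, nm_tm, th_tm)
  for (f in nm_tm) expect_equal(back_tm[[f]], tm[[f]], tolerance = 1e-12)

  # the q2 transform maps the whole real line into (0, 1)
  for (x in c(-20, -1, 0.3, 5, 40)) {
    p <- telegraphfit:::set_free_params(cpm, "q2", x)
    expect_true(p$q2 > 0 && p$q2 < 1)
  }
})

test_that("time-course MLE recovers the generating telegraph parameters", {
  tm <- telegraph_params(0.36, 0.18, 12.5, 1)
  tl <- c(0.2, 0.4, 0.6, 0.9, 1.2, 1.5, 1.8, 2.2, 2.6)
  sn <- sample_snapshots(tm, tl, 1000, seed = 75, independent = TRUE)
  ft <- fit_timecourse(tm, sn, n_starts = 4, seed = 76)
  rel <- abs(c(ft$params$lam_bar / 0.36, ft$params$gam_bar / 0.18,
               ft$params$rho_bar / 12.5) - 1)
  expect_lt(median(rel), 0.2)
  expect_true(all(ft$hd_per_time >= 0 & ft$hd_per_time <= 1))
})

test_that("cross-talk snapshots prefer their generating model over TM", {
  truth <- complex_model_params("CPM", rho = 20, lam1 = 0.2, lam2 = 4,
                                gam = 1, q1 = 0.6)
  tl <- c(0.3, 0.7, 1.2, 2, 3.5, 6)
  sn <- sample_snapshots(truth, tl, 600, seed = 77)
  ft_cpm <- fit_timecourse(truth, sn, n_starts = 2, seed = 78)
  ft_tm <- fit_timecourse(initial_values(sn$counts[, length(tl)]), sn,
                          n_starts = 4, seed = 79)
  expect_lt(ft_cpm$hd_total, ft_tm$hd_total)

  # a negative-feedback fit of cross-talk data drives the feedback
  # strength to the zero boundary (below the smallest grid value 0.05)
  nfm0 <- complex_model_params("NFM", rho = 20, lam = 1, gam = 1, nu = 0.05)
  ft_nfm <- fit_timecourse(nfm0, sn, n_starts = 3, seed = 80)
  expect_lt(ft_nfm$params$nu, 0.05)
})

test_that("the profile statistic is calibrated at the MLE", {
  tm <- telegraph_params(1.2, 0.6, 8, 1)
  sn <- sample_snapshots(tm, c(0.3, 0.6, 1, 1.5, 2, 3), 400, seed = 81,
                         independent = TRUE)
  ft <- fit_timecourse(tm, sn, n_starts = 2, seed = 82)
  ci <- profile_likelihood_ci(ft, sn, "rho_bar",
                              grid = ft$params$rho_bar *
                                10^seq(-0.5, 0.5, length.out = 13))
  expect_true(all(is.finite(ci$trace$q)))
  expect_true(all(ci$trace$q >= 0))
  expect_lt(min(ci$trace$q), 0.2) # profile minimum sits at the MLE
  expect_true(ci$lower <= ci$estimate && ci$estimate <= ci$upper)
  expect_true(ci$lower <= 8 && 8 <= ci$upper)
  expect_gt(ci$uncertainty, 0)
})
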