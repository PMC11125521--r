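test_that("Cartesian grids reproduce the printed designs", {
  for (m in c("TSM", "CPM", "PFM", "NFM")) {
    g <- grid_625(m)
    expect_length(g, 625)
    expect_identical(grid_625(m), g) # construction is deterministic
  }
  g <- grid_625("CPM")
  expect_true(all(vapply(g, `[[`, 0, "lam1") == 0.2))
  expect_true(all(vapply(g, `[[`, 0, "lam2") > 0.2))

  pf <- grid_625("PFM")
  key <- vapply(pf, function(p) paste(p$rho, p$lam, p$gam, p$mu), "")
  expect_true("10 0.3 0.3 0.05" %in% key) # Cartesian corners
  expect_true("30 4 4 1.5" %in% key)

  ts <- grid_625("TSM")
  expect_setequal(unique(vapply(ts, `[[`, 0, "rho")), c(10, 15, 20, 25, 30))
  expect_setequal(unique(vapply(ts, `[[`, 0, "lam1")), c(0.3, 0.7, 1, 2, 4))

  sg <- subgrid(g, 25, seed = 9)
  expect_length(sg, 25)
  expect_identical(vapply(subgrid(g, 25, seed = 9), `[[`, 0, "rho"),
                   vapply(sg, `[[`, 0, "rho"))
})

test_that("random grids respect the box and switching-frequency bounds", {
  g <- grid_random150("TSM", seed = 10, n = 40)
  expect_length(g, 40)
  for (p in g) {
    ht <- mean_holding_times(p)
    expect_true(1 / ht$T_off >= 0.05 && 1 / ht$T_off <= 2.5)
    expect_true(1 / ht$T_on >= 0.1 && 1 / ht$T_on <= 2.5)
    expect_true(p$rho >= 10 && p$rho <= 30)
    expect_true(all(c(p$lam1, p$lam2) >= 0.1 & c(p$lam1, p$lam2) <= 5))
  }
  expect_identical(vapply(grid_random150("TSM", seed = 10, n = 40), `[[`, 0, "gam"),
                   vapply(g, `[[`, 0, "gam"))

  gc <- grid_random150("CPM", seed = 11, n = 25)
  for (p in gc) expect_lte(1 / mean_holding_times(p)$T_off, 2.5)

  gp <- grid_random150("PFM", seed = 12, n = 10)
  for (p in gp) expect_lte(1 / mean_holding_times(p)$T_off, 2.5 + 1e-9)
  gn <- grid_random150("NFM", seed = 13, n = 10)
  for (p in gn) expect_lte(1 / mean_holding_times(p)$T_on, 2.5 + 1e-9)
})

test_that("relative errors follow the printed sign conventions", {
  truth <- tsm_ref() # T_off = 1, T_on = 1, rho = 15
  perfect <- telegraph_params(1, 1, 15, 1)
  re <- relative_errors(perfect, truth)
  expect_equal(unlist(re), c(RE_rho = 0, RE_lam = 0, RE_gam = 0))
  re2 <- relative_errors(telegraph_params(1, 1, 18, 1), truth)
  expect_equal(re2$RE_rho, 0.2)
  expect_equal(expected_sign_pattern("TSM"), c(RE_lam = 1, RE_gam = 1, RE_rho = 1))
  expect_error(expected_sign_pattern("XXX"), "unknown")
})

test_that("experiment runs are reproducible from their seeds", {
  g <- subgrid(grid_625("TSM"), 2, seed = 14)
  r1 <- run_steady_fit_experiment(g, n_cells = 1500, seed = 15,
                                  conditionals = FALSE, n_starts = 5)
  r2 <- run_steady_fit_experiment(g, n_cells = 1500, seed = 15,
                                  conditionals = FALSE, n_starts = 5)
  expect_identical(r1, r2)
  expect_true(all(c("HD", "KLD", "RE_lam", "RE_gam", "RE_rho", "shape")
                  %in% names(r1)))
})

test_that("extrinsic noise of zero reproduces the noiseless pipeline", {
  g <- subgrid(grid_625("NFM"), 2, seed = 16)
  base <- run_steady_fit_experiment(g, n_cells = 1000, seed = 17,
                                    conditionals = FALSE)
  rb <- run_robustness_experiment(g, noise_levels = c(0, 0.5),
                                  n_cells = 1000, seed = 17)
  zero <- rb$per_set[rb$per_set$noise_level == 0, names(base)]
  rownames(zero) <- NULL
  expect_equal(zero, base, ignore_attr = TRUE)
  expect_equal(rb$summary$param, rep("RE_lam", 2))
})

test_that("tuning scans normalize at the lowest mean and label trends", {
  nfm <- complex_model_params("NFM", rho = 20, lam = 1, gam = 1, nu = 0.5)
  sc <- tuning_scan(nfm, "nu", n_cells = 5000, seed = 18)
  tr <- attr(sc, "trends")
  # weakening negative feedback raises the mean: rho_bar rises while
  # lam_bar stays put and gam_bar never rises with the mean -- the
  # signature separating nu-tuning from rho-tuning
  expect_equal(unname(tr["rho_bar"]), "increasing")
  expect_false(tr["gam_bar"] == "increasing")
  expect_equal(unname(tr["lam_bar"]), "invariant")
  expect_equal(sc$lam_bar_norm[1], 1)
  expect_equal(sc$gam_bar_norm[1], 1)
  expect_equal(sc$rho_bar_norm[1], 1)

  # insufficient mean modulation is rejected
  expect_error(tuning_scan(nfm, "lam", tuning_values = c(0.98, 1, 1.02),
                           n_cells = 400, seed = 19), "two-fold")
})

test_that("bimodal-region scans respect the telegraph bimodality criterion", {
  scans <- lapply(c(TSM = "TSM", PFM = "PFM"), function(m)
    bimodal_region_scan(m, seed = 20, n_cells = 2000, n_sets = 30))
  for (res in scans) {
    expect_true(all(res$f_off <= 2.5 + 1e-9 & res$f_on <= 2.5 + 1e-9))
    bi <- res$shape == "bimodal"
    # every set classified bimodal has fitted switching rates below decay
    expect_true(all(res$lam_bar[bi] < 1 & res$gam_bar[bi] < 1))
  }
  # positive feedback pushes fits into the bimodal region more than the
  # refractory model does
  expect_gt(attr(scans$PFM, "frac_bimodal"), attr(scans$TSM, "frac_bimodal"))
})

test_that("Wilson intervals bracket the observed fraction", {
  wi <- wilson_interval(50, 100)
  expect_true(wi[1] < 0.5 && 0.5 < wi[2])
  expect_true(all(wilson_interval(0, 20) >= 0))
  expect_true(all(wilson_interval(20, 20) <= 1))
  expect_lt(diff(wilson_interval(500, 1000)), diff(wilson_interval(5, 10)))
})
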