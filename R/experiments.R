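# Seeded experiment runners for the grid-scale analyses
# at configurable scale.

set_seed_i <- function(seed, i, off = 0L) as.integer(seed + 7919L * i + off)

#' Steady-state fit experiment over a parameter grid
#'
#' For each parameter set: simulate \code{n_cells} independent cells at
#' steady state (with gene-state labels), fit the counts to the telegraph
#' model by maximum likelihood, and record the goodness of fit (HD, KLD of
#' the marginal; HD of the on- and off-state conditionals), the effective
#' parameters, their relative errors against the generating model, and the
#' shape class of the fitted pmf.
#'
#' @param params_list list of \code{complex_params} (a grid or subgrid)
#' @param n_cells cells per set (default 1e4)
#' @param seed root seed; per-set seeds are derived deterministically
#' @param noise extrinsic-noise CV applied to the synthesis rate (0 = none)
#' @param conditionals also fit/score the gene-state conditionals
#' @param n_starts telegraph-fit multi-start count
#' @return data.frame, one row per set
#' @export
run_steady_fit_experiment <- function(params_list, n_cells = 1e4, seed = 1,
                                      noise = 0, conditionals = TRUE,
                                      n_starts = 20) {
  rows <- lapply(seq_along(params_list), function(i) try_set(i, {
    truth <- params_list[[i]]
    cells <- sample_steady_state(truth, n_cells, seed = set_seed_i(seed, i),
                                 noise = noise)
    fit <- fit_telegraph_mle(cells$count, d = truth$d, n_starts = n_starts,
                             seed = set_seed_i(seed, i, 1L))
    ht <- mean_holding_times(truth)
    re <- relative_errors(fit, truth, holding = ht)
    out <- data.frame(model = truth$model, set = i,
                      mean_expr = mean(cells$count),
                      HD = fit$HD, KLD = fit$KLD,
                      lam_bar = fit$params$lam_bar,
                      gam_bar = fit$params$gam_bar,
                      rho_bar = fit$params$rho_bar,
                      RE_lam = re$RE_lam, RE_gam = re$RE_gam,
                      RE_rho = re$RE_rho,
                      f_off = 1 / ht$T_off, f_on = 1 / ht$T_on,
                      shape = classify_shape(
                        telegraph_pmf_extended(fit$params, max(cells$count))),
                      converged = fit$converged)
    if (conditionals) {
      cond_fit <- conditional_pmfs(steady_state_pmf(fit$params, tol = 1e-10))
      # conditionals from ergodic time-averaging: conditioning the N-cell
      # snapshot on a rarely occupied gene state is too noisy
      occ <- ssa_occupancy(truth, seed = set_seed_i(seed, i, 2L))
      cond_emp <- conditional_pmfs(occ)
      out$HD_on <- hellinger(cond_emp$pn_on, cond_fit$pn_on)
      out$HD_off <- hellinger(cond_emp$pn_off, cond_fit$pn_off)
    }
    out
  }))
  bind_sets(rows)
}

# per-set failure tolerance: a failed set is logged and skipped, never
# aborts a grid run
try_set <- function(i, expr) {
  tryCatch(expr, error = function(e) {
    warning("parameter set ", i, " failed: ", conditionMessage(e),
            call. = FALSE)
    NULL
  })
}

bind_sets <- function(rows) {
  failed <- sum(vapply(rows, is.null, TRUE))
  out <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  attr(out, "n_failed") <- failed
  out
}

#' Over/under-estimation sign-pattern summary
#'
#' Summarizes a \code{\link{run_steady_fit_experiment}} result per the sign
#' rules: for each effective parameter, the fraction of sets whose relative
#' error matches the expected sign for the model (cases with
#' \code{|RE| < noise_floor} excluded as fit noise), together with the
#' sample mean and sd of |RE| and the fraction with |RE| > 0.2.
#'
#' @param res result data.frame of \code{run_steady_fit_experiment}
#' @param noise_floor |RE| below which a sign is not counted (default 0.05)
#' @return data.frame, one row per effective parameter
#' @export
sign_pattern_summary <- function(res, noise_floor = 0.05) {
  stopifnot(length(unique(res$model)) == 1)
  expct <- expected_sign_pattern(res$model[1])
  do.call(rbind, lapply(names(expct), function(pn) {
    re <- res[[pn]]
    informative <- abs(re) >= noise_floor
    data.frame(model = res$model[1], param = pn,
               expected_sign = expct[[pn]],
               n_informative = sum(informative),
               frac_sign_ok = if (any(informative))
                 mean(sign(re[informative]) == expct[[pn]]) else NA,
               mean_abs_re = mean(abs(re)), sd_abs_re = sd(abs(re)),
               frac_gt_0.2 = mean(abs(re) > 0.2))
  }))
}

#' Bimodal-region scan on random parameter sets
#'
#' For each set of a \code{\link{grid_random150}}-style grid: the true
#' switching frequencies (1/T_off, 1/T_on), the fitted effective rates
#' (lam_bar, gam_bar), and the shape class of the fitted telegraph pmf.
#'
#' @param model model tag
#' @param seed root seed (also seeds the random grid)
#' @param n_cells cells per set
#' @param n_sets number of random sets (default 150)
#' @return data.frame with per-set rows; bimodal fraction in attribute
#'   \code{frac_bimodal}
#' @export
bimodal_region_scan <- function(model, seed, n_cells = 1e4, n_sets = 150) {
  grid <- grid_random150(model, seed = seed, n = n_sets)
  res <- run_steady_fit_experiment(grid, n_cells = n_cells, seed = seed + 1,
                                   conditionals = FALSE)
  structure(res, frac_bimodal = mean(res$shape == "bimodal"))
}

#' Wilson score interval for a binomial fraction
#' @param x successes
#' @param n trials
#' @param level confidence level
#' @return c(lower, upper)
#' @export
wilson_interval <- function(x, n, level = 0.95) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  p <- x / n
  den <- 1 + z^2 / n
  ctr <- (p + z^2 / (2 * n)) / den
  hw <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  c(lower = max(0, ctr - hw), upper = min(1, ctr + hw))
}

#' AICc misselection-rate experiment
#'
#' For each parameter set and each sample size: simulate steady-state
#' counts, fit both the generating complex model (k = 4; CPM lam1 fixed)
#' and the telegraph model (k = 3), and record whether the telegraph model
#' wins AICc ("incorrect selection" since the data come from the complex
#' model).
#'
#' @param params_list list of generating \code{complex_params}
#' @param n_cells_list sample sizes (default 1e2, 1e3, 1e4, 1e5)
#' @param seed root seed
#' @param n_starts_complex multi-start count of the complex-model fit
#' @return list with \code{per_set} (data.frame) and \code{fractions}
#'   (per-N incorrect fraction with Wilson interval)
#' @export
misselection_rate <- function(params_list,
                              n_cells_list = c(1e2, 1e3, 1e4, 1e5),
                              seed = 1, n_starts_complex = 3) {
  rows <- list()
  for (i in seq_along(params_list)) {
    truth <- params_list[[i]]
    for (j in seq_along(n_cells_list)) {
      N <- n_cells_list[j]
      cells <- sample_steady_state(truth, N,
                                   seed = set_seed_i(seed, i, 31L * j))
      set.seed(set_seed_i(seed, i, 31L * j + 1L))
      sel <- select_model(cells$count, truth,
                          n_starts_complex = n_starts_complex)
      rows[[length(rows) + 1]] <-
        data.frame(model = truth$model, set = i, n_cells = N,
                   winner = sel$winner, aicc_tm = sel$aicc_tm,
                   aicc_complex = sel$aicc_complex,
                   incorrect = sel$winner == "telegraph")
    }
  }
  per_set <- do.call(rbind, rows)
  fr <- do.call(rbind, lapply(sort(unique(per_set$n_cells)), function(N) {
    sub <- per_set[per_set$n_cells == N, ]
    wi <- wilson_interval(sum(sub$incorrect), nrow(sub))
    data.frame(n_cells = N, n_sets = nrow(sub),
               frac_incorrect = mean(sub$incorrect),
               wilson_lower = wi[1], wilson_upper = wi[2])
  }))
  list(per_set = per_set, fractions = fr)
}

# default 10-point tuning ranges: log-spaced across the five-value grid
# range of grid_625 (linear for selection probabilities)
tuning_range <- function(model, param) {
  rng <- switch(model,
    TSM = switch(param, rho = c(10, 30), c(0.3, 4)),
    CPM = switch(param, rho = c(10, 30), q1 = c(0.1, 0.9), q2 = c(0.1, 0.9),
                 c(0.5, 8)),
    PFM = switch(param, rho = c(10, 30), mu = c(0.05, 1.5), c(0.3, 4)),
    NFM = switch(param, rho = c(10, 30), nu = c(0.05, 1.5), c(0.3, 4)))
  if (param %in% c("q1", "q2")) return(seq(rng[1], rng[2], length.out = 10))
  exp(seq(log(rng[1]), log(rng[2]), length.out = 10))
}

#' Tuning-scan experiment: effective parameters under a varying condition
#'
#' Tunes one parameter of a complex model over 10 values (the others
#' fixed), simulates and fits each condition to the telegraph model, and
#' reports the effective parameters as a function of the mean expression
#' level, normalized to 1 at the lowest-mean condition, with a trend label
#' per effective parameter: "invariant" if the normalized fold change is
#' < \code{fold_min}; "increasing"/"decreasing" if the series is strictly
#' rank-monotone in the mean and changes by >= \code{fold_min};
#' "non-monotonic" otherwise. Conditions whose mean expression does not
#' change at least two-fold across the scan are rejected, matching the
#' study-design filter.
#'
#' @param fixed_params \code{complex_params} holding the non-tuned values
#' @param tuning_param name of the tuned parameter
#' @param tuning_values optional explicit values (default: the grid range
#'   log-extended one step, 10 points)
#' @param n_cells cells per condition
#' @param seed root seed
#' @param fold_min invariance threshold (default 1.5)
#' @return object of class \code{tuning_scan}: data.frame (one row per
#'   condition) with attributes \code{trends} (named labels for lam_bar,
#'   gam_bar, rho_bar) and \code{tuning_param}
#' @export
tuning_scan <- function(fixed_params, tuning_param, tuning_values = NULL,
                        n_cells = 1e4, seed = 1, fold_min = 1.5) {
  if (is.null(tuning_values))
    tuning_values <- tuning_range(fixed_params$model, tuning_param)
  stopifnot(length(tuning_values) >= 3)
  rows <- lapply(seq_along(tuning_values), function(i) {
    p <- fixed_params
    if (tuning_param == "q2") {
      p$q2 <- tuning_values[i]; p$q1 <- 1 - p$q2
    } else if (tuning_param == "q1") {
      p$q1 <- tuning_values[i]; p$q2 <- 1 - p$q1
    } else p[[tuning_param]] <- tuning_values[i]
    cells <- sample_steady_state(p, n_cells, seed = set_seed_i(seed, i))
    fit <- fit_telegraph_mle(cells$count, d = p$d,
                             seed = set_seed_i(seed, i, 1L))
    data.frame(tuning_value = tuning_values[i], mean_expr = mean(cells$count),
               lam_bar = fit$params$lam_bar, gam_bar = fit$params$gam_bar,
               rho_bar = fit$params$rho_bar)
  })
  res <- do.call(rbind, rows)
  if (max(res$mean_expr) < 2 * min(res$mean_expr))
    stop("mean expression changes less than two-fold across the scan; ",
         "condition rejected")
  res <- res[order(res$mean_expr), ]
  i0 <- 1 # lowest mean
  for (pn in c("lam_bar", "gam_bar", "rho_bar"))
    res[[paste0(pn, "_norm")]] <- res[[pn]] / res[[pn]][i0]
  trends <- vapply(c("lam_bar", "gam_bar", "rho_bar"), function(pn) {
    y <- res[[paste0(pn, "_norm")]]
    fold <- max(y) / min(y)
    if (fold < fold_min) return("invariant")
    rho_s <- stats::cor(res$mean_expr, y, method = "spearman")
    # 0.95 tolerates one adjacent rank swap from fit noise in a 10-point
    # scan while rejecting genuinely humped series
    if (rho_s >= 0.95) "increasing"
    else if (rho_s <= -0.95) "decreasing"
    else "non-monotonic"
  }, "")
  structure(res, trends = trends, tuning_param = tuning_param,
            class = c("tuning_scan", "data.frame"))
}

#' Response-time experiment: complex model vs effective telegraph model
#'
#' For each parameter set: fit steady-state SSA data to the telegraph
#' model, compute the FSP mean curves of the generating model and of its
#' effective telegraph model from the silenced initial condition, and the
#' response-time gap \code{G = d (tau_e - tau_c)} (response time = first
#' half-rise crossing of each curve's own steady-state mean).
#'
#' @param params_list list of \code{complex_params}
#' @param n_cells cells per set
#' @param seed root seed
#' @return data.frame with per-set \code{tau_c}, \code{tau_e}, \code{G}
#' @export
run_response_time_experiment <- function(params_list, n_cells = 1e4,
                                         seed = 1) {
  rows <- lapply(seq_along(params_list), function(i) try_set(i, {
    truth <- params_list[[i]]
    cells <- sample_steady_state(truth, n_cells, seed = set_seed_i(seed, i))
    fit <- fit_telegraph_mle(cells$count, d = truth$d,
                             seed = set_seed_i(seed, i, 1L))
    curve_c <- mean_curve_auto(truth)
    curve_e <- mean_curve_auto(fit$params)
    g <- response_time_gap(curve_c, curve_e, d = truth$d)
    data.frame(model = truth$model, set = i, tau_c = g$tau_c,
               tau_e = g$tau_e, G = g$G,
               lam_bar = fit$params$lam_bar, gam_bar = fit$params$gam_bar,
               rho_bar = fit$params$rho_bar)
  }))
  bind_sets(rows)
}

#' Extrinsic-noise robustness experiment
#'
#' Repeats the steady-state fit experiment under several extrinsic-noise
#' levels (log-normal per-cell synthesis rate) and summarizes the relative
#' error of the model's headline parameter (lam_bar for NFM, rho_bar
#' otherwise) together with the fit quality.
#'
#' @param params_list list of \code{complex_params} for one model
#' @param noise_levels CVs of the per-cell synthesis rate
#' @param n_cells cells per set
#' @param seed root seed (shared across noise levels so the 0-noise run
#'   reproduces the noiseless pipeline)
#' @return list with \code{per_set} and \code{summary} data.frames
#' @export
run_robustness_experiment <- function(params_list,
                                      noise_levels = c(0, 0.05, 0.1, 0.5),
                                      n_cells = 1e4, seed = 1) {
  model <- params_list[[1]]$model
  key <- if (model == "NFM") "RE_lam" else "RE_rho"
  per <- lapply(noise_levels, function(nl) {
    res <- run_steady_fit_experiment(params_list, n_cells = n_cells,
                                     seed = seed, noise = nl,
                                     conditionals = FALSE)
    res$noise_level <- nl
    res
  })
  per_set <- do.call(rbind, per)
  summary <- do.call(rbind, lapply(per, function(res) {
    re <- abs(res[[key]])
    data.frame(noise_level = res$noise_level[1], param = key,
               mean_abs_re = mean(re), sd_abs_re = sd(re),
               frac_gt_0.2 = mean(re > 0.2), max_hd = max(res$HD))
  }))
  list(per_set = per_set, summary = summary)
}
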