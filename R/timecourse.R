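# Fitting models to snapshot distributions at multiple time points and
# profile-likelihood confidence intervals.

# N(t_l, n) table: times x counts(0..n_max)
snapshot_table <- function(snapshots, n_max = max(snapshots$counts)) {
  t(apply(snapshots$counts, 2, function(x)
    tabulate(x + 1L, nbins = n_max + 1L)))
}

timecourse_free_params <- function(params) {
  switch(params$model,
    TM  = c("lam_bar", "gam_bar", "rho_bar"),
    TSM = c("lam1", "lam2", "gam", "rho"),
    CPM = c("lam1", "lam2", "gam", "rho", "q2"),
    PFM = c("lam", "gam", "rho", "mu"),
    NFM = c("lam", "gam", "rho", "nu"))
}

#' Time-course log-likelihood of snapshot data
#'
#' \code{sum_l sum_n N(t_l, n) log P_n(t_l, theta)} with the transient
#' distributions computed by finite-state projection from the silenced
#' initial condition (no gene product, gene inactive; CPM starts in the
#' (q1, q2) mixture over its two off states). Model probabilities are
#' floored at 1e-300.
#'
#' @param params a model parameter object
#' @param snapshots a \code{snapshot_series}
#' @param n_max optional truncation override
#' @param tol FSP probability-loss tolerance
#' @return the log-likelihood
#' @export
loglik_timecourse <- function(params, snapshots, n_max = NULL, tol = 1e-8) {
  tab <- snapshot_table(snapshots)
  maxc <- ncol(tab) - 1L
  if (is.null(n_max)) n_max <- as.integer(ceiling(1.3 * maxc + 15))
  fs <- fsp_transient(params, snapshots$times, n_max = n_max, tol = tol)
  P <- pmax(fs$marginal[, seq_len(maxc + 1L), drop = FALSE], 1e-300)
  sum(tab * log(P))
}

#' Fit a model to snapshot data at multiple time points
#'
#' Maximizes the time-course likelihood over the model's free parameters
#' (rates via \code{theta = exp(theta~)}; the CPM strong-pathway selection
#' probability via \code{q2 = 1 - exp(-|q2~|)}), with the decay rate fixed.
#' Multi-start Nelder-Mead around the template values.
#'
#' @param template a \code{telegraph_params} or \code{complex_params} object
#'   providing the model, fixed d and the central starting values
#' @param snapshots a \code{snapshot_series}
#' @param n_starts number of starts (template + perturbations)
#' @param perturb_sd log-scale sd of the start perturbations
#' @param control passed to \code{\link[stats]{optim}}
#' @param seed optional RNG seed for the perturbations
#' @return object of class \code{timecourse_fit}: list with \code{params},
#'   \code{logL}, \code{hd_per_time}, \code{hd_total}, \code{converged}
#' @export
fit_timecourse <- function(template, snapshots, n_starts = 10,
                           perturb_sd = 0.5,
                           control = list(reltol = 1e-9, maxit = 1500),
                           seed = NULL) {
  maybe_seed(seed)
  nm <- timecourse_free_params(template)
  tab <- snapshot_table(snapshots)
  maxc <- ncol(tab) - 1L
  n_max <- as.integer(ceiling(1.3 * maxc + 15))
  nonzero <- tab > 0
  nll <- function(th) {
    if (any(abs(th) > 12)) return(1e12)
    p <- set_free_params_any(template, nm, th)
    if (is.null(p)) return(1e12)
    fs <- tryCatch(
      fsp_run(p, snapshots$times, "silenced", n_max, 1e-6, "off1", FALSE,
              n_gene_states(p)),
      error = function(e) NULL)
    if (is.null(fs) || max(fs$loss) > 1e-3) return(1e12)
    P <- pmax(fs$marginal[, seq_len(maxc + 1L), drop = FALSE], 1e-300)
    -sum(tab[nonzero] * log(P[nonzero]))
  }
  th0 <- free_params_to_theta_any(template, nm)
  starts <- rbind(th0,
                  if (n_starts > 1)
                    t(replicate(n_starts - 1,
                                th0 + rnorm(length(th0), 0, perturb_sd))))
  best <- NULL; conv <- FALSE
  for (i in seq_len(nrow(starts))) {
    o <- optim(starts[i, ], nll, method = "Nelder-Mead", control = control)
    if (is.null(best) || o$value < best$value) best <- o
    if (o$convergence == 0) conv <- TRUE
  }
  pars <- set_free_params_any(template, nm, best$par)
  fs <- fsp_transient(pars, snapshots$times, n_max = n_max, tol = 1e-8)
  nt <- length(snapshots$times)
  hd <- vapply(seq_len(nt), function(l) {
    emp <- tab[l, ] / sum(tab[l, ])
    hellinger(emp, fs$marginal[l, ])
  }, 0)
  structure(list(params = pars, logL = -best$value, hd_per_time = hd,
                 hd_total = sum(hd), converged = conv,
                 free_params = nm, n_max = n_max,
                 theta_hat = best$par),
            class = "timecourse_fit")
}

# transform helpers that also work for telegraph_params templates
set_free_params_any <- function(template, nm, th) {
  if (template$model == "TM") {
    v <- unname(exp(th))
    out <- template
    out[nm] <- as.list(v)
    return(out)
  }
  set_free_params(template, nm, th)
}

free_params_to_theta_any <- function(template, nm) {
  if (template$model == "TM")
    return(log(unlist(template[nm])))
  free_params_to_theta(template, nm)
}

#' @export
print.timecourse_fit <- function(x, ...) {
  cat("<timecourse_fit> ", x$params$model, " model, logL=",
      format(x$logL, digits = 8), ", total HD=",
      format(x$hd_total, digits = 4), "\n", sep = "")
  print(x$params)
  invisible(x)
}

#' Profile-likelihood confidence interval
#'
#' Fixes one parameter on a grid, re-maximizes the time-course likelihood
#' over the remaining parameters (warm-started outward from the MLE), and
#' forms the profile statistic \code{q(v) = 2 [logL_max - logL~(v)]}. The
#' 95\% interval is \code{{v : q(v) < 3.84}} (chi-square with 1 df);
#' endpoints are interpolated in log-parameter space. Grids default to 41
#' log-spaced points over +/- 2 decades around the point estimate.
#'
#' @param fit a \code{timecourse_fit}
#' @param snapshots the data the fit was computed from
#' @param param_name one of the fit's free parameters
#' @param grid optional vector of parameter values to profile over
#' @param level confidence level (default 0.95)
#' @param control optimizer control for the profile re-fits
#' @return object of class \code{ci_summary}: list with \code{param},
#'   \code{estimate}, \code{lower}, \code{upper}, \code{uncertainty}
#'   (width/estimate), \code{open_ended}, and the profile \code{trace}
#'   (data.frame value, q)
#' @export
profile_likelihood_ci <- function(fit, snapshots, param_name, grid = NULL,
                                  level = 0.95,
                                  control = list(reltol = 1e-8, maxit = 800)) {
  stopifnot(inherits(fit, "timecourse_fit"))
  nm <- fit$free_params
  if (!param_name %in% nm) stop("unknown free parameter: ", param_name)
  template <- fit$params
  qcut <- stats::qchisq(level, df = 1)
  est <- if (param_name == "q2") template$q2 else template[[param_name]]
  if (is.null(grid)) grid <- est * 10^seq(-2, 2, length.out = 41)
  grid <- sort(grid)
  i_fix <- match(param_name, nm)
  nm_free <- nm[-i_fix]
  tab <- snapshot_table(snapshots)
  maxc <- ncol(tab) - 1L
  n_max <- fit$n_max
  nonzero <- tab > 0
  prof_nll <- function(th_free, v) {
    th <- numeric(length(nm))
    th[-i_fix] <- th_free
    th[i_fix] <- if (param_name == "q2") -log(1 - v) else log(v)
    if (any(abs(th) > 14)) return(1e12)
    p <- set_free_params_any(template, nm, th)
    if (is.null(p)) return(1e12)
    fs <- tryCatch(
      fsp_run(p, snapshots$times, "silenced", n_max, 1e-6, "off1", FALSE,
              n_gene_states(p)),
      error = function(e) NULL)
    if (is.null(fs) || max(fs$loss) > 1e-3) return(1e12)
    P <- pmax(fs$marginal[, seq_len(maxc + 1L), drop = FALSE], 1e-300)
    -sum(tab[nonzero] * log(P[nonzero]))
  }
  profile_at <- function(v, th_start) {
    o <- optim(th_start, prof_nll, v = v, method = "Nelder-Mead",
               control = control)
    list(logL = -o$value, th = o$par)
  }
  th_hat_free <- fit$theta_hat[-i_fix]
  # walk outward from the estimate in both directions, warm-starting, then
  # refine each q = qcut crossing by bisection in log-parameter space
  evals <- list()
  refine_cross <- function(v_in, q_in, th_in, v_out, q_out, n_iter = 6) {
    th_ws <- th_in
    for (it in seq_len(n_iter)) {
      if (abs(q_in - qcut) < 0.15) break
      v_mid <- exp((log(v_in) + log(v_out)) / 2)
      pr <- profile_at(v_mid, th_ws)
      q_mid <- max(0, 2 * (fit$logL - pr$logL))
      evals[[length(evals) + 1]] <<- c(value = v_mid, q = q_mid)
      if (q_mid <= qcut) {
        v_in <- v_mid; q_in <- q_mid; th_ws <- pr$th
      } else {
        v_out <- v_mid; q_out <- q_mid
      }
    }
    # linear interpolation of the refined bracket in log space
    exp(log(v_in) + (qcut - q_in) / (q_out - q_in) * (log(v_out) - log(v_in)))
  }
  bounds <- c(lower = NA_real_, upper = NA_real_)
  below <- rev(grid[grid < est]); above <- grid[grid >= est]
  for (side_name in c("lower", "upper")) {
    side <- if (side_name == "lower") below else above
    th_ws <- th_hat_free
    v_in <- est; q_in <- 0; th_in <- th_hat_free
    for (v in side) {
      pr <- profile_at(v, th_ws)
      th_ws <- pr$th
      q <- max(0, 2 * (fit$logL - pr$logL))
      evals[[length(evals) + 1]] <- c(value = v, q = q)
      if (q > qcut) {
        bounds[side_name] <- refine_cross(v_in, q_in, th_in, v, q)
        break
      }
      v_in <- v; q_in <- q; th_in <- pr$th
    }
  }
  tr <- as.data.frame(do.call(rbind, evals))
  tr <- tr[order(tr$value), ]
  lower <- bounds[["lower"]]; upper <- bounds[["upper"]]
  open <- c(lower = is.na(lower), upper = is.na(upper))
  if (is.na(lower)) lower <- min(tr$value)
  if (is.na(upper)) upper <- max(tr$value)
  structure(list(param = param_name, estimate = est, lower = lower,
                 upper = upper, uncertainty = (upper - lower) / est,
                 open_ended = open, level = level, trace = tr),
            class = "ci_summary")
}

#' @export
print.ci_summary <- function(x, ...) {
  cat(sprintf("<ci_summary> %s = %.4g, %g%% CI [%.4g, %.4g]%s, uncertainty %.3g\n",
              x$param, x$estimate, 100 * x$level, x$lower, x$upper,
              if (any(x$open_ended)) " (open-ended)" else "",
              x$uncertainty))
  invisible(x)
}
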