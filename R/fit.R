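# Maximum-likelihood fitting of count data to the telegraph model,
# goodness-of-fit distances, AICc model selection and shape classification.

#' Moment-matched starting point for the telegraph MLE
#'
#' The synthesis-rate start is set from the largest observed count
#' (\code{rho0 = d * max(counts)}); the switching-rate starts follow from
#' matching the sample mean and variance to the Beta-Poisson moments of the
#' telegraph model: with \code{r = rho0/d}, \code{p0 = mean/r},
#' \code{a + b + 1 = r (1 - p0) / (Fano - 1)}, \code{a = p0 (a + b)}.
#' Degenerate cases (Fano near or below 1) fall back to a fast-switching,
#' near-constitutive start.
#'
#' @param counts non-negative integer counts, not all zero
#' @param d known decay rate
#' @return a \code{telegraph_params} starting point
#' @export
initial_values <- function(counts, d = 1) {
  stopifnot(length(counts) > 0, all(counts >= 0))
  if (all(counts == 0)) stop("all counts are zero: no information about rho")
  rho0 <- d * max(counts)
  m <- mean(counts); v <- var(counts)
  if (!is.finite(v) || v <= 0) v <- m
  r <- rho0 / d
  p0 <- min(max(m / r, 1e-4), 1 - 1e-4)
  fano <- v / m
  s <- if (fano > 1 + 1e-8) r * (1 - p0) / (fano - 1) - 1 else 100
  if (!is.finite(s) || s <= 1e-3) s <- 100
  a <- min(max(p0 * s, 1e-3), 1e4)
  b <- min(max((1 - p0) * s, 1e-3), 1e4)
  telegraph_params(lam_bar = a * d, gam_bar = b * d, rho_bar = rho0, d = d)
}

#' Fit the telegraph model to counts by maximum likelihood
#'
#' Maximizes \code{sum_n N(n) log P_n(theta)} over (lam_bar, gam_bar,
#' rho_bar) with the decay rate \code{d} fixed. Positivity is enforced by
#' optimizing log-parameters (Nelder-Mead); the moment-matched start of
#' \code{\link{initial_values}} is augmented with log-normal perturbations
#' (factor-e scale) for a multi-start search.
#'
#' @param counts non-negative integer counts
#' @param d known decay rate (default 1)
#' @param n_starts number of starts (default 20: heuristic + 19 perturbed)
#' @param seed optional RNG seed for the start perturbations
#' @param control passed to \code{\link[stats]{optim}}
#' @return object of class \code{telegraph_fit}: list with \code{params},
#'   \code{logL}, \code{AICc}, \code{HD}, \code{KLD}, \code{n_starts},
#'   \code{converged}, \code{n}
#' @export
fit_telegraph_mle <- function(counts, d = 1, n_starts = 20, seed = NULL,
                              control = list(reltol = 1e-10, maxit = 2000)) {
  stopifnot(length(counts) > 0, all(counts >= 0))
  if (all(counts == 0)) stop("all counts are zero: telegraph fit undefined")
  maybe_seed(seed)
  N <- length(counts)
  maxc <- max(counts)
  tab <- tabulate(counts + 1L, nbins = maxc + 1L)
  # box (on the log scale) keeping the pmf series cheap and the fit sane
  lo <- log(1e-6); hi_rate <- log(1e4); hi_rho <- log(d * 10 * (maxc + 10))
  nll <- function(th) {
    if (anyNA(th) || any(th < lo) || th[1] > hi_rate || th[2] > hi_rate ||
        th[3] > hi_rho)
      return(1e12)
    v <- -cpp_telegraph_loglik(tab, exp(th[1]), exp(th[2]), exp(th[3]), d)
    if (!is.finite(v)) 1e12 else v
  }
  st <- initial_values(counts, d)
  th0 <- log(c(st$lam_bar, st$gam_bar, st$rho_bar))
  # deliberately slow-switching start: anchors the identifiable end of the
  # fast-switching ridge that near-Poisson data leave flat
  s0 <- st$lam_bar + st$gam_bar
  th_slow <- if (s0 > 20 * d)
    log(c(st$lam_bar, st$gam_bar, st$rho_bar) * c(rep(20 * d / s0, 2), 1))
  else NULL
  starts <- rbind(th0, th_slow,
                  if (n_starts > 1)
                    t(replicate(n_starts - 1, th0 + rnorm(3, 0, 1))))
  opts <- list()
  conv <- FALSE
  for (i in seq_len(nrow(starts))) {
    o <- optim(starts[i, ], nll, method = "Nelder-Mead", control = control)
    opts[[i]] <- o
    if (o$convergence == 0) conv <- TRUE
  }
  vals <- vapply(opts, `[[`, 0, "value")
  # tie-break on the degenerate ridge: among optima statistically
  # indistinguishable from the best (within ridge_tol logL units), report
  # the slowest-switching representative
  ridge_tol <- 2.0
  cand <- which(vals <= min(vals) + ridge_tol)
  sums <- vapply(cand, function(i) sum(exp(opts[[i]]$par[1:2])), 0)
  best <- opts[[cand[which.min(sums)]]]
  pars <- telegraph_params(exp(best$par[1]), exp(best$par[2]),
                           exp(best$par[3]), d)
  logL <- -best$value
  model_pmf <- telegraph_pmf_extended(pars, maxc)
  emp <- tab / N
  structure(list(params = pars, logL = logL,
                 AICc = aicc(logL, k = 3, N = N),
                 HD = hellinger(emp, model_pmf),
                 KLD = kld(emp, model_pmf),
                 n_starts = n_starts, converged = conv, n = N),
            class = "telegraph_fit")
}

#' @export
print.telegraph_fit <- function(x, ...) {
  p <- x$params
  cat(sprintf(paste0("<telegraph_fit> lam_bar=%.4g gam_bar=%.4g rho_bar=%.4g",
                     " (d=%.3g)\n  logL=%.2f AICc=%.2f HD=%.4f KLD=%.5f",
                     " converged=%s\n"),
              p$lam_bar, p$gam_bar, p$rho_bar, p$d,
              x$logL, x$AICc, x$HD, x$KLD, x$converged))
  invisible(x)
}

# model pmf on a support wide enough that the ignored tail mass is < 1e-7
telegraph_pmf_extended <- function(pars, n_lo, tail_tol = 1e-7) {
  n_hi <- n_lo + 30L
  repeat {
    p <- telegraph_pmf_analytic(pars, n_hi)
    if (1 - sum(p) < tail_tol || n_hi > n_lo + 4000L) return(p)
    n_hi <- n_hi * 2L + 50L
  }
}

pad_common <- function(p, q) {
  L <- max(length(p), length(q))
  list(p = c(p, rep(0, L - length(p))), q = c(q, rep(0, L - length(q))))
}

check_norm <- function(x, name) {
  s <- sum(x)
  if (abs(s - 1) > 1e-6) {
    warning(name, " does not sum to 1 (", format(s), "); renormalizing")
    x <- x / s
  }
  x
}

#' Hellinger distance between two pmfs
#'
#' \code{HD = sqrt(1 - sum sqrt(p q))}, in [0, 1]. Supports of different
#' length are zero-padded; inputs off normalization by more than 1e-6 are
#' renormalized with a warning.
#'
#' @param p,q numeric pmfs over 0..n
#' @return distance in [0, 1]
#' @export
hellinger <- function(p, q) {
  pq <- pad_common(p, q)
  p <- check_norm(pq$p, "p"); q <- check_norm(pq$q, "q")
  sqrt(max(0, 1 - sum(sqrt(p * q))))
}

#' Kullback-Leibler divergence KL(p || q)
#'
#' \code{sum p log(p/q)} with \code{0 log 0 = 0}; requires \code{q > 0}
#' wherever \code{p > 0}.
#'
#' @param p data (reference) pmf
#' @param q model pmf
#' @return divergence >= 0
#' @export
kld <- function(p, q) {
  pq <- pad_common(p, q)
  p <- check_norm(pq$p, "p"); q <- check_norm(pq$q, "q")
  i <- p > 0
  if (any(q[i] <= 0)) stop("KL divergence undefined: model support violation")
  sum(p[i] * log(p[i] / q[i]))
}

#' Corrected Akaike information criterion
#'
#' \code{AICc = -2 logL + 2k + 2k(k+1)/(N-k-1)}.
#'
#' @param logL maximized log-likelihood
#' @param k number of free parameters
#' @param N sample size (> k + 1)
#' @return criterion value
#' @export
aicc <- function(logL, k, N) {
  if (N <= k + 1) stop("AICc requires N > k + 1")
  -2 * logL + 2 * k + 2 * k * (k + 1) / (N - k - 1)
}

#' Classify the shape of a model pmf
#'
#' Labels a (model-evaluated, not raw empirical) pmf as one of
#' "unimodal-zero-peak", "unimodal-nonzero-peak" or "bimodal": a zero peak
#' is present iff \code{P_0 > P_1}; an interior mode iff some \code{n >= 1}
#' has \code{P_n > P_{n-1}} and \code{P_n >= P_{n+1}}; bimodal iff both.
#'
#' @param pmf numeric pmf over 0..n
#' @return one of the three shape labels
#' @export
classify_shape <- function(pmf) {
  if (length(pmf) == 0) stop("empty pmf")
  if (length(pmf) == 1) return("unimodal-zero-peak")
  zero_peak <- pmf[1] > pmf[2]
  pmf_ext <- c(pmf, 0)
  interior <- FALSE
  if (length(pmf) >= 2) {
    nn <- 2:length(pmf)
    interior <- any(pmf_ext[nn] > pmf_ext[nn - 1] & pmf_ext[nn] >= pmf_ext[nn + 1])
  }
  if (zero_peak && interior) "bimodal"
  else if (zero_peak) "unimodal-zero-peak"
  else "unimodal-nonzero-peak"
}

# -------- complex-model steady-state MLE (for AICc model selection) --------

# free-parameter template: names and transform box per model (lam1 fixed at
# its template value for CPM so every complex model has 4 free parameters)
complex_free_params <- function(template) {
  switch(template$model,
    TSM = c("lam1", "lam2", "gam", "rho"),
    CPM = c("lam2", "gam", "rho", "q2"),
    PFM = c("lam", "gam", "rho", "mu"),
    NFM = c("lam", "gam", "rho", "nu"))
}

set_free_params <- function(template, nm, th) {
  # th unconstrained: theta = exp(theta~) for rates, q2 = 1 - exp(-|q2~|)
  th <- unname(th)
  for (i in seq_along(nm)) {
    template[[nm[i]]] <- if (nm[i] == "q2") {
      q <- 1 - exp(-abs(th[i]))
      min(max(q, 1e-6), 1 - 1e-6)
    } else exp(th[i])
  }
  if (template$model == "CPM") {
    template$q1 <- 1 - template$q2
    if (template$lam2 <= template$lam1) return(NULL) # strong pathway violated
  }
  template
}

free_params_to_theta <- function(template, nm) {
  vapply(nm, function(f)
    if (f == "q2") -log(1 - template[[f]]) else log(template[[f]]), 0)
}

#' Fit a complex model to steady-state counts by maximum likelihood
#'
#' Maximizes the multinomial log-likelihood with the model pmf computed from
#' the CME null space at each evaluation. Four free parameters per model
#' (CPM: \code{lam1} stays fixed at its template value). Starts at the
#' template parameters plus log-normal perturbations.
#'
#' @param counts non-negative integer counts
#' @param template a \code{complex_params} object giving the model, the
#'   fixed quantities (d, cooperativity, CPM lam1) and the starting values
#' @param n_starts multi-start count (default 3)
#' @param control passed to \code{\link[stats]{optim}}
#' @return list with \code{params}, \code{logL}, \code{AICc}, \code{k}
#' @export
fit_complex_mle <- function(counts, template, n_starts = 3,
                            control = list(reltol = 1e-8, maxit = 500)) {
  stopifnot(inherits(template, "complex_params"), all(counts >= 0))
  N <- length(counts)
  maxc <- max(counts)
  tab <- tabulate(counts + 1L, nbins = maxc + 1L)
  n_max <- as.integer(ceiling(1.3 * maxc + 15))
  nm <- complex_free_params(template)
  nll <- function(th) {
    if (any(abs(th) > 12)) return(1e12)
    p <- set_free_params(template, nm, th)
    if (is.null(p)) return(1e12)
    pm <- tryCatch(
      colSums(matrix(null_solve(generator_matrix(p, n_max)),
                     nrow = n_gene_states(p))),
      error = function(e) NULL)
    if (is.null(pm)) return(1e12)
    pm <- pmax(pm[seq_len(maxc + 1L)], 1e-300)
    -sum(tab[tab > 0] * log(pm[tab > 0]))
  }
  th0 <- free_params_to_theta(template, nm)
  starts <- rbind(th0,
                  if (n_starts > 1)
                    t(replicate(n_starts - 1, th0 + rnorm(length(th0), 0, 0.5))))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    o <- optim(starts[i, ], nll, method = "Nelder-Mead", control = control)
    if (is.null(best) || o$value < best$value) best <- o
  }
  k <- length(nm)
  logL <- -best$value
  list(params = set_free_params(template, nm, best$par), logL = logL,
       AICc = aicc(logL, k = k, N = N), k = k)
}

# bare null-space solve used in likelihood loops (no adaptive growth)
null_solve <- function(A) {
  dim <- nrow(A)
  A[1L, ] <- 1
  p <- as.numeric(Matrix::solve(A, c(1, rep(0, dim - 1L))))
  p[p < 0] <- 0
  p / sum(p)
}

#' AICc model selection: telegraph vs a complex model
#'
#' Fits both the telegraph model (k = 3) and the complex model of the
#' template (k = 4) to the same steady-state counts and returns the
#' lower-AICc winner. Exact ties resolve to the telegraph model (fewer
#' parameters).
#'
#' @param counts non-negative integer counts
#' @param template a \code{complex_params} object (see
#'   \code{\link{fit_complex_mle}})
#' @param d decay rate for the telegraph fit
#' @param n_starts_tm,n_starts_complex multi-start counts
#' @return list with \code{winner} ("telegraph" or "complex"),
#'   \code{aicc_tm}, \code{aicc_complex}, and both fits
#' @export
select_model <- function(counts, template, d = template$d,
                         n_starts_tm = 20, n_starts_complex = 3) {
  ft <- fit_telegraph_mle(counts, d = d, n_starts = n_starts_tm)
  fc <- fit_complex_mle(counts, template, n_starts = n_starts_complex)
  winner <- if (fc$AICc < ft$AICc) "complex" else "telegraph"
  list(winner = winner, aicc_tm = ft$AICc, aicc_complex = fc$AICc,
       fit_tm = ft, fit_complex = fc)
}
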