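#' @importFrom Matrix sparseMatrix Diagonal colSums rowSums t solve
NULL

# gene-state switching transitions of a model: list of (from, to, rate(n))
switch_transitions <- function(params) {
  pv <- pars_vector(params)
  cp <- coop_of(params); ff <- params$feedback_form %||% "factorial"
  switch(params$model,
    TM = list(list(0L, 1L, function(n) rep(pv[["lam1"]], length(n))),
              list(1L, 0L, function(n) rep(pv[["gam"]], length(n)))),
    TSM = list(list(0L, 1L, function(n) rep(pv[["lam1"]], length(n))),
               list(1L, 2L, function(n) rep(pv[["lam2"]], length(n))),
               list(2L, 0L, function(n) rep(pv[["gam"]], length(n)))),
    CPM = list(list(0L, 2L, function(n) rep(pv[["lam1"]], length(n))),
               list(1L, 2L, function(n) rep(pv[["lam2"]], length(n))),
               list(2L, 0L, function(n) rep(pv[["gam"]] * pv[["q1"]], length(n))),
               list(2L, 1L, function(n) rep(pv[["gam"]] * (1 - pv[["q1"]]), length(n)))),
    PFM = list(list(0L, 1L, function(n) pv[["lam1"]] + pv[["mu"]] * fcoop(n, cp, ff)),
               list(1L, 0L, function(n) rep(pv[["gam"]], length(n)))),
    NFM = list(list(0L, 1L, function(n) rep(pv[["lam1"]], length(n))),
               list(1L, 0L, function(n) pv[["gam"]] + pv[["nu"]] * fcoop(n, cp, ff))))
}

#' Truncated CME generator
#'
#' Assembles the sparse transition-rate operator \code{A} of the chemical
#' master equation \code{dp/dt = A p} over the state space (gene state,
#' copy number) with copy number truncated at \code{n_max}. States are
#' ordered gene-state-fastest: index \code{i + S*n + 1}. Interior columns sum
#' to zero; at \code{n = n_max} the synthesis propensity is kept in the
#' diagonal with no destination, so probability leaks out of the projection
#' there (the usual finite-state projection sink, giving a computable error
#' bound).
#'
#' @param params a model parameter object
#' @param n_max copy-number truncation (>= 1)
#' @return a sparse \code{dgCMatrix} of dimension \code{S*(n_max+1)}
#' @export
generator_matrix <- function(params, n_max) {
  stopifnot(n_max >= 1)
  S <- n_gene_states(params)
  on <- on_state(params)
  pv <- pars_vector(params)
  n <- 0:n_max
  idx <- function(i, nn) i + S * nn + 1L
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  outflow <- numeric(S * (n_max + 1))
  add <- function(from, to, rate) {
    keep <- rate > 0
    ii <<- c(ii, to[keep]); jj <<- c(jj, from[keep]); xx <<- c(xx, rate[keep])
  }
  # synthesis (on state): n -> n+1, boundary outflow at n_max
  from <- idx(on, n); rate <- rep(pv[["rho"]], n_max + 1)
  outflow[from] <- outflow[from] + rate
  add(from[-(n_max + 1)], idx(on, n[-1]), rate[-(n_max + 1)])
  # decay: d*n for every gene state
  for (i in 0:(S - 1L)) {
    from <- idx(i, n[-1]); rate <- pv[["d"]] * n[-1]
    outflow[from] <- outflow[from] + rate
    add(from, idx(i, n[-(n_max + 1)]), rate)
  }
  # gene-state switching
  for (tr in switch_transitions(params)) {
    rate <- tr[[3]](n)
    from <- idx(tr[[1]], n)
    outflow[from] <- outflow[from] + rate
    add(from, idx(tr[[2]], n), rate)
  }
  dim <- S * (n_max + 1L)
  A <- sparseMatrix(i = ii, j = jj, x = xx, dims = c(dim, dim))
  A - Diagonal(dim, outflow)
}

#' Steady-state joint distribution from the CME null space
#'
#' Solves \code{A p = 0} on the truncated state space (one balance equation
#' replaced by the normalization constraint) and grows \code{n_max} until the
#' probability mass in the top copy-number bin falls below \code{tol}.
#'
#' @param params a model parameter object
#' @param tol tail-mass tolerance (default 1e-10)
#' @param n_max optional starting truncation
#' @param n_max_cap hard cap signalling pathological parameters
#' @return object of class \code{joint_pmf}: list with \code{P} (matrix,
#'   gene states x copy numbers 0..n_max), \code{n_max}, \code{p_off},
#'   \code{tail} and \code{params}
#' @export
steady_state_pmf <- function(params, tol = 1e-10, n_max = NULL,
                             n_max_cap = 20000L) {
  pv <- pars_vector(params)
  if (is.null(n_max)) n_max <- as.integer(ceiling(3 * pv[["rho"]] / pv[["d"]] + 20))
  S <- n_gene_states(params)
  repeat {
    A <- generator_matrix(params, n_max)
    dim <- S * (n_max + 1L)
    M <- A
    M[1L, ] <- 1
    b <- c(1, rep(0, dim - 1L))
    p <- as.numeric(Matrix::solve(M, b))
    p[p < 0] <- 0
    p <- p / sum(p)
    P <- matrix(p, nrow = S)
    tail <- sum(P[, n_max + 1L])
    if (tail < tol || n_max >= n_max_cap) break
    n_max <- min(n_max * 2L, n_max_cap)
  }
  if (tail >= tol)
    stop("steady-state solve failed to confine the tail below tol at n_max cap")
  structure(list(P = P, n_max = n_max, p_off = 1 - sum(P[S, ]),
                 tail = tail, params = params),
            class = "joint_pmf")
}

#' Marginal copy-number pmf of a joint distribution
#' @param joint a \code{joint_pmf}
#' @return numeric vector over counts 0..n_max
#' @export
marginal_pmf <- function(joint) colSums(joint$P)

#' @export
print.joint_pmf <- function(x, ...) {
  cat("<joint_pmf> ", x$params$model, " model, n_max=", x$n_max,
      ", P_off=", format(x$p_off, digits = 4),
      ", tail=", format(x$tail, digits = 2), "\n", sep = "")
  invisible(x)
}

#' Analytic steady-state telegraph pmf
#'
#' Closed-form stationary distribution of the telegraph model,
#' \deqn{P_n = \frac{(\rho/d)^n}{n!}
#'   \frac{(\lambda/d)_n}{((\lambda+\gamma)/d)_n}
#'   {}_1F_1(\lambda/d + n;\, (\lambda+\gamma)/d + n;\, -\rho/d),}
#' evaluated in a cancellation-free form (Kummer transformation, all series
#' terms non-negative). Falls back to the generator null-space solve if the
#' evaluation ever loses validity.
#'
#' @param params a \code{telegraph_params} object
#' @param n_max largest copy number evaluated
#' @return numeric pmf over 0..n_max (not renormalized; the infinite-support
#'   pmf is exact, so the truncated sum is <= 1)
#' @export
telegraph_pmf_analytic <- function(params, n_max) {
  stopifnot(inherits(params, "telegraph_params"))
  p <- cpp_telegraph_pmf(params$lam_bar, params$gam_bar, params$rho_bar,
                         params$d, as.integer(n_max))
  s <- sum(p)
  if (all(is.finite(p)) && all(p >= 0) && s <= 1 + 1e-8) return(p)
  joint <- steady_state_pmf(params, tol = 1e-12,
                            n_max = as.integer(max(n_max, 10)))
  marginal_pmf(joint)[seq_len(n_max + 1)]
}

#' Conditional distributions given the gene state
#'
#' Pools all inactive gene states into i = 0 and returns the conditionals
#' \code{P_{n|0}}, \code{P_{n|1}} together with \code{P_off}; the mixture
#' identity \code{P_n = (1 - P_off) P_{n|1} + P_off P_{n|0}} holds exactly.
#'
#' @param joint a \code{joint_pmf}
#' @return list with \code{pn_off}, \code{pn_on}, \code{p_off},
#'   \code{marginal}
#' @export
conditional_pmfs <- function(joint) {
  P <- joint$P
  S <- nrow(P)
  p_on_vec <- P[S, ]
  p_off_vec <- if (S == 2L) P[1, ] else colSums(P[-S, , drop = FALSE])
  p_off <- sum(p_off_vec)
  if (p_off <= 0) stop("P_off = 0: conditional on the inactive state undefined")
  if (p_off >= 1) stop("P_on = 0: conditional on the active state undefined")
  list(pn_off = p_off_vec / p_off, pn_on = p_on_vec / (1 - p_off),
       p_off = p_off, marginal = p_off_vec + p_on_vec)
}

# initial distribution over gene states for "silenced" start (no product,
# gene inactive). TSM defaults to the state entered from the active state
# (earliest in the activation sequence); CPM to the (q1, q2) pathway mixture.
initial_state_probs <- function(params, tsm_init = c("off1", "off2")) {
  tsm_init <- match.arg(tsm_init)
  switch(params$model,
    TM = c(1, 0),
    TSM = if (tsm_init == "off1") c(1, 0, 0) else c(0, 1, 0),
    CPM = c(params$q1, params$q2, 0),
    PFM = c(1, 0),
    NFM = c(1, 0))
}

# pick a transient truncation from the steady-state support
transient_n_max <- function(params, tol) {
  joint <- steady_state_pmf(params, tol = min(tol, 1e-8) * 1e-2)
  m <- marginal_pmf(joint)
  n_hi <- max(which(cumsum(m) < 1 - 1e-12), 1L)
  list(n_max = as.integer(ceiling(1.4 * n_hi + 15)), joint = joint)
}

#' Transient CME solution by finite-state projection
#'
#' Propagates the truncated CME forward in time by uniformization
#' (Poisson-weighted powers of the uniformized jump matrix), which is
#' unconditionally stable for stiff generators and has a directly
#' controllable truncation error. Probability lost through the projection
#' boundary is monitored; the truncation is regrown until the loss over the
#' whole horizon stays below \code{tol}.
#'
#' @param params a model parameter object
#' @param t_grid increasing vector of output times (may start at 0)
#' @param initial "silenced" (no gene product, gene inactive) or a numeric
#'   probability vector over gene states for the count-0 column
#' @param n_max optional truncation (chosen from the steady-state support if
#'   omitted)
#' @param tol bound on probability loss over the horizon (default 1e-8)
#' @param tsm_init which TSM inactive state is "the" silenced state
#' @param keep_joint also return the per-time joint tables
#' @return object of class \code{fsp_result}: list with \code{times},
#'   \code{mean}, \code{var}, \code{m2}, \code{marginal} (times x counts
#'   matrix), \code{loss} (per-time probability deficit), \code{n_max}, and
#'   optionally \code{joint}
#' @export
fsp_transient <- function(params, t_grid, initial = "silenced", n_max = NULL,
                          tol = 1e-8, tsm_init = "off1", keep_joint = FALSE) {
  stopifnot(all(diff(t_grid) > 0) || length(t_grid) == 1, all(t_grid >= 0))
  S <- n_gene_states(params)
  if (is.null(n_max)) n_max <- transient_n_max(params, tol)$n_max
  repeat {
    res <- fsp_run(params, t_grid, initial, n_max, tol, tsm_init, keep_joint, S)
    if (max(res$loss) < tol || n_max > 16384L) break
    n_max <- n_max * 2L
  }
  if (max(res$loss) >= tol) stop("FSP truncation cap exceeded")
  res
}

fsp_run <- function(params, t_grid, initial, n_max, tol, tsm_init,
                    keep_joint, S) {
  A <- generator_matrix(params, n_max)
  dim <- S * (n_max + 1L)
  if (is.character(initial)) {
    stopifnot(identical(initial, "silenced"))
    gs <- initial_state_probs(params, tsm_init)
  } else {
    stopifnot(length(initial) == S, all(initial >= 0))
    gs <- initial / sum(initial)
  }
  p <- numeric(dim); p[seq_len(S)] <- gs # count 0 column
  Lam <- max(-Matrix::diag(A)) + 1e-12
  B <- A / Lam + Diagonal(dim)
  nt <- length(t_grid)
  step_tol <- tol / max(1, ceiling(Lam * max(t_grid) / 40) + nt)
  uni_step <- function(p, dt) {
    m <- Lam * dt
    if (m == 0) return(p)
    ns <- ceiling(m / 40)
    dm <- m / ns
    for (s in seq_len(ns)) {
      w <- exp(-dm); acc <- w * p; q <- p; wsum <- w
      k <- 0
      kmax <- ceiling(dm + 12 * sqrt(dm) + 30)
      while (k < kmax && (1 - wsum) > step_tol) {
        k <- k + 1
        q <- as.numeric(B %*% q)
        w <- w * dm / k
        acc <- acc + w * q
        wsum <- wsum + w
      }
      p <- acc
    }
    p
  }
  n <- 0:n_max
  means <- vars <- m2s <- loss <- numeric(nt)
  marg <- matrix(0, nt, n_max + 1L)
  joint <- if (keep_joint) vector("list", nt) else NULL
  t_prev <- 0
  for (l in seq_len(nt)) {
    p <- uni_step(p, t_grid[l] - t_prev)
    t_prev <- t_grid[l]
    P <- matrix(p, nrow = S)
    m <- colSums(P)
    tot <- sum(m)
    loss[l] <- 1 - tot
    mn <- m / tot
    means[l] <- sum(n * mn)
    m2s[l] <- sum(n^2 * mn)
    vars[l] <- m2s[l] - means[l]^2
    marg[l, ] <- mn
    if (keep_joint) joint[[l]] <- P / tot
  }
  structure(list(times = t_grid, mean = means, var = vars, m2 = m2s,
                 marginal = marg, loss = loss, n_max = n_max, joint = joint,
                 params = params),
            class = "fsp_result")
}

#' Time-dependent mean curve
#'
#' Convenience wrapper around \code{\link{fsp_transient}} returning the mean
#' expression curve from the silenced initial condition, with the
#' steady-state mean attached.
#'
#' @param params a model parameter object
#' @param t_end horizon (non-dimensional time)
#' @param n_points grid resolution
#' @param ... passed to \code{\link{fsp_transient}}
#' @return object of class \code{mean_curve}: data.frame \code{(t, M, var)}
#'   with attribute \code{m_inf}
#' @export
mean_curve <- function(params, t_end, n_points = 200, ...) {
  tg <- seq(t_end / n_points, t_end, length.out = n_points)
  fs <- fsp_transient(params, tg, ...)
  m <- marginal_pmf(steady_state_pmf(params))
  m_inf <- sum((seq_along(m) - 1) * m)
  out <- data.frame(t = c(0, fs$times), M = c(0, fs$mean), var = c(0, fs$var))
  structure(out, m_inf = m_inf, class = c("mean_curve", "data.frame"))
}

#' Response time of a mean curve
#'
#' First time at which the mean curve reaches half of its steady-state
#' value, linearly interpolated between grid points. For non-monotonic
#' (overshooting) curves the first crossing is returned.
#'
#' @param curve a \code{mean_curve}, or any data.frame with columns
#'   \code{t} and \code{M}
#' @param m_inf steady-state mean (taken from the curve attribute if absent)
#' @return the crossing time
#' @export
response_time <- function(curve, m_inf = NULL) {
  if (is.null(m_inf)) m_inf <- attr(curve, "m_inf")
  if (is.null(m_inf) || m_inf <= 0) stop("positive steady-state mean required")
  half <- m_inf / 2
  above <- which(curve$M >= half)
  if (!length(above)) stop("mean curve does not reach half of steady state within the horizon")
  i <- above[1]
  if (i == 1) return(curve$t[1])
  t0 <- curve$t[i - 1]; t1 <- curve$t[i]
  m0 <- curve$M[i - 1]; m1 <- curve$M[i]
  t0 + (half - m0) / (m1 - m0) * (t1 - t0)
}

#' Response-time gap between a complex model and its effective telegraph fit
#'
#' \code{G = d (tau_e - tau_c)}: positive when the effective telegraph model
#' responds more slowly than the complex model.
#'
#' @param complex_curve mean curve of the complex model
#' @param effective_curve mean curve of the effective telegraph model
#' @param d decay rate used for non-dimensionalization
#' @return list with \code{tau_c}, \code{tau_e} and \code{G}
#' @export
response_time_gap <- function(complex_curve, effective_curve, d = 1) {
  tau_c <- response_time(complex_curve)
  tau_e <- response_time(effective_curve)
  list(tau_c = tau_c, tau_e = tau_e, G = d * (tau_e - tau_c))
}

# mean curve with automatic horizon extension until the half-rise crossing
mean_curve_auto <- function(params, t0 = NULL, ...) {
  d <- pars_vector(params)[["d"]]
  t_end <- if (is.null(t0)) 8 / d else t0
  repeat {
    cv <- mean_curve(params, t_end, ...)
    m_inf <- attr(cv, "m_inf")
    if (any(cv$M >= m_inf / 2) || t_end > 600 / d) return(cv)
    t_end <- t_end * 2
  }
}
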