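#' @useDynLib telegraphfit, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats optim rlnorm runif rnorm median var sd quantile setNames
#' @importFrom utils read.csv write.csv head
NULL

.MODEL_CODES <- c(TM = 0L, TSM = 1L, CPM = 2L, PFM = 3L, NFM = 4L)

#' Telegraph model parameters
#'
#' The two-state telegraph model: the gene switches on with rate
#' \code{lam_bar} and off with rate \code{gam_bar}; the gene product is
#' synthesized with rate \code{rho_bar} while the gene is on and decays with
#' rate \code{d}. All rates are per unit time; \code{d} is the
#' non-dimensionalizing scale and defaults to 1.
#'
#' @param lam_bar gene activation rate (>= 0)
#' @param gam_bar gene inactivation rate (>= 0)
#' @param rho_bar synthesis rate (>= 0)
#' @param d decay rate (> 0)
#' @return an object of class \code{telegraph_params}
#' @export
telegraph_params <- function(lam_bar, gam_bar, rho_bar, d = 1) {
  stopifnot(lam_bar >= 0, gam_bar >= 0, rho_bar >= 0, d > 0)
  structure(list(model = "TM", lam_bar = lam_bar, gam_bar = gam_bar,
                 rho_bar = rho_bar, d = d),
            class = c("telegraph_params", "gene_model"))
}

#' Complex gene-expression model parameters
#'
#' Four extensions of the telegraph model:
#' \describe{
#'   \item{TSM}{three-state (refractory) model: after inactivation (rate
#'     \code{gam}) the gene passes through two sequential off states with
#'     rates \code{lam1} then \code{lam2} before becoming active again.}
#'   \item{CPM}{cross-talk pathway model: on inactivation the gene enters a
#'     weak pathway (reactivation rate \code{lam1}) with probability
#'     \code{q1} or a strong pathway (rate \code{lam2 > lam1}) with
#'     probability \code{1 - q1}; off times are hyperexponential.}
#'   \item{PFM}{positive autoregulation: protein increases its own
#'     activation propensity to \code{lam + mu * f(n)}.}
#'   \item{NFM}{negative autoregulation: protein increases the inactivation
#'     propensity to \code{gam + nu * f(n)}.}
#' }
#' For the feedback models \code{f(n) = n} when \code{cooperativity = 1}.
#' With \code{cooperativity = 2} the default is mass-action binding of two
#' protein copies, \code{f(n) = n (n - 1)} (\code{feedback_form =
#' "factorial"}), whose fast-switching mean-field limit gives the rate
#' equation with a \code{mu x^2} regulation term; \code{feedback_form =
#' "square"} uses \code{f(n) = n^2} instead.
#'
#' Copy number is not changed by gene (in)activation events: binding and
#' unbinding only modulate the switching propensities.
#'
#' @param model one of "TSM", "CPM", "PFM", "NFM"
#' @param rho synthesis rate
#' @param d decay rate (default 1, the non-dimensionalizing scale)
#' @param lam1,lam2 activation rates (TSM: sequential steps; CPM: weak and
#'   strong pathway, requires \code{lam2 > lam1})
#' @param q1 CPM weak-pathway selection probability, in (0, 1)
#' @param lam activation rate (PFM, NFM)
#' @param gam inactivation rate
#' @param mu positive feedback strength (PFM)
#' @param nu negative feedback strength (NFM)
#' @param cooperativity 1 or 2 protein copies mediating feedback
#' @param feedback_form "factorial" for f(n) = n(n-1) or "square" for n^2
#'   (cooperativity 2 only)
#' @return an object of class \code{complex_params}
#' @export
complex_model_params <- function(model = c("TSM", "CPM", "PFM", "NFM"),
                                 rho, d = 1,
                                 lam1 = NULL, lam2 = NULL, q1 = NULL,
                                 lam = NULL, gam = NULL, mu = NULL, nu = NULL,
                                 cooperativity = 1L,
                                 feedback_form = c("factorial", "square")) {
  model <- match.arg(model)
  feedback_form <- match.arg(feedback_form)
  stopifnot(rho >= 0, d > 0, cooperativity %in% c(1L, 2L))
  p <- list(model = model, rho = rho, d = d,
            cooperativity = as.integer(cooperativity),
            feedback_form = feedback_form)
  if (model == "TSM") {
    stopifnot(lam1 >= 0, lam2 >= 0, gam >= 0)
    p$lam1 <- lam1; p$lam2 <- lam2; p$gam <- gam
  } else if (model == "CPM") {
    stopifnot(lam1 >= 0, lam2 >= 0, gam >= 0, q1 > 0, q1 < 1)
    if (lam2 <= lam1)
      stop("CPM requires a strong pathway with lam2 > lam1")
    p$lam1 <- lam1; p$lam2 <- lam2; p$q1 <- q1; p$q2 <- 1 - q1; p$gam <- gam
  } else if (model == "PFM") {
    stopifnot(lam >= 0, gam >= 0, mu >= 0)
    p$lam <- lam; p$gam <- gam; p$mu <- mu
  } else {
    stopifnot(lam >= 0, gam >= 0, nu >= 0)
    p$lam <- lam; p$gam <- gam; p$nu <- nu
  }
  structure(p, class = c("complex_params", "gene_model"))
}

#' @export
print.gene_model <- function(x, ...) {
  flds <- setdiff(names(x), c("model", "cooperativity", "feedback_form"))
  vals <- vapply(flds, function(f) format(x[[f]], digits = 4), "")
  cat("<", x$model, " model> ", paste(flds, vals, sep = "=", collapse = ", "),
      sep = "")
  if (!is.null(x$cooperativity) && x$cooperativity > 1L)
    cat(", cooperativity=", x$cooperativity, " (", x$feedback_form, ")",
        sep = "")
  cat("\n")
  invisible(x)
}

# number of gene states and the index (0-based) of the active state
n_gene_states <- function(params) {
  if (params$model %in% c("TSM", "CPM")) 3L else 2L
}
on_state <- function(params) n_gene_states(params) - 1L

gene_state_labels <- function(params) {
  switch(params$model,
         TM  = c("off", "on"),
         TSM = c("off1", "off2", "on"),
         CPM = c("off_weak", "off_strong", "on"),
         PFM = c("off", "on"),
         NFM = c("off", "on"))
}

# feedback modulation f(n)
fcoop <- function(n, cooperativity, feedback_form = "factorial") {
  if (cooperativity == 1L) return(n)
  if (feedback_form == "factorial") n * pmax(n - 1, 0) else n^2
}

# flattened 8-slot parameter vector shared with the C++ backend:
# [lam1, lam2, q1, gam, rho, mu, nu, d]
pars_vector <- function(params) {
  m <- params$model
  c(lam1 = switch(m, TM = params$lam_bar, TSM = params$lam1,
                  CPM = params$lam1, params$lam),
    lam2 = switch(m, TSM = params$lam2, CPM = params$lam2, 0),
    q1   = if (m == "CPM") params$q1 else 0,
    gam  = switch(m, TM = params$gam_bar, params$gam),
    rho  = switch(m, TM = params$rho_bar, params$rho),
    mu   = if (m == "PFM") params$mu else 0,
    nu   = if (m == "NFM") params$nu else 0,
    d    = params$d)
}

model_code <- function(params) .MODEL_CODES[[params$model]]
coop_of <- function(params) {
  if (is.null(params$cooperativity)) 1L else params$cooperativity
}
form_code <- function(params) {
  if (identical(params$feedback_form, "square")) 1L else 0L
}

#' Reaction propensities at a given state
#'
#' Enumerates the reactions enabled at \code{state = c(gene_state, count)}
#' (gene state 0-based, active state highest) with their propensities and
#' state changes. Synthesis fires only in the active state; decay has
#' propensity \code{d * n}; feedback enters additively in the switching
#' propensities, so \code{mu = 0} / \code{nu = 0} reduce exactly to the
#' telegraph model.
#'
#' @param params a \code{telegraph_params} or \code{complex_params} object
#' @param state integer vector \code{c(gene_state, count)}
#' @return data.frame with columns \code{reaction}, \code{gene_to} (new gene
#'   state), \code{dcount} (+1/-1/0) and \code{rate}
#' @export
propensities <- function(params, state) {
  g <- as.integer(state[[1]]); n <- as.integer(state[[2]])
  if (n < 0) stop("negative copy number")
  S <- n_gene_states(params)
  if (g < 0 || g >= S) stop("invalid gene state for model ", params$model)
  on <- on_state(params)
  pv <- pars_vector(params)
  rows <- list()
  if (g == on)
    rows$synthesis <- c(gene_to = g, dcount = 1, rate = pv[["rho"]])
  rows$decay <- c(gene_to = g, dcount = -1, rate = pv[["d"]] * n)
  cp <- coop_of(params); ff <- params$feedback_form %||% "factorial"
  sw <- switch(params$model,
    TM  = if (g == 0) list(activate = c(1, 0, pv[["lam1"]]))
          else list(deactivate = c(0, 0, pv[["gam"]])),
    TSM = if (g == 0) list(step1 = c(1, 0, pv[["lam1"]]))
          else if (g == 1) list(step2 = c(2, 0, pv[["lam2"]]))
          else list(deactivate = c(0, 0, pv[["gam"]])),
    CPM = if (g == 0) list(activate_weak = c(2, 0, pv[["lam1"]]))
          else if (g == 1) list(activate_strong = c(2, 0, pv[["lam2"]]))
          else list(deactivate_weak = c(0, 0, pv[["gam"]] * pv[["q1"]]),
                    deactivate_strong = c(1, 0, pv[["gam"]] * (1 - pv[["q1"]]))),
    PFM = if (g == 0)
            list(activate = c(1, 0, pv[["lam1"]] + pv[["mu"]] * fcoop(n, cp, ff)))
          else list(deactivate = c(0, 0, pv[["gam"]])),
    NFM = if (g == 0) list(activate = c(1, 0, pv[["lam1"]]))
          else list(deactivate = c(0, 0, pv[["gam"]] + pv[["nu"]] * fcoop(n, cp, ff))))
  rows <- c(rows, sw)
  out <- data.frame(reaction = names(rows),
                    gene_to = vapply(rows, `[`, 0, 1),
                    dcount = as.integer(vapply(rows, `[`, 0, 2)),
                    rate = vapply(rows, `[`, 0, 3),
                    row.names = NULL)
  out[out$rate >= 0, , drop = FALSE]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Mean active and inactive gene durations
#'
#' Mean holding times of the active state (\code{T_on}) and of the pooled
#' inactive states (\code{T_off}). Closed forms: telegraph
#' \code{(1/gam, 1/lam)}; TSM \code{(1/gam, 1/lam1 + 1/lam2)}; CPM
#' \code{(1/gam, q1/lam1 + q2/lam2)}. For the feedback models the off (PFM)
#' or on (NFM) exit rate is copy-number dependent and the holding times are
#' computed from stationary flux balance on the exact steady-state CME
#' solution: \code{T_on = P_on / J} and \code{T_off = P_off / J} where
#' \code{J} is the stationary switching flux (see
#' \code{\link{holding_times_flux}}).
#'
#' @param params a model parameter object
#' @return list with \code{T_on} and \code{T_off}
#' @export
mean_holding_times <- function(params) {
  m <- params$model
  if (m == "TM") {
    if (params$gam_bar <= 0 || params$lam_bar <= 0)
      stop("holding times undefined at zero switching rate")
    return(list(T_on = 1 / params$gam_bar, T_off = 1 / params$lam_bar))
  }
  if (m == "TSM") {
    if (params$gam <= 0 || params$lam1 <= 0 || params$lam2 <= 0)
      stop("holding times undefined at zero switching rate")
    return(list(T_on = 1 / params$gam,
                T_off = 1 / params$lam1 + 1 / params$lam2))
  }
  if (m == "CPM") {
    if (params$gam <= 0 || params$lam1 <= 0 || params$lam2 <= 0)
      stop("holding times undefined at zero switching rate")
    return(list(T_on = 1 / params$gam,
                T_off = params$q1 / params$lam1 + params$q2 / params$lam2))
  }
  holding_times_flux(params)
}

#' Holding times from stationary flux balance
#'
#' Generic route valid for every model: solve the steady-state CME for the
#' joint distribution \code{P_{i,n}}, compute the stationary off-to-on
#' switching flux \code{J = sum_n P_{off,n} * (activation propensity at n)},
#' and use the renewal identities \code{T_on = P_on / J},
#' \code{T_off = P_off / J}. For TSM/CPM this reproduces the closed forms
#' and serves as their cross-check.
#'
#' @param params a model parameter object
#' @param tol steady-state tail tolerance
#' @return list with \code{T_on} and \code{T_off}
#' @export
holding_times_flux <- function(params, tol = 1e-10) {
  joint <- steady_state_pmf(params, tol = tol)
  P <- joint$P
  S <- nrow(P); on <- S # 1-based row of the active state
  n <- 0:(ncol(P) - 1)
  p_on <- sum(P[on, ])
  p_off <- 1 - p_on
  # flux out of the on state = flux into it, at stationarity
  pv <- pars_vector(params)
  exit_on <- switch(params$model,
    TM = pv[["gam"]] + 0 * n, TSM = pv[["gam"]] + 0 * n,
    CPM = pv[["gam"]] + 0 * n,
    PFM = pv[["gam"]] + 0 * n,
    NFM = pv[["gam"]] + pv[["nu"]] * fcoop(n, coop_of(params), params$feedback_form %||% "factorial"))
  J <- sum(P[on, ] * exit_on)
  if (J <= 0) stop("zero stationary switching flux")
  list(T_on = p_on / J, T_off = p_off / J)
}

#' Deterministic fixed points of the cooperative positive feedback model
#'
#' Under cooperative regulation (two protein copies) and fast gene
#' switching, the deterministic rate equation for the PFM protein density is
#' \deqn{dx/dt = \rho (\lambda + \mu x^2) / (\lambda + \gamma + \mu x^2) - d x.}
#' Its equilibria are the non-negative real roots of the cubic
#' \eqn{d \mu x^3 - \rho \mu x^2 + d(\lambda + \gamma) x - \rho \lambda = 0};
#' with positive parameters there are one or three (two stable flanking one
#' unstable, i.e. deterministic bistability).
#'
#' @param params a PFM \code{complex_params} object with
#'   \code{cooperativity = 2}
#' @return list with \code{roots} (ascending) and logical \code{stable}
#' @export
deterministic_fixed_points <- function(params) {
  stopifnot(params$model == "PFM")
  if (coop_of(params) != 2L)
    stop("fixed-point analysis applies to the cooperative (2-copy) PFM")
  lam <- params$lam; gam <- params$gam; rho <- params$rho
  mu <- params$mu; d <- params$d
  if (mu <= 0) stop("mu must be positive")
  # d*mu x^3 - rho*mu x^2 + d(lam+gam) x - rho*lam = 0
  rt <- polyroot(c(-rho * lam, d * (lam + gam), -rho * mu, d * mu))
  x <- Re(rt[abs(Im(rt)) < 1e-8 * (1 + Mod(rt))])
  x <- sort(unique(round(x[x >= -1e-12], 10)))
  x[x < 0] <- 0
  g <- function(z) rho * (lam + mu * z^2) / (lam + gam + mu * z^2) - d * z
  eps <- 1e-6 * max(1, rho / d)
  stable <- vapply(x, function(z) g(z + eps) - g(max(z - eps, 0)) < 0, TRUE)
  list(roots = x, stable = stable)
}
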