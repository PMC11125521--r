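# Parameter-grid constructions for the grid experiments.

#' The 625-set Cartesian parameter grid
#'
#' Five values per free parameter (d = 1 throughout): TSM
#' \code{rho in {10,15,20,25,30}} x \code{lam1, lam2, gam in
#' {0.3,0.7,1,2,4}}; CPM \code{lam1 = 0.2} fixed, \code{lam2, gam in
#' {0.5,1,2,4,8}}, \code{q1 in {0.1,0.3,0.5,0.7,0.9}}; PFM/NFM \code{lam,
#' gam in {0.3,0.7,1,2,4}} and feedback strength \code{mu or nu in
#' {0.05,0.1,0.5,1,1.5}}.
#'
#' @param model one of "TSM", "CPM", "PFM", "NFM"
#' @param cooperativity 1 or 2 (feedback models)
#' @return list of \code{complex_params} (length 625) with attributes
#'   \code{model} and \code{label}
#' @export
grid_625 <- function(model = c("TSM", "CPM", "PFM", "NFM"),
                     cooperativity = 1L) {
  model <- match.arg(model)
  rho <- c(10, 15, 20, 25, 30)
  g <- switch(model,
    TSM = expand.grid(rho = rho, lam1 = c(0.3, 0.7, 1, 2, 4),
                      lam2 = c(0.3, 0.7, 1, 2, 4), gam = c(0.3, 0.7, 1, 2, 4)),
    CPM = expand.grid(rho = rho, lam2 = c(0.5, 1, 2, 4, 8),
                      gam = c(0.5, 1, 2, 4, 8), q1 = c(0.1, 0.3, 0.5, 0.7, 0.9)),
    PFM = expand.grid(rho = rho, lam = c(0.3, 0.7, 1, 2, 4),
                      gam = c(0.3, 0.7, 1, 2, 4), mu = c(0.05, 0.1, 0.5, 1, 1.5)),
    NFM = expand.grid(rho = rho, lam = c(0.3, 0.7, 1, 2, 4),
                      gam = c(0.3, 0.7, 1, 2, 4), nu = c(0.05, 0.1, 0.5, 1, 1.5)))
  sets <- lapply(seq_len(nrow(g)), function(i) {
    r <- as.list(g[i, ])
    switch(model,
      TSM = complex_model_params("TSM", rho = r$rho, lam1 = r$lam1,
                                 lam2 = r$lam2, gam = r$gam),
      CPM = complex_model_params("CPM", rho = r$rho, lam1 = 0.2,
                                 lam2 = r$lam2, gam = r$gam, q1 = r$q1),
      PFM = complex_model_params("PFM", rho = r$rho, lam = r$lam, gam = r$gam,
                                 mu = r$mu, cooperativity = cooperativity),
      NFM = complex_model_params("NFM", rho = r$rho, lam = r$lam, gam = r$gam,
                                 nu = r$nu, cooperativity = cooperativity))
  })
  structure(sets, model = model, label = "grid625")
}

#' Random parameter sets with bounded switching frequencies
#'
#' Draws parameter sets uniformly within per-model boxes and keeps those
#' whose true switching frequencies satisfy \code{1/T_off} and
#' \code{1/T_on} in (0, 2.5 d]: \code{rho in [10, 30]} for all models; TSM
#' \code{gam in [0.1, 2.5]}, \code{lam1, lam2 in [0.1, 5]}; CPM \code{gam in
#' [0.1, 2.5]}, \code{q1 in [0.1, 0.9]}, \code{lam1 in [0.05, 0.5]},
#' \code{lam2 in [1, 8]} with \code{1/T_off <= 2.5} enforced by rejection;
#' PFM \code{gam in [0.1, 2.5]}, \code{lam in [0.1, 1.5]}, \code{mu in
#' [0.01, 0.15]} with the flux-balance \code{1/T_off <= 2.5}; NFM
#' \code{lam in [0.1, 2.5]}, \code{gam in [0.1, 1.5]}, \code{nu in
#' [0.01, 0.15]} with \code{1/T_on <= 2.5}.
#'
#' @param model one of "TSM", "CPM", "PFM", "NFM"
#' @param seed RNG seed (mandatory: the grid is part of the experiment design)
#' @param n number of accepted sets (default 150)
#' @return list of \code{complex_params} with attributes \code{model},
#'   \code{label}
#' @export
grid_random150 <- function(model = c("TSM", "CPM", "PFM", "NFM"), seed,
                           n = 150) {
  model <- match.arg(model)
  set.seed(seed)
  sets <- vector("list", n)
  k <- 0
  while (k < n) {
    cand <- switch(model,
      TSM = complex_model_params("TSM", rho = runif(1, 10, 30),
                                 lam1 = runif(1, 0.1, 5),
                                 lam2 = runif(1, 0.1, 5),
                                 gam = runif(1, 0.1, 2.5)),
      CPM = {
        l1 <- runif(1, 0.05, 0.5)
        complex_model_params("CPM", rho = runif(1, 10, 30), lam1 = l1,
                             lam2 = runif(1, 1, 8), gam = runif(1, 0.1, 2.5),
                             q1 = runif(1, 0.1, 0.9))
      },
      PFM = complex_model_params("PFM", rho = runif(1, 10, 30),
                                 lam = runif(1, 0.1, 1.5),
                                 gam = runif(1, 0.1, 2.5),
                                 mu = runif(1, 0.01, 0.15)),
      NFM = complex_model_params("NFM", rho = runif(1, 10, 30),
                                 lam = runif(1, 0.1, 2.5),
                                 gam = runif(1, 0.1, 1.5),
                                 nu = runif(1, 0.01, 0.15)))
    ht <- mean_holding_times(cand)
    ok <- 1 / ht$T_off <= 2.5 && 1 / ht$T_on <= 2.5
    if (ok) {
      k <- k + 1
      sets[[k]] <- cand
    }
  }
  structure(sets, model = model, label = "random150")
}

#' Seeded subgrid of a parameter grid
#'
#' Deterministic subsample used for desk-scale runs of the grid
#' experiments.
#'
#' @param grid a list of parameter sets (e.g. from \code{\link{grid_625}})
#' @param n subgrid size
#' @param seed RNG seed
#' @return sub-list with the same attributes
#' @export
subgrid <- function(grid, n, seed) {
  stopifnot(n <= length(grid))
  set.seed(seed)
  idx <- sort(sample.int(length(grid), n))
  structure(grid[idx], model = attr(grid, "model"),
            label = paste0(attr(grid, "label"), "_sub", n), idx = idx)
}

#' Relative errors of the effective parameters
#'
#' Signed deviations of the fitted effective telegraph parameters from
#' their ground-truth counterparts in the generating complex model:
#' \code{RE_rho = (rho_bar - rho)/rho}, \code{RE_lam = (lam_bar -
#' 1/T_off)/(1/T_off)}, \code{RE_gam = (gam_bar - 1/T_on)/(1/T_on)}.
#' Positive = over-estimated, negative = under-estimated.
#'
#' @param fit a \code{telegraph_fit} (or its \code{telegraph_params})
#' @param truth the generating \code{complex_params}
#' @param holding optional precomputed \code{mean_holding_times(truth)}
#' @return list with \code{RE_rho}, \code{RE_lam}, \code{RE_gam}
#' @export
relative_errors <- function(fit, truth, holding = NULL) {
  p <- if (inherits(fit, "telegraph_fit")) fit$params else fit
  if (is.null(holding)) holding <- mean_holding_times(truth)
  f_off <- 1 / holding$T_off # true activation frequency
  f_on <- 1 / holding$T_on   # true inactivation frequency
  if (truth$rho <= 0 || f_off <= 0 || f_on <= 0)
    stop("relative errors undefined at zero reference rate")
  list(RE_rho = (p$rho_bar - truth$rho) / truth$rho,
       RE_lam = (p$lam_bar - f_off) / f_off,
       RE_gam = (p$gam_bar - f_on) / f_on)
}

#' Expected over/under-estimation sign pattern
#'
#' Per-model signs of the relative errors of (lam_bar, gam_bar, rho_bar):
#' TSM all over-estimated; CPM and PFM all under-estimated; NFM lam_bar
#' over-estimated, gam_bar and rho_bar under-estimated.
#'
#' @param model model tag
#' @return named numeric vector of +1/-1 over (RE_lam, RE_gam, RE_rho)
#' @export
expected_sign_pattern <- function(model) {
  switch(model,
         TSM = c(RE_lam = 1, RE_gam = 1, RE_rho = 1),
         CPM = c(RE_lam = -1, RE_gam = -1, RE_rho = -1),
         PFM = c(RE_lam = -1, RE_gam = -1, RE_rho = -1),
         NFM = c(RE_lam = 1, RE_gam = -1, RE_rho = -1),
         stop("unknown model tag"))
}
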