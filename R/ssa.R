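# Exact stochastic simulation (Gillespie) of all models. Uses R's RNG
# through the compiled backend, so set.seed()/the seed arguments give
# bit-reproducible samples.

maybe_seed <- function(seed) if (!is.null(seed)) set.seed(seed)

#' Single SSA trajectory
#'
#' Exact jump trajectory of (gene state, copy number) up to \code{t_end}.
#'
#' @param params a model parameter object
#' @param t_end simulation horizon (> 0)
#' @param initial integer \code{c(gene_state, count)} (0-based gene state)
#' @param seed optional RNG seed
#' @param max_events event cap guard
#' @return data.frame with columns \code{time}, \code{gene_state},
#'   \code{count} (piecewise-constant; first row is the initial state)
#' @export
ssa_trajectory <- function(params, t_end, initial = c(0L, 0L), seed = NULL,
                           max_events = 5e6) {
  stopifnot(t_end > 0, initial[2] >= 0,
            initial[1] >= 0, initial[1] < n_gene_states(params))
  maybe_seed(seed)
  tr <- cpp_ssa_trajectory(model_code(params), pars_vector(params),
                           coop_of(params), form_code(params),
                           t_end, as.integer(initial[1]),
                           as.integer(initial[2]), as.integer(max_events))
  data.frame(time = tr$time, gene_state = tr$gene_state, count = tr$count)
}

# CME relaxation time 1/gap from the spectral gap of the truncated
# generator; dominates the burn-in for metastable (bimodal) parameter sets
# where microscopic switching is fast but mode hopping is slow
relaxation_time <- function(params) {
  nm <- transient_n_max(params, 1e-8)$n_max
  A <- as.matrix(generator_matrix(params, min(nm, 400L)))
  ev <- Re(eigen(A, only.values = TRUE)$values)
  gap <- -max(ev[ev < -1e-9])
  if (!is.finite(gap) || gap <= 0) return(0)
  1 / gap
}

# burn-in long enough to forget the initial condition: several decay times,
# several full on/off cycles, and several CME relaxation times
default_burn_in <- function(params) {
  d <- pars_vector(params)[["d"]]
  ht <- tryCatch(mean_holding_times(params), error = function(e) NULL)
  cyc <- if (is.null(ht)) 0 else ht$T_on + ht$T_off
  max(50 / d, 20 * cyc, 7 * relaxation_time(params))
}

#' Steady-state sample of independent cells
#'
#' One sample per cell: each cell starts at (lowest inactive state, 0
#' molecules) and is evolved for \code{burn_in} time units by the exact SSA;
#' the final copy number and gene state are recorded, so conditional
#' distributions given the gene state are estimable.
#'
#' @param params a model parameter object
#' @param n_cells number of cells (>= 1)
#' @param burn_in relaxation time per cell; default
#'   \code{max(50/d, 20 (T_on + T_off))}
#' @param seed optional RNG seed
#' @param noise extrinsic-noise coefficient of variation of the per-cell
#'   synthesis rate (0 = none); see \code{\link{apply_extrinsic_noise}}
#' @return data.frame with columns \code{cell_id}, \code{count},
#'   \code{gene_state}, \code{on} (logical)
#' @export
sample_steady_state <- function(params, n_cells, burn_in = NULL, seed = NULL,
                                noise = 0) {
  stopifnot(n_cells >= 1)
  maybe_seed(seed)
  if (is.null(burn_in)) burn_in <- default_burn_in(params)
  rho_cell <- if (noise > 0)
    apply_extrinsic_noise(pars_vector(params)[["rho"]], noise, n_cells)
  else numeric(0)
  m <- cpp_ssa_steady(model_code(params), pars_vector(params),
                      coop_of(params), form_code(params),
                      as.integer(n_cells), burn_in, rho_cell, integer(0))
  data.frame(cell_id = seq_len(n_cells), count = m[, 1], gene_state = m[, 2],
             on = m[, 2] == on_state(params))
}

#' Snapshot samples at multiple time points
#'
#' Every cell is initialized with no gene product and the gene inactive
#' (TSM: the inactive state entered from the active state by default; CPM:
#' the \code{(q1, q2)} pathway mixture) and observed at each time in
#' \code{t_list}.
#'
#' @param params a model parameter object
#' @param t_list increasing observation times (0 allowed)
#' @param n_cells cells per snapshot
#' @param seed optional RNG seed
#' @param tsm_init "off1" (default) or "off2"
#' @param noise extrinsic-noise CV of the per-cell synthesis rate
#' @param independent if \code{FALSE} (default) the same cells are followed
#'   through time (live-cell imaging protocol); if \code{TRUE} every time
#'   point observes a fresh cohort (destructive measurements such as smFISH
#'   or flow cytometry), which makes the snapshot likelihood's independence
#'   assumption exact
#' @return object of class \code{snapshot_series}: list with \code{times},
#'   \code{counts} (cells x times matrix), \code{states} and \code{n_cells}
#' @export
sample_snapshots <- function(params, t_list, n_cells, seed = NULL,
                             tsm_init = "off1", noise = 0,
                             independent = FALSE) {
  stopifnot(all(diff(t_list) > 0) || length(t_list) == 1, all(t_list >= 0))
  maybe_seed(seed)
  gs <- initial_state_probs(params, tsm_init)
  draw_init <- function() {
    if (params$model == "CPM")
      sample.int(length(gs), n_cells, replace = TRUE, prob = gs) - 1L
    else rep(which(gs > 0)[1] - 1L, n_cells)
  }
  draw_rho <- function() {
    if (noise > 0)
      apply_extrinsic_noise(pars_vector(params)[["rho"]], noise, n_cells)
    else numeric(0)
  }
  run <- function(times) {
    cpp_ssa_snapshots(model_code(params), pars_vector(params),
                      coop_of(params), form_code(params),
                      as.integer(n_cells), as.numeric(times),
                      as.integer(draw_init()), draw_rho())
  }
  if (independent) {
    counts <- states <- matrix(0L, n_cells, length(t_list))
    for (l in seq_along(t_list)) {
      r <- run(t_list[l])
      counts[, l] <- r$counts[, 1]
      states[, l] <- r$states[, 1]
    }
    res <- list(counts = counts, states = states)
  } else {
    res <- run(t_list)
  }
  structure(list(times = as.numeric(t_list), counts = res$counts,
                 states = res$states, n_cells = n_cells,
                 model = params$model),
            class = "snapshot_series")
}

#' @export
print.snapshot_series <- function(x, ...) {
  cat("<snapshot_series> ", x$model, " model, ", x$n_cells, " cells at ",
      length(x$times), " time points\n", sep = "")
  invisible(x)
}

#' Ergodic estimate of the stationary joint distribution
#'
#' Time-averaged occupancy of (gene state, copy number) along one long SSA
#' trajectory after a burn-in. This is the low-noise route to the
#' conditional distributions given the gene state: conditioning a snapshot
#' sample on a rarely occupied gene state leaves few cells, whereas the
#' time average uses every sojourn.
#'
#' @param params a model parameter object
#' @param t_total averaging window after burn-in (default \code{1e5/d})
#' @param burn_in relaxation time discarded (default as in
#'   \code{\link{sample_steady_state}})
#' @param seed optional RNG seed
#' @return a \code{joint_pmf}-like object (occupancy fractions)
#' @export
ssa_occupancy <- function(params, t_total = NULL, burn_in = NULL,
                          seed = NULL) {
  maybe_seed(seed)
  d <- pars_vector(params)[["d"]]
  if (is.null(t_total)) t_total <- 1e5 / d
  if (is.null(burn_in)) burn_in <- default_burn_in(params)
  n_max <- as.integer(ceiling(6 * pars_vector(params)[["rho"]] / d + 60))
  occ <- cpp_ssa_occupancy(model_code(params), pars_vector(params),
                           coop_of(params), form_code(params),
                           burn_in, t_total, n_max)
  P <- occ / sum(occ)
  structure(list(P = P, n_max = n_max, p_off = 1 - sum(P[nrow(P), ]),
                 tail = sum(P[, n_max + 1L]), params = params),
            class = "joint_pmf")
}

#' Per-cell synthesis rates under static extrinsic noise
#'
#' Draws one synthesis rate per cell from a log-normal distribution whose
#' mean equals the nominal rate \code{rho} and whose standard deviation is
#' \code{noise * rho} (moment matching: \code{sdlog^2 = log(1 + noise^2)},
#' \code{meanlog = log(rho) - sdlog^2/2}). The rate is constant within a
#' cell (static extrinsic noise).
#'
#' @param rho nominal synthesis rate
#' @param noise coefficient of variation (>= 0); 0 returns \code{rho}
#'   unchanged
#' @param n_cells number of draws
#' @return numeric vector of per-cell rates
#' @export
apply_extrinsic_noise <- function(rho, noise, n_cells) {
  if (noise < 0) stop("noise level must be non-negative")
  if (noise == 0) return(rep(rho, n_cells))
  s2 <- log(1 + noise^2)
  rlnorm(n_cells, meanlog = log(rho) - s2 / 2, sdlog = sqrt(s2))
}

#' Empirical pmf of a count sample
#' @param counts non-negative integer vector
#' @param n_max support upper end (default max observed)
#' @return numeric pmf over 0..n_max
#' @export
empirical_pmf <- function(counts, n_max = max(counts)) {
  stopifnot(length(counts) > 0, all(counts >= 0))
  tabulate(counts + 1L, nbins = n_max + 1L) / length(counts)
}

# gene off/on dwell times extracted from a trajectory (complete sojourns only)
dwell_times <- function(traj, on_index) {
  on <- traj$gene_state == on_index
  r <- rle(on)
  ends <- cumsum(r$lengths)
  starts <- c(1, head(ends, -1) + 1)
  # sojourn s spans traj$time[starts[s]] .. traj$time[ends[s]+1]
  keep <- ends < nrow(traj) & seq_along(ends) > 1 # drop first and censored last
  data.frame(on = r$values[keep],
             duration = traj$time[ends[keep] + 1] - traj$time[starts[keep]])
}

#' Write / read count tables
#'
#' Plain CSV interchange: counts as \code{cell_id,count,gene_state};
#' snapshots as \code{time,cell_id,count}.
#'
#' @param x data.frame from \code{\link{sample_steady_state}} or a
#'   \code{snapshot_series}
#' @param path file path
#' @return \code{read_counts_csv} returns the counts data.frame;
#'   \code{read_snapshots_csv} a \code{snapshot_series}-like list
#' @export
write_counts_csv <- function(x, path) {
  write.csv(x[, c("cell_id", "count", "gene_state")], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_counts_csv
#' @export
read_counts_csv <- function(path) {
  df <- read.csv(path)
  stopifnot(all(c("cell_id", "count") %in% names(df)))
  df
}

#' @rdname write_counts_csv
#' @export
write_snapshots_csv <- function(x, path) {
  long <- data.frame(time = rep(x$times, each = x$n_cells),
                     cell_id = rep(seq_len(x$n_cells), length(x$times)),
                     count = as.vector(x$counts))
  write.csv(long, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_counts_csv
#' @export
read_snapshots_csv <- function(path) {
  df <- read.csv(path)
  stopifnot(all(c("time", "cell_id", "count") %in% names(df)))
  times <- sort(unique(df$time))
  counts <- vapply(times, function(t) df$count[df$time == t],
                   numeric(sum(df$time == times[1])))
  structure(list(times = times, counts = counts, states = NULL,
                 n_cells = nrow(counts), model = NA_character_),
            class = "snapshot_series")
}
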