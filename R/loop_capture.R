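# Condensin loop-capture interactions: stochastic pairwise bonds between
# binding sites that form on proximity and turn over.

#' Update the condensin bond set
#'
#' One stochastic bond update: (1) every existing bond is released with
#' probability `p_release`; (2) all currently free site pairs closer than
#' `d_cutoff` are collected, the list is shuffled uniformly (so crowded
#' rosettes carry no index-order bias), and each pair whose two sites are
#' still free bonds with probability `p_capture`. No site ever holds more
#' than one bond (a condensin entraps exactly two chromatin segments), so
#' the bond set is always a matching.
#'
#' @param state a [chain_state()].
#' @param sites integer vector of condensin site bead indices (1-based).
#' @param bonds 2-column integer matrix of bonded site pairs, as indices
#'   into `sites` (not bead indices).
#' @param capture a [capture_params()].
#' @param seed integer seed for this update.
#' @return the updated bond matrix (same encoding).
#' @export
update_bonds <- function(state, sites, bonds, capture, seed = NULL) {
  stopifnot(inherits(state, "chain_state"),
            inherits(capture, "capture_params"))
  if (is.null(seed)) seed <- floor(runif(1, 1, 2^31 - 1))
  bonds <- matrix(as.integer(bonds), ncol = 2)
  cpp_update_bonds(state$positions, as.integer(sites), bonds,
                   capture$d_cutoff, capture$p_capture, capture$p_release,
                   capture$min_separation, seed)
}

#' Condensin bond forces
#'
#' Hookean attraction between bonded condensin sites toward the bond rest
#' length; zero on all unbonded beads. Internal forces: the per-chain total
#' is exactly zero.
#'
#' @inheritParams update_bonds
#' @return N x 3 matrix of per-bead forces.
#' @export
condensin_force <- function(state, sites, bonds, capture) {
  stopifnot(inherits(state, "chain_state"),
            inherits(capture, "capture_params"))
  bonds <- matrix(as.integer(bonds), ncol = 2)
  if (nrow(bonds) == 0) {
    return(matrix(0, nrow(state$positions), 3))
  }
  bead_pairs <- cbind(as.integer(sites)[bonds[, 1]],
                      as.integer(sites)[bonds[, 2]])
  cpp_condensin_force(state$positions, bead_pairs, capture$bond_spring,
                      capture$bond_rest_length)
}

#' Run a loop-capture simulation
#'
#' Brownian dynamics with condensin loop capture switched on: dynamics
#' steps alternate with bond updates every `capture$bond_every` steps.
#' Bonds keep forming and breaking at steady state, which is therefore an
#' actively maintained stationary shape rather than a passive equilibrium;
#' the emergent structures are compacted chromatin rosettes whose mean size
#' lies well below the unconstrained equilibrium at equal N.
#'
#' @param params an [engine_params()].
#' @param capture a [capture_params()].
#' @param init starting [chain_state()]; defaults to a pivot-equilibrated
#'   unconstrained conformation (see [init_equilibrated()]).
#' @param n_steps dynamics steps.
#' @param sample_every steps between shape samples.
#' @param seed integer seed.
#' @param ... passed on to [simulate_chain()].
#' @return a `chain_trajectory`; its shape series carries the per-frame
#'   bond count in `n_bonds`.
#' @export
run_loop_capture <- function(params, capture = capture_params(),
                             init = NULL, n_steps, sample_every = 1000L,
                             seed = NULL, ...) {
  stopifnot(inherits(params, "engine_params"),
            inherits(capture, "capture_params"))
  if (is.null(seed)) seed <- floor(runif(1, 1, 2^31 - 1))
  if (is.null(init)) init <- init_equilibrated(params, seed = seed)
  simulate_chain(init, params, n_steps = n_steps,
                 sample_every = sample_every, capture = capture,
                 seed = derive_seed(seed, 4), ...)
}

#' Steady-state summary of a loop-capture trajectory
#'
#' Means over the last `fraction` of the run (by time), with a drift check:
#' the difference between the means of the last two quarters of the
#' steady-state window, in units of the s.e.m. of the window.
#'
#' @param traj a `chain_trajectory`.
#' @param fraction final fraction of the run treated as steady state.
#' @return one-row tibble with `length`, `width`, `depth`, `roundness`,
#'   `n_bonds`, their s.e.m.s, and `drift_z` (length drift z-score).
#' @export
steady_state_summary <- function(traj, fraction = 0.5) {
  sh <- traj$shapes
  t_lo <- max(sh$time) - fraction * (max(sh$time) - min(sh$time))
  ss <- dplyr::filter(sh, .data$time >= t_lo)
  half <- (min(ss$time) + max(ss$time)) / 2
  q3 <- dplyr::filter(ss, .data$time < half)
  q4 <- dplyr::filter(ss, .data$time >= half)
  sem <- function(v) sd(v) / sqrt(length(v))
  tibble(
    n_beads = traj$params$n_beads,
    length = mean(ss$length), width = mean(ss$width),
    depth = mean(ss$depth), roundness = mean(ss$roundness),
    n_bonds = mean(ss$n_bonds),
    sem_length = sem(ss$length), sem_width = sem(ss$width),
    sem_roundness = sem(ss$roundness),
    drift_z = (mean(q4$length) - mean(q3$length)) /
      max(sem(ss$length), .Machine$double.eps)
  )
}
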