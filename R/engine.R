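# Overdamped Brownian dynamics of the self-avoiding bead-spring chain.

#' Chain spring forces
#'
#' Hookean forces along consecutive-bead bonds toward the rest length.
#' Internal: equal and opposite on the two beads of each bond, so the total
#' force over the chain is zero.
#'
#' @param state a [chain_state()].
#' @param params an [engine_params()].
#' @return N x 3 matrix of per-bead forces.
#' @export
spring_force <- function(state, params) {
  stopifnot(inherits(state, "chain_state"), inherits(params, "engine_params"))
  cpp_spring_force(state$positions, params$spring_constant,
                   params$rest_length)
}

#' Soft steric repulsion forces
#'
#' Harmonic-overlap repulsion `|F| = k_rep (2a - d)` for bead pairs closer
#' than one bead diameter, zero beyond; continuous in distance. Exactly
#' coincident beads are pushed apart along the +x axis (deterministic
#' fallback, never NaN). Evaluated with a cell list, near-linear in N.
#'
#' @inheritParams spring_force
#' @return N x 3 matrix of per-bead forces.
#' @export
repulsion_force <- function(state, params) {
  stopifnot(inherits(state, "chain_state"), inherits(params, "engine_params"))
  cpp_repulsion_force(state$positions, params$repulsion_constant,
                      params$bead_radius)
}

#' Advance the chain by overdamped Brownian steps
#'
#' Euler-Maruyama update
#' `x <- x + (dt/gamma) F + sqrt(2 (kT/gamma) dt) xi` with standard normal
#' `xi` per coordinate. `extra_forces` (constant over the call) are added
#' to the spring and repulsion forces, which is how condensin bond forces
#' enter during loop-capture runs.
#'
#' @inheritParams spring_force
#' @param n_steps number of timesteps to take.
#' @param extra_forces optional N x 3 matrix of additional constant forces.
#' @param seed integer seed for the noise stream; a given seed reproduces
#'   the trajectory bit-identically.
#' @return the advanced [chain_state()].
#' @export
step_brownian <- function(state, params, n_steps = 1L, extra_forces = NULL,
                          seed = NULL) {
  stopifnot(inherits(state, "chain_state"), inherits(params, "engine_params"))
  if (is.null(extra_forces)) {
    extra_forces <- matrix(0, 0, 0)
  } else {
    extra_forces <- as.matrix(extra_forces)
    if (!all(is.finite(extra_forces))) {
      bad <- which(!apply(is.finite(extra_forces), 1, all))[1]
      stop("non-finite force input at bead ", bad)
    }
  }
  if (is.null(seed)) seed <- floor(runif(1, 1, 2^31 - 1))
  out <- cpp_step_brownian(state$positions, params$spring_constant,
                           params$rest_length, params$repulsion_constant,
                           params$bead_radius, params$kT, params$friction,
                           params$dt, extra_forces, as.integer(n_steps),
                           seed)
  chain_state(out$positions, state$time + out$time)
}

new_trajectory <- function(shapes, final_state, params, capture, bonds,
                           frames = NULL, seed = NULL) {
  structure(
    list(shapes = shapes, final_state = final_state, params = params,
         capture = capture, bonds = bonds, frames = frames, seed = seed),
    class = "chain_trajectory"
  )
}

#' @export
print.chain_trajectory <- function(x, ...) {
  cat("<chain_trajectory> N =", x$params$n_beads,
      "|", nrow(x$shapes), "samples | t in [",
      signif(min(x$shapes$time), 4), ",", signif(max(x$shapes$time), 4),
      "] |", if (is.null(x$capture)) "no loop capture" else "loop capture",
      "\n")
  invisible(x)
}

#' Tidy a trajectory into its shape time series
#'
#' One row per sampled frame: time, covariance-eigenvalue length, width,
#' depth, roundness (width/length) and active condensin bond count.
#'
#' @param x a `chain_trajectory`.
#' @param ... unused.
#' @return a tibble with columns `time`, `length`, `width`, `depth`,
#'   `roundness`, `n_bonds`.
#' @method tidy chain_trajectory
#' @export
tidy.chain_trajectory <- function(x, ...) x$shapes

#' @method glance chain_trajectory
#' @export
glance.chain_trajectory <- function(x, ...) {
  last_half <- dplyr::filter(x$shapes, .data$time >=
                               (min(.data$time) + max(.data$time)) / 2)
  tibble(
    n_beads = x$params$n_beads,
    n_samples = nrow(x$shapes),
    t_final = max(x$shapes$time),
    mean_length = mean(last_half$length),
    mean_width = mean(last_half$width),
    mean_roundness = mean(last_half$roundness),
    mean_bonds = mean(last_half$n_bonds)
  )
}

#' Simulate the chain
#'
#' Runs the Brownian dynamics engine from `state` for `n_steps` timesteps,
#' sampling the covariance-eigenvalue shape every `sample_every` steps
#' (the initial state is sample zero). With a [capture_params()] object in
#' `capture`, condensin loop-capture bonds between the binding sites (every
#' 10th bead by default, see [condensin_sites()]) are updated every
#' `capture$bond_every` steps and their Hookean forces act on the chain.
#'
#' Aborts with a diagnostic if any chain bond exceeds 10x its rest length
#' (integration instability; reduce `dt`).
#'
#' @param state starting [chain_state()].
#' @param params an [engine_params()].
#' @param n_steps dynamics steps to run.
#' @param sample_every steps between shape samples.
#' @param capture optional [capture_params()]; `NULL` disables loop capture.
#' @param sites integer vector of condensin site bead indices; defaults to
#'   every 10th bead.
#' @param bonds optional 2-column matrix of initially bonded site pairs
#'   (indices into `sites`).
#' @param seed integer seed; same seed and inputs give a bit-identical
#'   trajectory.
#' @param store_frames keep the sampled bead coordinates (N x 3 x frames
#'   array) in the result.
#' @return a `chain_trajectory` with the shape series (see
#'   [tidy.chain_trajectory()]), final state and final bond set.
#' @examples
#' p <- engine_params(50)
#' tr <- simulate_chain(init_random_walk(50, seed = 1), p,
#'                      n_steps = 200, sample_every = 50, seed = 2)
#' tidy(tr)
#' @export
simulate_chain <- function(state, params, n_steps, sample_every = 1000L,
                           capture = NULL, sites = NULL, bonds = NULL,
                           seed = NULL, store_frames = FALSE) {
  stopifnot(inherits(state, "chain_state"), inherits(params, "engine_params"))
  if (nrow(state$positions) != params$n_beads) {
    stop("state has ", nrow(state$positions), " beads but params expect ",
         params$n_beads)
  }
  if (is.null(seed)) seed <- floor(runif(1, 1, 2^31 - 1))
  has_capture <- !is.null(capture)
  if (has_capture) stopifnot(inherits(capture, "capture_params"))
  if (is.null(sites)) sites <- condensin_sites(params$n_beads)
  if (is.null(bonds)) bonds <- matrix(0L, 0, 2)
  cp <- if (has_capture) capture else capture_params()
  out <- cpp_run(state$positions, state$time,
                 params$spring_constant, params$rest_length,
                 params$repulsion_constant, params$bead_radius,
                 params$kT, params$friction, params$dt,
                 has_capture, as.integer(sites),
                 matrix(as.integer(bonds), ncol = 2),
                 cp$d_cutoff, cp$p_capture, cp$p_release,
                 cp$min_separation,
                 cp$bond_spring, cp$bond_rest_length, cp$bond_every,
                 as.integer(n_steps), as.integer(sample_every),
                 seed, store_frames)
  shapes <- tibble(
    time = out$shapes[, 1], length = out$shapes[, 2],
    width = out$shapes[, 3], depth = out$shapes[, 4],
    roundness = out$shapes[, 5], n_bonds = as.integer(out$shapes[, 6])
  )
  new_trajectory(shapes, chain_state(out$positions, out$time), params,
                 capture, out$bonds,
                 frames = if (store_frames) out$frames else NULL,
                 seed = seed)
}

#' Equilibrium run of the unconstrained chain
#'
#' Convenience wrapper: equilibrates the self-avoiding chain (pivot Monte
#' Carlo global equilibration plus Brownian relaxation, see
#' [init_equilibrated()]), then samples a Brownian dynamics run. The
#' pivot-equilibrated start replaces a long dynamical burn-in, whose
#' duration would grow as roughly N^2.2 and dominate any desk-scale run;
#' frames from the returned trajectory are equilibrium samples from step
#' zero.
#'
#' @param params an [engine_params()].
#' @param n_steps dynamics steps to sample over.
#' @param sample_every steps between samples.
#' @param seed integer seed.
#' @param ... passed to [simulate_chain()].
#' @return a `chain_trajectory`.
#' @export
run_equilibrium <- function(params, n_steps, sample_every = 1000L,
                            seed = NULL, ...) {
  if (is.null(seed)) seed <- floor(runif(1, 1, 2^31 - 1))
  st <- init_equilibrated(params, seed = seed)
  simulate_chain(st, params, n_steps = n_steps,
                 sample_every = sample_every,
                 seed = derive_seed(seed, 3), ...)
}

#' Ensemble of independent equilibrium conformations
#'
#' Draws `n_conformations` statistically independent equilibrium
#' conformations of the unconstrained self-avoiding chain (each one a fresh
#' pivot equilibration plus Brownian relaxation) and returns their shape
#' records. Independent draws converge much faster than frames of a single
#' dynamical trajectory, whose global-shape autocorrelation time grows as
#' roughly N^2.2.
#'
#' @param params an [engine_params()].
#' @param n_conformations number of independent draws.
#' @param seed integer seed for the whole ensemble.
#' @param sweeps pivot attempts per draw, as a multiple of N.
#' @param relax_time Brownian relaxation per draw, reduced time units
#'   (bond-length thermalisation needs ~gamma/k_spr = 0.04 time units, so
#'   the default is a comfortable 75x that).
#' @return a tibble with one row per conformation: `conformation`,
#'   `length`, `width`, `depth`, `roundness`.
#' @export
equilibrium_ensemble <- function(params, n_conformations = 30, seed = NULL,
                                 sweeps = 8, relax_time = 3) {
  stopifnot(inherits(params, "engine_params"))
  if (is.null(seed)) seed <- floor(runif(1, 1, 2^31 - 1))
  purrr::map_dfr(seq_len(n_conformations), function(i) {
    st <- init_equilibrated(params, sweeps = sweeps,
                            relax_time = relax_time,
                            seed = derive_seed(seed, i))
    dplyr::mutate(covariance_shape(st$positions), conformation = i,
                  .before = 1)
  })
}
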