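# Initial conformations: random walk, elongated ellipsoid, and
# pivot-equilibrated self-avoiding starts.

# run code under a temporary R RNG seed, restoring the caller's RNG state
with_local_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Random-walk initial conformation
#'
#' Places the chain as a random walk with every bond of exact length
#' `rest_length` and i.i.d. bond directions drawn uniformly on the unit
#' sphere, the standard unconstrained-chain start.
#'
#' @param n_beads chain length N (>= 2).
#' @param rest_length bond length l0.
#' @param seed integer seed; the same seed reproduces the conformation
#'   bit-identically. `NULL` uses the current RNG state.
#' @return a [chain_state()] at time 0.
#' @examples
#' st <- init_random_walk(50, seed = 1)
#' range(sqrt(rowSums(diff(st$positions)^2)))  # all bonds exactly l0
#' @export
init_random_walk <- function(n_beads, rest_length = 2, seed = NULL) {
  n_beads <- as.integer(n_beads)
  stopifnot(n_beads >= 2, rest_length > 0)
  with_local_seed(seed, {
    g <- matrix(rnorm(3 * (n_beads - 1)), ncol = 3)
    steps <- g / sqrt(rowSums(g^2)) * rest_length
    pos <- rbind(c(0, 0, 0), apply(steps, 2, cumsum))
    chain_state(pos)
  })
}

#' Elongated ellipsoidal initial conformation
#'
#' Emulates the elongated prophase-like starting state: bead z coordinates
#' are drawn from a Gaussian of standard deviation `L0/2` and sorted
#' ascending, then each bead receives independent transverse x and y
#' coordinates from a Gaussian of standard deviation `w0/2` (width and
#' depth start out equal because the experimental data cannot distinguish
#' them). Bond lengths are not enforced; the first dynamics steps relax any
#' stretch. A bond longer than `10 * rest_length` is resampled so the
#' engine's instability guard is never tripped at t = 0.
#'
#' @param n_beads chain length N.
#' @param L0 target initial length (covariance-eigenvalue definition);
#'   typically 4x the steady-state length.
#' @param w0 target initial width and depth; typically 1x the steady-state
#'   width.
#' @param rest_length chain bond rest length, used only for the
#'   overstretch resampling rule.
#' @param seed integer seed, `NULL` for current RNG state.
#' @return a [chain_state()] at time 0 with z sorted ascending.
#' @export
init_elongated <- function(n_beads, L0, w0, rest_length = 2, seed = NULL) {
  n_beads <- as.integer(n_beads)
  stopifnot(n_beads >= 2, L0 > 0, w0 >= 0)
  with_local_seed(seed, {
    z <- sort(rnorm(n_beads, sd = L0 / 2))
    x <- rnorm(n_beads, sd = w0 / 2)
    y <- rnorm(n_beads, sd = w0 / 2)
    pos <- cbind(x, y, z, deparse.level = 0)
    # resample transverse coordinates of any bead whose bond exceeds 10 l0;
    # the axial spread dominates bond stretch so this converges quickly
    limit <- 10 * rest_length
    for (pass in 1:100) {
      bl <- sqrt(rowSums((pos[-1, , drop = FALSE] -
                            pos[-n_beads, , drop = FALSE])^2))
      bad <- which(bl > limit)
      if (length(bad) == 0) break
      idx <- unique(pmin(bad + 1L, n_beads))
      pos[idx, 1] <- rnorm(length(idx), sd = w0 / 2)
      pos[idx, 2] <- rnorm(length(idx), sd = w0 / 2)
      # if the axial gap itself exceeds the limit, pull the z's together
      bl <- sqrt(rowSums((pos[-1, , drop = FALSE] -
                            pos[-n_beads, , drop = FALSE])^2))
      bad <- which(bl > limit)
      if (length(bad) > 0) {
        for (b in bad) {
          pos[b + 1L, 3] <- pos[b, 3] +
            sign(pos[b + 1L, 3] - pos[b, 3]) * limit * 0.9
        }
        pos <- pos[order(pos[, 3]), , drop = FALSE]
      }
    }
    chain_state(pos)
  })
}

#' Pivot-equilibrated self-avoiding conformation
#'
#' Draws an equilibrium conformation of the self-avoiding chain by
#' Metropolis pivot Monte Carlo: starting from a random walk, chain arms
#' are repeatedly rotated about random interior beads by uniform random
#' rotations and accepted by the change in soft-overlap energy (the same
#' harmonic-overlap potential the dynamics engine integrates). The pivot
#' move is the standard global-equilibration move for self-avoiding
#' polymers; a short Brownian relaxation (`relax_time` reduced time units)
#' afterwards restores thermal bond-length fluctuations, which the
#' fixed-bond pivot chain lacks.
#'
#' @param params an [engine_params()] object.
#' @param sweeps pivot attempts as a multiple of N (default 10 N attempts).
#' @param relax_time duration of the Brownian relaxation run.
#' @param seed integer seed for the whole draw.
#' @return a [chain_state()] at time 0.
#' @export
init_equilibrated <- function(params, sweeps = 10, relax_time = 5,
                              seed = NULL) {
  stopifnot(inherits(params, "engine_params"))
  if (is.null(seed)) seed <- floor(runif(1, 1, 2^31 - 1))
  st <- init_random_walk(params$n_beads, params$rest_length, seed = seed)
  piv <- cpp_pivot(st$positions, params$repulsion_constant,
                   params$bead_radius, params$kT,
                   as.integer(ceiling(sweeps * params$n_beads)),
                   derive_seed(seed, 1))
  st <- chain_state(piv$positions)
  if (relax_time > 0) {
    n_steps <- as.integer(ceiling(relax_time / params$dt))
    out <- cpp_step_brownian(st$positions, params$spring_constant,
                             params$rest_length, params$repulsion_constant,
                             params$bead_radius, params$kT, params$friction,
                             params$dt, matrix(0, 0, 0), n_steps,
                             derive_seed(seed, 2))
    st <- chain_state(out$positions)
  }
  st
}
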