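#' Engine parameters for the bead-spring chromatin chain
#'
#' Collects the force-field and integrator constants of the overdamped
#' Brownian dynamics engine. Reduced units: `bead_radius` a is the length
#' unit (25 nm of chromatin per bead), `kT` the energy unit and `friction`
#' the friction unit, so the free-bead diffusion constant is `kT/friction`.
#'
#' Consecutive beads are joined by Hookean springs of rest length
#' `rest_length` and stiffness `spring_constant`; any two beads closer than
#' `2 * bead_radius` repel with the soft harmonic-overlap force
#' `k_rep * (2a - d)`, which keeps the chain self-avoiding without hard
#' exclusion. The default spring constant keeps bond-length fluctuations at
#' `sqrt(kT/k_spr) = 0.2 a`, far below chain dimensions, while allowing a
#' stable timestep; the stability guard `dt * spring_constant / friction <
#' 0.1` is enforced here.
#'
#' @param n_beads number of beads N (>= 2).
#' @param bead_radius bead radius a, the reduced length unit.
#' @param spring_constant chain spring stiffness, kT/a^2.
#' @param rest_length spring rest length, defaults to touching beads (2a).
#' @param repulsion_constant soft-overlap repulsion stiffness, kT/a^2.
#' @param kT thermal energy.
#' @param friction bead friction coefficient gamma.
#' @param dt integrator timestep in reduced time; the default keeps the
#'   stability margin `dt * spring_constant / friction` at 0.075.
#' @return an object of class `engine_params` (a named list).
#' @examples
#' p <- engine_params(100)
#' p$dt * p$spring_constant / p$friction  # stability margin, < 0.1
#' @export
engine_params <- function(n_beads,
                          bead_radius = 1,
                          spring_constant = 25,
                          rest_length = 2 * bead_radius,
                          repulsion_constant = 25,
                          kT = 1,
                          friction = 1,
                          dt = 3e-3) {
  n_beads <- as.integer(n_beads)
  stopifnot(n_beads >= 2, bead_radius > 0, spring_constant >= 0,
            rest_length > 0, repulsion_constant >= 0, kT >= 0,
            friction > 0, dt > 0)
  if (dt * spring_constant / friction >= 0.1) {
    stop("unstable timestep: dt * spring_constant / friction must be < 0.1 ",
         "(got ", dt * spring_constant / friction, ")")
  }
  structure(
    list(n_beads = n_beads, bead_radius = bead_radius,
         spring_constant = spring_constant, rest_length = rest_length,
         repulsion_constant = repulsion_constant, kT = kT,
         friction = friction, dt = dt),
    class = "engine_params"
  )
}

#' @export
print.engine_params <- function(x, ...) {
  cat("<engine_params> N =", x$n_beads,
      "| a =", x$bead_radius, "| k_spr =", x$spring_constant,
      "| l0 =", x$rest_length, "| k_rep =", x$repulsion_constant,
      "| kT =", x$kT, "| gamma =", x$friction, "| dt =", x$dt, "\n")
  invisible(x)
}

#' Condensin loop-capture parameters
#'
#' Parameters of the stochastic pairwise condensin bonds layered on the
#' chain: when two free condensin binding sites diffuse within `d_cutoff`
#' of each other, a Hookean bond forms with probability `p_capture` at the
#' next bond update; every existing bond is released with probability
#' `p_release` per update, so the mean bond lifetime is
#' `bond_every / p_release` dynamics steps. Each site holds at most one
#' bond (a condensin entraps exactly two chromatin segments). Bond updates
#' run every `bond_every` dynamics steps.
#'
#' Defaults are calibrated so that a compact steady state emerges and is
#' maintained by ongoing bond turnover, and are robust to halving/doubling
#' `p_capture` (see the methods vignette for the calibration).
#'
#' @param d_cutoff capture radius, reduced length.
#' @param p_capture capture probability per eligible free pair per update.
#' @param p_release release probability per bond per update.
#' @param bond_spring bonded-pair spring stiffness, kT/a^2; softer than
#'   the chain backbone by default, since a condensin bridge is a flexible
#'   protein linkage rather than a chromatin segment.
#' @param bond_rest_length bond rest length, one bead diameter.
#' @param bond_every dynamics steps between bond updates.
#' @param min_separation minimum genomic separation between capturable
#'   sites, in site intervals; 1 (the default) applies no restriction
#'   beyond the spatial cutoff.
#' @return an object of class `capture_params`.
#' @export
capture_params <- function(d_cutoff = 3,
                           p_capture = 0.5,
                           p_release = 0.025,
                           bond_spring = 5,
                           bond_rest_length = 2,
                           bond_every = 10L,
                           min_separation = 1L) {
  stopifnot(d_cutoff > 0,
            p_capture >= 0, p_capture <= 1,
            p_release >= 0, p_release <= 1,
            bond_spring >= 0, bond_rest_length > 0, bond_every >= 1,
            min_separation >= 1)
  structure(
    list(d_cutoff = d_cutoff, p_capture = p_capture, p_release = p_release,
         bond_spring = bond_spring, bond_rest_length = bond_rest_length,
         bond_every = as.integer(bond_every),
         min_separation = as.integer(min_separation)),
    class = "capture_params"
  )
}

#' @export
print.capture_params <- function(x, ...) {
  cat("<capture_params> d_cutoff =", x$d_cutoff,
      "| P =", x$p_capture, "| p_release =", x$p_release,
      "| k_bond =", x$bond_spring, "| rest =", x$bond_rest_length,
      "| update every", x$bond_every, "steps\n")
  invisible(x)
}

#' Condensin binding sites along the chain
#'
#' Every `spacing`-th bead is a condensin binding site (default every 10th,
#' matching the empirical ~23.4 kb / 11.7 bead condensin site spacing in
#' fission yeast at 2 kb per bead).
#'
#' @param n_beads chain length N.
#' @param spacing beads between consecutive sites.
#' @return integer vector of 1-based bead indices, strictly increasing.
#' @export
condensin_sites <- function(n_beads, spacing = 10L) {
  n_beads <- as.integer(n_beads)
  spacing <- as.integer(spacing)
  stopifnot(n_beads >= 2, spacing >= 1)
  seq.int(1L, n_beads, by = spacing)
}

#' Chain state constructor
#'
#' A chain state holds the N x 3 bead positions (reduced length units) and
#' the simulation clock. Validates finiteness and minimal size.
#'
#' @param positions N x 3 numeric matrix of bead coordinates.
#' @param time simulation time in reduced units.
#' @return an object of class `chain_state`.
#' @export
chain_state <- function(positions, time = 0) {
  positions <- as.matrix(positions)
  storage.mode(positions) <- "double"
  if (ncol(positions) != 3L) stop("positions must have 3 columns")
  if (nrow(positions) < 2L) stop("a chain needs at least 2 beads")
  if (!all(is.finite(positions))) stop("non-finite bead coordinates")
  structure(list(positions = positions, time = as.numeric(time)),
            class = "chain_state")
}

#' @export
print.chain_state <- function(x, ...) {
  dims <- covariance_shape(x$positions)
  cat("<chain_state> N =", nrow(x$positions),
      "| t =", signif(x$time, 4),
      "| L =", signif(dims$length, 4),
      "w =", signif(dims$width, 4),
      "d =", signif(dims$depth, 4), "\n")
  invisible(x)
}

#' Convert bead counts to genomic length
#'
#' Each bead coarse-grains about 10 nucleosomes, i.e. 2 kb of DNA, so a
#' chain of N = 4000 beads represents an 8 Mb chromatin fibre.
#'
#' @param n_beads number of beads.
#' @param kb_per_bead kilobases of DNA per bead.
#' @return genomic length in megabases.
#' @examples
#' beads_to_genome_mb(4000)  # 8
#' @export
beads_to_genome_mb <- function(n_beads, kb_per_bead = 2) {
  stopifnot(n_beads >= 1, kb_per_bead > 0)
  n_beads * kb_per_bead / 1000
}
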