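# Independent oracles used across the suite. These deliberately avoid the
# package's computational paths: plain-R brute force, closed forms, and
# quadrature.

# O(N^2) all-pairs soft-overlap repulsion, straight from the force law
brute_repulsion <- function(pos, k_rep, a) {
  n <- nrow(pos)
  f <- matrix(0, n, 3)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      dvec <- pos[i, ] - pos[j, ]
      d <- sqrt(sum(dvec^2))
      if (d < 2 * a && d > 0) {
        fij <- k_rep * (2 * a - d) * dvec / d
        f[i, ] <- f[i, ] + fij
        f[j, ] <- f[j, ] - fij
      }
    }
  }
  f
}

# pairwise Hookean chain springs, direct summation
brute_spring <- function(pos, k, l0) {
  n <- nrow(pos)
  f <- matrix(0, n, 3)
  for (i in seq_len(n - 1)) {
    dvec <- pos[i + 1, ] - pos[i, ]
    d <- sqrt(sum(dvec^2))
    fi <- k * (d - l0) * dvec / d
    f[i, ] <- f[i, ] + fi
    f[i + 1, ] <- f[i + 1, ] - fi
  }
  f
}

# eigenvalues of a symmetric 3x3 matrix by solving the characteristic
# cubic with polyroot(), descending order
char_poly_eigenvalues <- function(m) {
  c2 <- -(m[1, 1] + m[2, 2] + m[3, 3])
  c1 <- m[1, 1] * m[2, 2] + m[1, 1] * m[3, 3] + m[2, 2] * m[3, 3] -
    m[1, 2]^2 - m[1, 3]^2 - m[2, 3]^2
  c0 <- -(m[1, 1] * (m[2, 2] * m[3, 3] - m[2, 3]^2) -
            m[1, 2] * (m[1, 2] * m[3, 3] - m[2, 3] * m[1, 3]) +
            m[1, 3] * (m[1, 2] * m[2, 3] - m[2, 2] * m[1, 3]))
  sort(Re(polyroot(c(c0, c1, c2, 1))), decreasing = TRUE)
}

# mean bond length of two beads joined by one Hookean spring at thermal
# equilibrium, by quadrature of the radial Boltzmann density
# p(x) ~ x^2 exp(-k (x - l0)^2 / (2 kT))
boltzmann_mean_bond <- function(k, l0, kT = 1) {
  dens <- function(x) x^2 * exp(-k * (x - l0)^2 / (2 * kT))
  z <- stats::integrate(dens, 0, l0 + 20 * sqrt(kT / k))$value
  stats::integrate(function(x) x * dens(x), 0,
                   l0 + 20 * sqrt(kT / k))$value / z
}

# R re-implementation of the documented bond-update rule (release, then
# uniformly shuffled greedy capture among eligible free pairs)
oracle_update_bonds <- function(pos, sites, partner, d_cutoff, p_capture,
                                p_release) {
  ns <- length(sites)
  for (s in seq_len(ns)) {
    t <- partner[s]
    if (!is.na(t) && t > s && runif(1) < p_release) {
      partner[c(s, t)] <- NA
    }
  }
  free <- which(is.na(partner))
  elig <- NULL
  if (length(free) >= 2) {
    cmb <- utils::combn(free, 2)
    d <- sqrt(rowSums((pos[sites[cmb[1, ]], , drop = FALSE] -
                         pos[sites[cmb[2, ]], , drop = FALSE])^2))
    elig <- cmb[, d < d_cutoff, drop = FALSE]
  }
  if (!is.null(elig) && ncol(elig) > 0) {
    for (k in sample.int(ncol(elig))) {
      s <- elig[1, k]; t <- elig[2, k]
      if (is.na(partner[s]) && is.na(partner[t]) && runif(1) < p_capture) {
        partner[s] <- t; partner[t] <- s
      }
    }
  }
  partner
}

# small random bead cloud
random_cloud <- function(n, spread = 3, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  matrix(rnorm(3 * n, sd = spread), ncol = 3)
}

expect_matching <- function(bonds, n_sites) {
  if (nrow(bonds) == 0) return(invisible(TRUE))
  idx <- as.vector(bonds)
  expect_true(all(idx >= 1 & idx <= n_sites))
  expect_false(any(duplicated(idx)))
  expect_false(any(bonds[, 1] == bonds[, 2]))
  invisible(TRUE)
}
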