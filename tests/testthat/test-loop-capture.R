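# Condensin loop-capture bonds: formation, release, matching invariant,
# forces.

test_that("zero capture probability only shrinks the bond set", {
  st <- chain_state(random_cloud(40, spread = 1, seed = 60))
  sites <- condensin_sites(40, 10)
  bonds <- rbind(c(1L, 2L), c(3L, 4L))
  cp_keep <- capture_params(p_capture = 0, p_release = 0)
  expect_equal(nrow(update_bonds(st, sites, bonds, cp_keep, seed = 1)), 2)
  cp_drop <- capture_params(p_capture = 0, p_release = 1)
  expect_equal(nrow(update_bonds(st, sites, bonds, cp_drop, seed = 1)), 0)
})

test_that("sites beyond the capture radius never bond", {
  pos <- matrix(0, 20, 3)
  pos[, 1] <- seq(0, 190, by = 10)   # everything far apart
  st <- chain_state(pos)
  sites <- condensin_sites(20, 10)   # beads 1 and 11, distance 100
  cp <- capture_params(d_cutoff = 2.5, p_capture = 1, p_release = 0)
  for (s in 1:20) {
    expect_equal(nrow(update_bonds(st, sites, matrix(0L, 0, 2), cp,
                                   seed = s)), 0)
  }
})

test_that("six mutually close sites form a perfect matching of 3 bonds", {
  set.seed(61)
  pos <- matrix(rnorm(60 * 3, sd = 0.3), ncol = 3)
  st <- chain_state(pos)
  sites <- condensin_sites(60, 10)   # 6 sites, all within any cutoff
  cp <- capture_params(d_cutoff = 10, p_capture = 1, p_release = 0)
  for (s in 1:20) {
    b <- update_bonds(st, sites, matrix(0L, 0, 2), cp, seed = s)
    expect_equal(nrow(b), 3)
    expect_matching(b, 6)
  }
})

test_that("pairing frequencies match the randomized-order matching oracle", {
  # 4 sites in a line with only short pairs eligible decides pairings by
  # shuffle order; compare pair frequencies against the R oracle
  pos <- matrix(0, 40, 3)
  pos[c(1, 11, 21, 31), 1] <- c(0, 1.5, 3.0, 4.5)
  st <- chain_state(pos)
  sites <- condensin_sites(40, 10)
  cp <- capture_params(d_cutoff = 2, p_capture = 1, p_release = 0)
  n_draws <- 600
  freq_cpp <- table(vapply(seq_len(n_draws), function(s) {
    b <- update_bonds(st, sites, matrix(0L, 0, 2), cp, seed = s)
    paste(apply(b, 1, paste, collapse = "-"), collapse = ",")
  }, character(1)))
  set.seed(62)
  freq_oracle <- table(vapply(seq_len(n_draws), function(s) {
    partner <- oracle_update_bonds(pos, sites, rep(NA_integer_, 4), 2, 1, 0)
    b <- cbind(which(!is.na(partner) & partner > seq_along(partner)))
    pairs <- sprintf("%d-%d", b, partner[b])
    paste(sort(pairs), collapse = ",")
  }, character(1)))
  # same support and similar frequencies (binomial fluctuation allowance)
  expect_setequal(names(freq_cpp), names(freq_oracle))
  for (nm in names(freq_cpp)) {
    p_hat <- freq_cpp[[nm]] / n_draws
    p_ref <- freq_oracle[[nm]] / n_draws
    se <- sqrt(p_ref * (1 - p_ref) / n_draws)
    expect_lt(abs(p_hat - p_ref), 5 * se + 0.02)
  }
})

test_that("the matching invariant survives random update sequences", {
  set.seed(63)
  p <- engine_params(80)
  st <- init_random_walk(80, seed = 8)
  sites <- condensin_sites(80, 10)
  cp <- capture_params(d_cutoff = 6, p_capture = 0.5, p_release = 0.3)
  bonds <- matrix(0L, 0, 2)
  for (i in 1:60) {
    st <- step_brownian(st, p, n_steps = 20, seed = 1000 + i)
    bonds <- update_bonds(st, sites, bonds, cp, seed = 2000 + i)
    expect_matching(bonds, length(sites))
  }
})

test_that("condensin forces match per-bond brute-force summation", {
  set.seed(64)
  st <- chain_state(random_cloud(50, spread = 2))
  sites <- condensin_sites(50, 10)
  bonds <- rbind(c(1L, 3L), c(2L, 5L))
  cp <- capture_params(bond_spring = 25, bond_rest_length = 2)
  f <- condensin_force(st, sites, bonds, cp)
  oracle <- matrix(0, 50, 3)
  for (b in 1:nrow(bonds)) {
    i <- sites[bonds[b, 1]]; j <- sites[bonds[b, 2]]
    dvec <- st$positions[j, ] - st$positions[i, ]
    d <- sqrt(sum(dvec^2))
    fb <- 25 * (d - 2) * dvec / d
    oracle[i, ] <- oracle[i, ] + fb
    oracle[j, ] <- oracle[j, ] - fb
  }
  expect_equal(f, oracle, tolerance = 1e-12)
  expect_lt(max(abs(colSums(f))), 1e-10)

  expect_equal(condensin_force(st, sites, matrix(0L, 0, 2), cp),
               matrix(0, 50, 3))
  # one bond exactly at rest length gives zero force
  st2 <- chain_state(outer(0:49, c(3, 0, 0)))  # beads along x, spacing 3
  cp2 <- capture_params(bond_spring = 25, bond_rest_length = 3)
  f2 <- condensin_force(st2, c(1L, 2L), rbind(c(1L, 2L)), cp2)
  expect_equal(f2, matrix(0, 50, 3))
})

test_that("out-of-range bond indices abort", {
  st <- chain_state(random_cloud(20, seed = 65))
  cp <- capture_params()
  expect_error(condensin_force(st, c(1L, 11L), rbind(c(1L, 5L)), cp))
})

test_that("bonds keep forming and breaking at steady state", {
  set.seed(66)
  p <- engine_params(100)
  cp <- capture_params()
  tr <- run_loop_capture(p, cp, n_steps = 3e4, sample_every = 300,
                         seed = 19)
  nb <- tidy(tr)$n_bonds
  expect_gt(max(nb), 0)                     # bonds do form
  expect_gt(length(unique(tail(nb, 50))), 1)  # and keep turning over
})
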