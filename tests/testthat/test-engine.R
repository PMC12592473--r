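# Brownian dynamics engine: forces, integrator statistics, determinism.

test_that("spring forces follow Hooke's law and pair up", {
  p <- engine_params(2, spring_constant = 25, rest_length = 2)
  at_rest <- chain_state(rbind(c(0, 0, 0), c(2, 0, 0)))
  expect_equal(spring_force(at_rest, p), matrix(0, 2, 3))

  stretched <- chain_state(rbind(c(0, 0, 0), c(4, 0, 0)))  # distance 2 l0
  f <- spring_force(stretched, p)
  expect_equal(f[1, ], c(25 * 2, 0, 0))       # pulled towards partner
  expect_equal(f[2, ], -f[1, ])               # Newton's third law
})

test_that("spring forces on a random chain match the brute-force oracle", {
  set.seed(71)
  p <- engine_params(20)
  for (rep in 1:5) {
    pos <- random_cloud(20, spread = 4)
    st <- chain_state(pos)
    f <- spring_force(st, p)
    expect_equal(f, brute_spring(pos, p$spring_constant, p$rest_length),
                 tolerance = 1e-12)
    expect_lt(max(abs(colSums(f))), 1e-10)    # internal: total force zero
  }
})

test_that("repulsion is zero beyond contact and harmonic inside", {
  p <- engine_params(2, repulsion_constant = 25, bead_radius = 1)
  apart <- chain_state(rbind(c(0, 0, 0), c(3, 0, 0)))
  expect_equal(repulsion_force(apart, p), matrix(0, 2, 3))

  overlap <- chain_state(rbind(c(0, 0, 0), c(1, 0, 0)))  # d = a
  f <- repulsion_force(overlap, p)
  expect_equal(f[1, 1], -25 * 1)   # |F| = k_rep (2a - d) = k_rep * a
  expect_equal(f[2, 1], 25 * 1)
  expect_equal(f[, 2:3], matrix(0, 2, 2))
})

test_that("cell-list repulsion matches the all-pairs oracle on random clouds", {
  set.seed(72)
  p <- engine_params(50)
  for (spread in c(1.5, 3, 8)) {
    pos <- random_cloud(50, spread = spread)
    f <- repulsion_force(chain_state(pos), p)
    expect_equal(f, brute_repulsion(pos, p$repulsion_constant,
                                    p$bead_radius),
                 tolerance = 1e-12)
  }
})

test_that("coincident beads get a finite deterministic push, never NaN", {
  p <- engine_params(3)
  pos <- rbind(c(1, 1, 1), c(1, 1, 1), c(5, 5, 5))
  f <- repulsion_force(chain_state(pos), p)
  expect_true(all(is.finite(f)))
  expect_equal(f[2, 1], p$repulsion_constant * 2)   # +x on higher index
  expect_equal(f[1, 1], -p$repulsion_constant * 2)
})

test_that("internal forces sum to zero along simulated trajectories", {
  set.seed(73)
  p <- engine_params(30)
  st <- init_random_walk(30, seed = 5)
  for (i in 1:10) {
    st <- step_brownian(st, p, n_steps = 200, seed = 100 + i)
    total <- colSums(spring_force(st, p) + repulsion_force(st, p))
    expect_lt(max(abs(total)), 1e-9 * 30)
  }
})

test_that("zero temperature and zero force leave positions unchanged", {
  p <- engine_params(5, spring_constant = 0, repulsion_constant = 0, kT = 0)
  st <- init_random_walk(5, seed = 2)
  out <- step_brownian(st, p, n_steps = 50, seed = 9)
  expect_identical(out$positions, st$positions)
  expect_equal(out$time, 50 * p$dt)
})

test_that("free-bead mean squared displacement obeys the Einstein relation", {
  # many independent beads: springs and repulsion off, D = kT / gamma = 1
  n <- 4000
  p <- engine_params(n, spring_constant = 0, repulsion_constant = 0)
  st <- chain_state(matrix(0, n, 3))
  t_run <- 0.5
  out <- step_brownian(st, p, n_steps = round(t_run / p$dt), seed = 41)
  msd <- mean(rowSums(out$positions^2))
  # oracle: <r^2> = 6 D t; s.e. of the mean over n beads
  se <- sd(rowSums(out$positions^2)) / sqrt(n)
  expect_lt(abs(msd - 6 * t_run), 4 * se)
})

test_that("a single spring samples the Boltzmann bond-length distribution", {
  p <- engine_params(2, repulsion_constant = 0, spring_constant = 25)
  st <- chain_state(rbind(c(0, 0, 0), c(2, 0, 0)))
  tr <- simulate_chain(st, p, n_steps = 4e5, sample_every = 40, seed = 11)
  # bond length = 2 * (covariance length of the 2-bead system) / 2:
  # for two beads, L = 2 sqrt(lambda1) = separation
  bonds <- tidy(tr)$length
  target <- boltzmann_mean_bond(25, 2)
  se <- sd(bonds) / sqrt(length(bonds) / 20)  # crude decorrelation factor
  expect_lt(abs(mean(bonds[-(1:100)]) - target), 4 * se)
})

test_that("identical seeds give bit-identical trajectories", {
  p <- engine_params(40)
  st <- init_random_walk(40, seed = 3)
  t1 <- simulate_chain(st, p, n_steps = 2000, sample_every = 500, seed = 77)
  t2 <- simulate_chain(st, p, n_steps = 2000, sample_every = 500, seed = 77)
  expect_identical(t1$shapes, t2$shapes)
  expect_identical(t1$final_state$positions, t2$final_state$positions)
  t3 <- simulate_chain(st, p, n_steps = 2000, sample_every = 500, seed = 78)
  expect_false(identical(t1$final_state$positions,
                         t3$final_state$positions))
})

test_that("instability (bond beyond 10 rest lengths) aborts with advice", {
  p <- engine_params(3)
  st <- chain_state(rbind(c(0, 0, 0), c(50, 0, 0), c(100, 0, 0)))
  expect_error(
    simulate_chain(st, p, n_steps = 100, sample_every = 10, seed = 1),
    "reduce dt")
})

test_that("non-finite extra forces abort naming the offending bead", {
  p <- engine_params(3)
  st <- init_random_walk(3, seed = 1)
  bad <- matrix(0, 3, 3); bad[2, 1] <- NaN
  expect_error(step_brownian(st, p, extra_forces = bad, seed = 1),
               "bead 2")
})

test_that("the timestep stability guard rejects oversized dt", {
  expect_error(engine_params(10, spring_constant = 100, dt = 2e-3),
               "unstable timestep")
  expect_s3_class(engine_params(10, spring_constant = 100, dt = 5e-4),
                  "engine_params")
})
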