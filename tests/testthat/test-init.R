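# Initial conformations: random walk, elongated ellipsoid, pivot
# equilibration.

test_that("random-walk init has exact bond lengths and ideal-chain extent", {
  st <- init_random_walk(2, seed = 1)
  expect_equal(sqrt(sum(diff(st$positions)^2)), 2, tolerance = 1e-12)

  # ensemble oracle: <R^2> = (N - 1) l0^2 for an ideal chain
  n <- 40; draws <- 3000
  set.seed(90)
  r2 <- replicate(draws, {
    pos <- init_random_walk(n, rest_length = 2)$positions
    sum((pos[n, ] - pos[1, ])^2)
  })
  expected <- (n - 1) * 4
  se <- sd(r2) / sqrt(draws)
  expect_lt(abs(mean(r2) - expected), 3 * se)
})

test_that("random-walk init is seed-deterministic", {
  a <- init_random_walk(30, seed = 42)
  b <- init_random_walk(30, seed = 42)
  c <- init_random_walk(30, seed = 43)
  expect_identical(a$positions, b$positions)
  expect_false(identical(a$positions, c$positions))
})

test_that("elongated init places sorted z and the requested spreads", {
  st <- init_elongated(200, L0 = 40, w0 = 0, seed = 7)
  expect_equal(st$positions[, 1], rep(0, 200))   # w0 = 0: on the z axis
  expect_equal(st$positions[, 2], rep(0, 200))
  expect_false(is.unsorted(st$positions[, 3]))

  # spreads recover L0/2 and w0/2 over an ensemble
  set.seed(91)
  draws <- 400
  sds <- t(replicate(draws, {
    p <- init_elongated(100, L0 = 60, w0 = 8)$positions
    c(sd(p[, 1]), sd(p[, 2]), sd(p[, 3]))
  }))
  for (col in 1:2) {
    se <- sd(sds[, col]) / sqrt(draws)
    expect_lt(abs(mean(sds[, col]) - 4), 3 * se + 0.05)
  }
  se_z <- sd(sds[, 3]) / sqrt(draws)
  expect_lt(abs(mean(sds[, 3]) - 30), 3 * se_z + 0.5)
})

test_that("elongated init mean covariance length recovers L0", {
  # oracle: Gaussian z with sd L0/2 has lambda1 -> (L0/2)^2, so L -> L0
  set.seed(92)
  draws <- 300
  L <- replicate(draws, {
    covariance_shape(init_elongated(400, L0 = 80, w0 = 4)$positions)$length
  })
  se <- sd(L) / sqrt(draws)
  expect_lt(abs(mean(L) - 80), 3 * se + 0.5)
})

test_that("pivot equilibration is seed-deterministic and bounded", {
  p <- engine_params(60)
  a <- init_equilibrated(p, seed = 5)
  b <- init_equilibrated(p, seed = 5)
  expect_identical(a$positions, b$positions)
  bl <- sqrt(rowSums(diff(a$positions)^2))
  expect_true(all(bl < 10 * p$rest_length))
})
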