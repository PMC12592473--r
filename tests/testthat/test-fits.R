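# Statistical estimators: power-law, relaxation, scaling exponent,
# exponent time series.

test_that("power-law fit recovers exact data to machine precision", {
  d <- tibble::tibble(length = 1:10, width = 2 * (1:10)^0.5)
  f <- suppressWarnings(fit_power_law(d))
  expect_equal(f$prefactor, 2, tolerance = 1e-10)
  expect_equal(f$exponent, 0.5, tolerance = 1e-10)

  flat <- tibble::tibble(length = c(1, 2, 4, 8), width = 3)
  expect_equal(suppressWarnings(fit_power_law(flat))$exponent, 0,
               tolerance = 1e-12)
})

test_that("power-law fit rejects nonpositive data with row indices", {
  d <- tibble::tibble(length = c(1, -2, 3, 0), width = c(1, 1, 1, 1))
  expect_error(fit_power_law(d), "rows: 2, 4")
  expect_error(fit_power_law(tibble::tibble(length = 1:2, width = 1:2)),
               "at least 3")
})

test_that("power-law CI covers the truth at the nominal rate", {
  # generator: w = c L^alpha exp(eps), eps ~ N(0, 0.1^2), n = 80
  set.seed(100)
  alpha_true <- 0.45
  hits <- vapply(1:500, function(i) {
    L <- exp(rnorm(80, log(4), 0.4))
    w <- 1.3 * L^alpha_true * exp(rnorm(80, 0, 0.1))
    f <- fit_power_law(tibble::tibble(length = L, width = w))
    f$ci_exponent[1] <= alpha_true && alpha_true <= f$ci_exponent[2]
  }, logical(1))
  expect_gte(mean(hits), 0.90)
})

test_that("relaxation fit is exact on noiseless identifiable data", {
  d <- tibble::tibble(time = 0:30, value = 10 + 40 * exp(-(0:30) / 5))
  f <- fit_relaxation(d)
  expect_true(f$converged)
  expect_equal(f$plateau, 10, tolerance = 1e-6)
  expect_equal(f$amplitude, 40, tolerance = 1e-6)
  expect_equal(f$tau, 5, tolerance = 1e-6)
})

test_that("a constant series is flagged unidentifiable with plateau = mean", {
  d <- tibble::tibble(time = 0:20, value = 7)
  f <- fit_relaxation(d)
  expect_false(f$identifiable)
  expect_equal(f$plateau + f$amplitude * mean(exp(-d$time / f$tau)), 7,
               tolerance = 0.05)
})

test_that("relaxation tau is recovered within 10% under noise", {
  set.seed(101)
  taus <- vapply(1:200, function(i) {
    t <- seq(0, 30, by = 0.5)
    v <- 10 + 40 * exp(-t / 5) + rnorm(length(t))
    fit_relaxation(tibble::tibble(time = t, value = v))$tau
  }, numeric(1))
  expect_lt(abs(median(taus) - 5) / 5, 0.10)
})

test_that("scaling-exponent fit recovers an exact Flory law", {
  d <- tibble::tibble(n_beads = c(100, 250, 500, 1000),
                      length = c(100, 250, 500, 1000)^0.588)
  f <- suppressWarnings(fit_scaling_exponent(d))
  expect_equal(f$exponent, 0.588, tolerance = 1e-10)
})

test_that("exponent series tracks an increasing alpha schedule", {
  # replicate-averaged widths across three chain lengths per time point
  set.seed(102)
  schedule <- seq(0.05, 0.45, length.out = 6)
  d <- purrr::map_dfr(seq_along(schedule), function(ti) {
    purrr::map_dfr(c(60, 120, 240), function(N) {
      L <- N^0.6
      tibble::tibble(
        time = ti, n_beads = N, replicate = 1:4,
        length = L * exp(rnorm(4, 0, 0.02)),
        width = 1.1 * L^schedule[ti] * exp(rnorm(4, 0, 0.02)))
    })
  })
  es <- exponent_time_series(d)
  expect_equal(nrow(es$series), 6)
  expect_gt(es$trend$rho, 0)
  expect_lt(es$trend$p.value, 0.05)
  # recovered endpoint near the schedule endpoint
  expect_equal(tail(es$series$alpha, 1), 0.45, tolerance = 0.1)
})

test_that("exponent series enforces its replicate and chain-count contracts", {
  d <- tibble::tibble(time = 1, n_beads = c(60, 120), replicate = 1,
                      length = c(10, 20), width = c(3, 4))
  expect_error(exponent_time_series(d), "replicates")
})
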