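# Image measurements: moving-Gaussian FWHM, equal-area ellipse, halving,
# deciles, roundness split.

test_that("FWHM on a noiseless straight rod matches the closed form", {
  img <- make_chromosome_image(10, 0.6, 0.065, noise = "none")
  m <- fwhm_width(img$image, img$mask, 0.065)
  expect_false(m$flagged)
  # FWHM = 2 sqrt(2 ln 2) sigma by definition of the Gaussian profile
  expect_lt(abs(m$width - 0.6) / 0.6, 0.005)
})

test_that("FWHM with a centerline handles curved rods", {
  img <- make_chromosome_image(10, 0.6, 0.065, curvature = 0.05,
                               noise = "none")
  m <- fwhm_width(img$image, img$mask, 0.065,
                  centerline = img$centerline)
  expect_false(m$flagged)
  expect_lt(abs(m$width - 0.6) / 0.6, 0.03)
})

test_that("FWHM recovery under Poisson noise stays within 3%", {
  widths <- vapply(1:40, function(s) {
    img <- make_chromosome_image(8, 0.6, 0.065, noise = "poisson",
                                 snr = 10, seed = 5000 + s)
    fwhm_width(img$image, img$mask, 0.065)$width
  }, numeric(1))
  expect_true(all(is.finite(widths)))
  expect_lt(abs(mean(widths) - 0.6) / 0.6, 0.03)
})

test_that("a zero image is a flagged failure, not a number", {
  m <- fwhm_width(matrix(0, 40, 40),
                  rbind(matrix(FALSE, 18, 40),
                        matrix(TRUE, 4, 40),
                        matrix(FALSE, 18, 40)), 0.1)
  expect_true(m$flagged)
  expect_true(is.na(m$width))
})

test_that("the FWHM estimator is scale equivariant", {
  base <- make_chromosome_image(8, 0.6, 0.065, noise = "none")
  fine <- make_chromosome_image(8, 0.6, 0.0325, noise = "none")
  w1 <- fwhm_width(base$image, base$mask, 0.065)$width
  w2 <- fwhm_width(fine$image, fine$mask, 0.0325)$width
  expect_lt(abs(w1 - w2) / w1, 0.01)
  # in pixel units the fine render is exactly twice as wide
  w1px <- fwhm_width(base$image, base$mask, 1)$width
  w2px <- fwhm_width(fine$image, fine$mask, 1)$width
  expect_lt(abs(w2px - 2 * w1px) / (2 * w1px), 0.01)
})

rasterize <- function(nrow_px, ncol_px, f) {
  xs <- matrix(rep(0:(ncol_px - 1), each = nrow_px), nrow_px)
  ys <- matrix(rep(0:(nrow_px - 1), ncol_px), nrow_px)
  f(xs, ys)
}

test_that("equal-area ellipse is exact on a disk and recovers ellipses", {
  disk <- rasterize(50, 50, function(x, y) (x - 24)^2 + (y - 24)^2 <= 400)
  e <- equal_area_ellipse(disk, 1)
  expect_false(e$flagged)
  expect_lt(abs(e$length - 40), 1)
  expect_lt(abs(e$width - 40), 1)
  # equal-area contract holds exactly: pi a b = pixel count
  expect_equal(pi * (e$length / 2) * (e$width / 2), sum(disk),
               tolerance = 1e-10)

  ell <- rasterize(40, 100, function(x, y)
    (x - 49)^2 / 40^2 + (y - 19)^2 / 10^2 <= 1)
  e2 <- equal_area_ellipse(ell, 1)
  expect_lt(abs(e2$length - 80) / 80, 0.02)
  expect_lt(abs(e2$width - 20) / 20, 0.02)
})

test_that("equal-area ellipse axes are rotation invariant", {
  th <- 37 * pi / 180
  rot <- rasterize(220, 220, function(x, y) {
    xr <- cos(th) * (x - 109) + sin(th) * (y - 109)
    yr <- -sin(th) * (x - 109) + cos(th) * (y - 109)
    xr^2 / 80^2 + yr^2 / 20^2 <= 1
  })
  straight <- rasterize(60, 200, function(x, y)
    (x - 99)^2 / 80^2 + (y - 29)^2 / 20^2 <= 1)
  e_rot <- equal_area_ellipse(rot, 1)
  e_str <- equal_area_ellipse(straight, 1)
  expect_lt(abs(e_rot$length - e_str$length) / e_str$length, 0.01)
  expect_lt(abs(e_rot$width - e_str$width) / e_str$width, 0.01)
  # orientation reported modulo pi in [-pi/2, pi/2); the image y axis
  # points down, so the mathematical angle appears mirrored
  expect_equal(abs(e_rot$orientation), th, tolerance = 0.02)
})

test_that("degenerate and undersized masks are handled explicitly", {
  line <- matrix(FALSE, 30, 30); line[15, 3:28] <- TRUE
  e <- equal_area_ellipse(line, 1)
  expect_true(e$flagged)
  expect_equal(e$width, 0)

  tiny <- matrix(FALSE, 10, 10); tiny[5, 5:8] <- TRUE
  expect_error(equal_area_ellipse(tiny, 1), "10 pixels")
})

test_that("halving produces two tagged arm records per chromosome", {
  d <- tibble::tibble(chromosome = c("c1", "c2"), timepoint = 12,
                      length = c(10, 8), width = c(2, 1))
  arms <- halve_to_arm(d)
  expect_equal(nrow(arms), 4)
  expect_equal(sort(arms$length), c(4, 4, 5, 5))
  expect_equal(sort(arms$width), c(0.5, 0.5, 1, 1))
  expect_true(all(arms$derived == "halved"))
  expect_error(halve_to_arm(tibble::tibble(length = 0, width = 1)),
               "nonpositive")
})

test_that("decile lengths agree with a sorting oracle", {
  d <- tibble::tibble(timepoint = 1, length = sample(1:10))
  p <- percentile_lengths(d)
  # oracle: sorted order statistics with linear interpolation between
  # ranks, the continuous index for quantile q of n = 10 being 1 + 9 q
  sorted <- sort(d$length)
  oracle <- vapply(seq(0.1, 0.9, 0.1), function(q) {
    idx <- 1 + q * 9
    lo <- floor(idx)
    sorted[lo] + (idx - lo) * (sorted[lo + 1] - sorted[lo])
  }, numeric(1))
  expect_equal(p$length, oracle, tolerance = 1e-12)

  same <- tibble::tibble(timepoint = 2, length = rep(4.2, 12))
  p2 <- percentile_lengths(same)
  expect_true(all(p2$length == 4.2))

  few <- tibble::tibble(timepoint = 3, length = 1:5)
  p3 <- percentile_lengths(few)
  expect_true(all(p3$flagged))
  expect_true(all(is.na(p3$length)))
})

test_that("decile timecourse reproduces the early-plateau pattern", {
  # construct arms where short quantiles plateau early and long ones decay
  set.seed(110)
  times <- c(10, 60, 240)
  d <- purrr::map_dfr(times, function(tp) {
    short <- rnorm(30, 2, 0.1)                       # already at plateau
    long <- rnorm(30, 2 + 16 * exp(-tp / 120), 0.3)  # still decaying
    tibble::tibble(timepoint = tp, length = c(short, long))
  })
  p <- percentile_lengths(d)
  lo <- dplyr::filter(p, percentile == 10)
  hi <- dplyr::filter(p, percentile == 90)
  expect_lt(diff(range(lo$length)), 0.5)   # low decile flat in time
  expect_lt(hi$length[3], hi$length[1] - 2)  # high decile keeps dropping
})

test_that("roundness split partitions, fits, and reports n.a. subsets", {
  set.seed(111)
  L_high <- exp(rnorm(40, log(2), 0.3))
  high <- tibble::tibble(length = L_high,
                         width = 0.8 * L_high^0.75 * exp(rnorm(40, 0, 0.05)))
  high$roundness <- high$width / high$length
  high <- dplyr::filter(high, .data$roundness > 0.55)
  L_low <- exp(rnorm(40, log(8), 0.3))
  low <- tibble::tibble(length = L_low,
                        width = 0.5 * L_low^0.4 * exp(rnorm(40, 0, 0.05)))
  low$roundness <- low$width / low$length
  low <- dplyr::filter(low, .data$roundness <= 0.55)
  out <- roundness_split(dplyr::bind_rows(high, low), 0.55)
  hrow <- dplyr::filter(out, subset == "high")
  expect_true(hrow$applicable)
  expect_true(hrow$conf.low < 0.75 && 0.75 < hrow$conf.high)

  out2 <- roundness_split(low, 0.55)
  expect_false(dplyr::filter(out2, subset == "high")$applicable)
  out3 <- roundness_split(dplyr::mutate(high, roundness = 0.9), 1e-6)
  expect_equal(dplyr::filter(out3, subset == "low")$n_arms, 0)
})
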