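# Synthetic-data generators: determinism and truth-record consistency.

test_that("image generator is seed-deterministic with a coherent truth", {
  a <- make_chromosome_image(6, 0.5, 0.065, noise = "gaussian", snr = 8,
                             seed = 12)
  b <- make_chromosome_image(6, 0.5, 0.065, noise = "gaussian", snr = 8,
                             seed = 12)
  c <- make_chromosome_image(6, 0.5, 0.065, noise = "gaussian", snr = 8,
                             seed = 13)
  expect_identical(a$image, b$image)
  expect_false(identical(a$image, c$image))
  # truth record: sigma_px consistent with the FWHM definition
  expect_equal(a$truth$sigma_px * 2 * sqrt(2 * log(2)) * 0.065, 0.5)
  expect_true(all(dim(a$mask) == dim(a$image)))
})

test_that("tiff round trip preserves the image to write precision", {
  img <- make_chromosome_image(5, 0.5, 0.065, noise = "none")
  path <- withr::local_tempfile(fileext = ".tif")
  write_image_tiff(img$image, path)
  back <- read_image_tiff(path)
  expect_equal(dim(back), dim(img$image))
  expect_lt(max(abs(back - img$image)), 1 / 65535 + 1e-6)
})

test_that("arm table with zero noise is recovered exactly by the fit", {
  d <- make_arm_table(n_arms = 40, c_true = 1.4, alpha_true = 0.6,
                      sigma_log = 0, seed = 3)
  f <- suppressWarnings(fit_power_law(d))
  expect_equal(f$prefactor, 1.4, tolerance = 1e-10)
  expect_equal(f$exponent, 0.6, tolerance = 1e-10)
})

test_that("arm table is seed-deterministic and carries its truth", {
  a <- make_arm_table(seed = 5)
  b <- make_arm_table(seed = 5)
  expect_identical(a$width, b$width)
  tr <- attr(a, "truth")
  expect_equal(tr$alpha_true, 0.45)
})

test_that("an increasing alpha schedule is recovered as a rising series", {
  times <- c(12, 30, 60, 120, 240, 360)
  sched <- seq(0, 0.45, length.out = 6)
  d <- purrr::map_dfr(1:4, function(rep) {
    tab <- make_arm_table(n_arms = 60, alpha_true = sched,
                          timepoints = times, sigma_log = 0.1,
                          seed = 400 + rep)
    dplyr::mutate(tab, replicate = rep, n_beads = 0)
  })
  # average arms into per-(time, replicate-set) records across three
  # length strata to emulate replicate-averaged chains
  d$n_beads <- cut(d$length, quantile(d$length, c(0, 1/3, 2/3, 1)),
                   labels = FALSE, include.lowest = TRUE)
  agg <- d |>
    dplyr::group_by(.data$timepoint, .data$n_beads, .data$replicate) |>
    dplyr::summarise(length = mean(.data$length),
                     width = mean(.data$width), .groups = "drop") |>
    dplyr::rename(time = "timepoint")
  es <- exponent_time_series(agg)
  expect_gt(es$trend$rho, 0)
  expect_lt(es$trend$p.value, 0.05)
  expect_true(all(diff(es$series$alpha) > -0.1))  # non-decreasing to noise
})
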