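# Synthetic data generators: DAPI-like chromosome arm images with known
# cross-section FWHM, and arm-dimension tables with power-law structure.
# Every generator is seed-deterministic and returns the ground truth
# alongside its output so recovery tests can score the measurement
# operators.

#' Synthetic chromosome arm image
#'
#' Renders a rod (straight or circularly curved) with a Gaussian
#' cross-section of known FWHM — the idealised appearance of a
#' DAPI-stained chromosome arm — and adds optional noise. The returned
#' truth record carries everything a recovery test needs: the exact FWHM,
#' the centerline polyline and the half-maximum mask.
#'
#' Noise models: `"gaussian"` adds i.i.d. noise of s.d. `peak / snr`;
#' `"poisson"` draws photon counts with peak expectation `snr^2` (so the
#' peak signal-to-noise ratio is `snr`) and rescales back.
#'
#' @param length_um rod length in micrometres.
#' @param fwhm_um cross-section full width at half maximum, micrometres.
#' @param pixel_size micrometres per pixel.
#' @param curvature centerline curvature in 1/um (0 = straight rod).
#' @param noise `"none"`, `"gaussian"` or `"poisson"`.
#' @param snr peak signal-to-noise ratio for noisy renders.
#' @param margin_px empty margin around the rod, pixels.
#' @param seed integer seed; identical seeds give identical images.
#' @return a list of class `synthetic_image`: `$image` (numeric matrix),
#'   `$mask` (half-maximum mask of the noiseless render), `$centerline`
#'   (k x 2 polyline, 0-based pixel coords), and `$truth` (tibble with
#'   `fwhm_um`, `sigma_px`, `length_um`, `pixel_size`, `curvature`,
#'   `noise`, `snr`, `seed`).
#' @export
make_chromosome_image <- function(length_um, fwhm_um, pixel_size,
                                  curvature = 0,
                                  noise = c("none", "gaussian", "poisson"),
                                  snr = 10, margin_px = 10, seed = NULL) {
  noise <- match.arg(noise)
  stopifnot(length_um > 0, fwhm_um > 0, pixel_size > 0, snr > 0,
            curvature >= 0)
  sigma_px <- fwhm_um / (2 * sqrt(2 * log(2))) / pixel_size
  len_px <- length_um / pixel_size
  # centerline polyline in 0-based pixel coordinates
  if (curvature == 0) {
    cl <- cbind(x = seq(0, len_px, length.out = max(2, ceiling(len_px))),
                y = 0)
  } else {
    radius_px <- 1 / (curvature * pixel_size)
    theta_max <- len_px / radius_px
    if (theta_max >= pi) stop("curvature too strong for the rod length")
    th <- seq(0, theta_max, length.out = max(8, ceiling(len_px)))
    cl <- cbind(x = radius_px * sin(th), y = radius_px * (1 - cos(th)))
  }
  pad <- margin_px + ceiling(4 * sigma_px)
  cl[, 1] <- cl[, 1] - min(cl[, 1]) + pad
  cl[, 2] <- cl[, 2] - min(cl[, 2]) + pad
  ncol_px <- ceiling(max(cl[, 1])) + pad
  nrow_px <- ceiling(max(cl[, 2])) + pad
  xs <- matrix(rep(0:(ncol_px - 1), each = nrow_px), nrow_px)
  ys <- matrix(rep(0:(nrow_px - 1), ncol_px), nrow_px)
  uv <- polyline_coords(cbind(as.vector(xs), as.vector(ys)), cl)
  total_len <- sum(sqrt(rowSums(diff(cl)^2)))
  along <- uv[, 1] > 0 & uv[, 1] < total_len  # flat caps excluded
  clean <- matrix(0, nrow_px, ncol_px)
  clean[along] <- exp(-uv[along, 2]^2 / (2 * sigma_px^2))
  mask <- clean >= 0.5
  img <- with_local_seed(seed, {
    switch(noise,
      none = clean,
      gaussian = clean + matrix(rnorm(length(clean), sd = 1 / snr),
                                nrow_px, ncol_px),
      poisson = matrix(rpois(length(clean), lambda = clean * snr^2),
                       nrow_px, ncol_px) / snr^2)
  })
  structure(
    list(image = img, mask = mask, centerline = cl,
         truth = tibble(fwhm_um = fwhm_um, sigma_px = sigma_px,
                        length_um = length_um, pixel_size = pixel_size,
                        curvature = curvature, noise = noise, snr = snr,
                        seed = if (is.null(seed)) NA_integer_ else seed)),
    class = "synthetic_image"
  )
}

#' @export
print.synthetic_image <- function(x, ...) {
  cat("<synthetic_image>", nrow(x$image), "x", ncol(x$image), "px |",
      "FWHM", x$truth$fwhm_um, "um |", x$truth$noise, "noise\n")
  invisible(x)
}

#' Synthetic chromosome arm table
#'
#' Draws arm lengths from a log-normal distribution and generates widths
#' with exact power-law structure plus multiplicative log-normal noise:
#' `w = c * L^alpha * exp(e)`, `e ~ N(0, sigma_log^2)`. `alpha` may be a
#' vector along `timepoints` to emulate the exponent increasing over a
#' mitotic time course.
#'
#' @param n_arms arms per timepoint.
#' @param c_true power-law prefactor.
#' @param alpha_true exponent, length 1 or `length(timepoints)`.
#' @param sigma_log multiplicative noise s.d. on the log scale.
#' @param timepoints numeric vector of timepoints (minutes).
#' @param length_meanlog,length_sdlog log-normal arm-length parameters
#'   (micrometre scale).
#' @param seed integer seed.
#' @return tibble of arm records (`arm_id`, `timepoint`, `length`,
#'   `width`, `roundness`, `method = "synthetic"`), with the generating
#'   parameters attached as attribute `"truth"`.
#' @export
make_arm_table <- function(n_arms = 80, c_true = 1, alpha_true = 0.45,
                           sigma_log = 0.1, timepoints = 0,
                           length_meanlog = log(4), length_sdlog = 0.4,
                           seed = NULL) {
  stopifnot(n_arms >= 1, c_true > 0, all(alpha_true >= 0), sigma_log >= 0)
  alpha_true <- rep_len(alpha_true, length(timepoints))
  out <- with_local_seed(seed, {
    purrr::map2_dfr(timepoints, alpha_true, function(tp, alpha) {
      L <- exp(rnorm(n_arms, length_meanlog, length_sdlog))
      w <- c_true * L^alpha * exp(rnorm(n_arms, 0, sigma_log))
      tibble(arm_id = paste0("t", tp, "_arm", seq_len(n_arms)),
             timepoint = tp, length = L, width = w,
             roundness = w / L, method = "synthetic")
    })
  })
  attr(out, "truth") <- tibble(timepoint = timepoints, c_true = c_true,
                               alpha_true = alpha_true,
                               sigma_log = sigma_log, n_arms = n_arms)
  out
}
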