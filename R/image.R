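# Chromosome arm measurement on 2D grayscale images: moving-Gaussian FWHM
# widths and equal-area ellipse dimensions, plus the percentile and
# roundness-threshold analyses.
#
# Image convention: a numeric matrix, image[i, j] = intensity at row i
# (y), column j (x). Pixel centres sit at integer coordinates on a 0-based
# grid, so pixel (i, j) has centre (x, y) = (j - 1, i - 1) in pixel units;
# physical coordinates are pixel units times pixel_size (um/pixel).

#' Read / write grayscale TIFF images
#'
#' Thin wrappers over the tiff package returning plain numeric matrices in
#' the package's image convention.
#'
#' @param path file path.
#' @param image numeric matrix, values in \[0, 1\] are stored as-is; other
#'   ranges are rescaled to \[0, 1\] on write.
#' @return `read_image_tiff` returns a numeric matrix.
#' @export
read_image_tiff <- function(path) {
  img <- tiff::readTIFF(path, as.is = FALSE)
  if (length(dim(img)) == 3) img <- img[, , 1]
  img
}

#' @rdname read_image_tiff
#' @export
write_image_tiff <- function(image, path) {
  rng <- range(image)
  if (rng[1] < 0 || rng[2] > 1) {
    image <- (image - rng[1]) / max(rng[2] - rng[1], .Machine$double.eps)
  }
  tiff::writeTIFF(image, path, bits.per.sample = 16)
  invisible(path)
}

# principal-axis direction (unit vector) of a set of 0-based pixel
# coordinates (x, y)
mask_principal_axis <- function(xy) {
  cen <- colMeans(xy)
  cc <- crossprod(sweep(xy, 2, cen)) / nrow(xy)
  eig <- eigen(cc, symmetric = TRUE)
  list(centroid = cen, axis = eig$vectors[, 1], eigenvalues = eig$values)
}

# arc-length coordinate u and signed perpendicular offset v of points
# relative to a polyline (k x 2, 0-based pixel coords)
polyline_coords <- function(xy, polyline) {
  k <- nrow(polyline)
  segs <- polyline[-1, , drop = FALSE] - polyline[-k, , drop = FALSE]
  seg_len <- sqrt(rowSums(segs^2))
  cum <- c(0, cumsum(seg_len))
  u <- numeric(nrow(xy)); v <- numeric(nrow(xy))
  best <- rep(Inf, nrow(xy))
  for (s in seq_len(k - 1)) {
    p0 <- polyline[s, ]; d <- segs[s, ]; len <- seg_len[s]
    if (len == 0) next
    rel <- sweep(xy, 2, p0)
    tpar <- pmin(pmax((rel %*% d) / len^2, 0), 1)
    px <- p0[1] + tpar * d[1]; py <- p0[2] + tpar * d[2]
    dx <- xy[, 1] - px; dy <- xy[, 2] - py
    dist2 <- dx^2 + dy^2
    sgn <- sign(dx * d[2] - dy * d[1])  # side of the segment
    upd <- dist2 < best
    best[upd] <- dist2[upd]
    u[upd] <- cum[s] + tpar[upd] * len
    v[upd] <- (sgn * sqrt(dist2))[upd]
  }
  cbind(u = u, v = v)
}

# Gaussian fit to one intensity slice; returns sigma (px) or NA
fit_slice_gaussian <- function(v, inten) {
  if (length(v) < 4 || sum(inten > 0) < 4) return(NA_real_)
  if (max(inten) <= 0 || diff(range(inten)) < 1e-12 * max(abs(inten)))
    return(NA_real_)  # flat profile
  w <- pmax(inten, 0)
  mu0 <- sum(v * w) / sum(w)
  s0 <- sqrt(max(sum(w * (v - mu0)^2) / sum(w), 0.25))
  a0 <- max(inten)
  # Levenberg-Marquardt on the raw residuals: robust where the formula
  # interface of nls() aborts (zero-residual or near-symmetric profiles)
  fit <- tryCatch(
    minpack.lm::nls.lm(
      par = c(a = a0, mu = mu0, s = s0),
      fn = function(p) inten - p[1] * exp(-(v - p[2])^2 / (2 * p[3]^2)),
      control = minpack.lm::nls.lm.control(maxiter = 100)),
    error = function(e) NULL)
  if (is.null(fit) || !fit$info %in% 1:4) return(NA_real_)
  s_hat <- abs(unname(fit$par["s"]))
  if (!is.finite(s_hat) || s_hat <= 0) NA_real_ else s_hat
}

#' Moving-Gaussian FWHM chromosome width
#'
#' The moving-Gaussian width protocol: intensities outside the traced mask
#' are set to zero, the image is cut into one-pixel slices perpendicular
#' to the chromosome length axis (the supplied centerline polyline, or
#' otherwise the mask's principal axis), a single Gaussian is fitted to
#' every slice profile, and the mean full width at half maximum,
#' `FWHM = 2 sqrt(2 ln 2) sigma`, over all successful slices is returned
#' in micrometres.
#'
#' Slices whose fit fails (flat or degenerate profile) are skipped and
#' counted; if more than half of the slices are skipped, or fewer than 5
#' slices exist, the measurement is flagged and the width is `NA`.
#'
#' @param image numeric intensity matrix.
#' @param mask logical (or 0/1) matrix of the traced region, same shape.
#' @param pixel_size micrometres per pixel.
#' @param centerline optional k x 2 matrix of (x, y) polyline vertices in
#'   0-based pixel coordinates; slices are then taken perpendicular to the
#'   local centerline direction.
#' @return one-row tibble: `width` (um, `NA` when flagged), `n_slices`,
#'   `n_skipped`, `flagged`.
#' @export
fwhm_width <- function(image, mask, pixel_size, centerline = NULL) {
  stopifnot(is.matrix(image), all(dim(mask) == dim(image)), pixel_size > 0)
  mask <- mask > 0
  img <- image
  img[!mask] <- 0  # intensities outside the mask are zeroed
  idx <- which(mask, arr.ind = TRUE)
  flagged_out <- tibble(width = NA_real_, n_slices = 0L, n_skipped = 0L,
                        flagged = TRUE)
  if (nrow(idx) < 10 || max(img) <= 0) return(flagged_out)
  xy <- cbind(x = idx[, 2] - 1, y = idx[, 1] - 1)
  inten <- img[idx]
  if (!is.null(centerline)) {
    uv <- polyline_coords(xy, as.matrix(centerline))
  } else {
    pa <- mask_principal_axis(xy)
    rel <- sweep(xy, 2, pa$centroid)
    uv <- cbind(u = rel %*% pa$axis,
                v = rel %*% c(-pa$axis[2], pa$axis[1]))
  }
  slice_id <- floor(uv[, 1])  # one-pixel slices along the axis
  sigmas <- vapply(split(seq_len(nrow(xy)), slice_id), function(ii) {
    fit_slice_gaussian(uv[ii, 2], inten[ii])
  }, numeric(1))
  n_slices <- length(sigmas)
  n_skipped <- sum(is.na(sigmas))
  flagged <- n_slices < 5 || n_skipped > n_slices / 2
  width <- if (flagged) NA_real_ else {
    2 * sqrt(2 * log(2)) * mean(sigmas, na.rm = TRUE) * pixel_size
  }
  tibble(width = width, n_slices = n_slices, n_skipped = n_skipped,
         flagged = flagged)
}

#' Equal-area ellipse dimensions of a traced region
#'
#' Fits the ellipse a tracing workflow reports for a mask: orientation and
#' axis ratio come from the mask's second central moments (pixel centres,
#' population covariance), and both axes are rescaled by a common factor
#' so the ellipse area exactly equals the mask area (pixel count times
#' pixel area). Returns the full major and minor axis lengths, in
#' micrometres, as (length, width).
#'
#' @param mask logical (or 0/1) matrix.
#' @param pixel_size micrometres per pixel.
#' @return one-row tibble: `length`, `width` (um), `orientation` (radians,
#'   major axis vs x), `area` (um^2), `flagged` (degenerate/collinear
#'   masks give width 0 and are flagged).
#' @export
equal_area_ellipse <- function(mask, pixel_size) {
  stopifnot(is.matrix(mask), pixel_size > 0)
  idx <- which(mask > 0, arr.ind = TRUE)
  if (nrow(idx) < 10) stop("mask area below 10 pixels")
  xy <- cbind(idx[, 2] - 1, idx[, 1] - 1)
  cen <- colMeans(xy)
  cc <- crossprod(sweep(xy, 2, cen)) / nrow(xy)
  eig <- eigen(cc, symmetric = TRUE)
  lam <- pmax(eig$values, 0)
  area_px <- nrow(xy)
  if (lam[2] <= 0) {
    return(tibble(length = 2 * sqrt(lam[1]) * 2 * pixel_size, width = 0,
                  orientation = atan2(eig$vectors[2, 1], eig$vectors[1, 1]),
                  area = area_px * pixel_size^2, flagged = TRUE))
  }
  # moment axes of a filled ellipse with semi-axes (A, B): lam = (A^2, B^2)/4
  semi <- 2 * sqrt(lam)
  scale <- sqrt(area_px / (pi * semi[1] * semi[2]))
  semi <- semi * scale  # exact equal-area contract
  # orientation is defined modulo pi; report in [-pi/2, pi/2)
  theta <- atan2(eig$vectors[2, 1], eig$vectors[1, 1])
  theta <- ((theta + pi / 2) %% pi) - pi / 2
  tibble(
    length = 2 * semi[1] * pixel_size,
    width = 2 * semi[2] * pixel_size,
    orientation = theta,
    area = area_px * pixel_size^2,
    flagged = FALSE
  )
}

#' Halve whole-chromosome measurements into arm records
#'
#' Early mitotic timepoints show no centromere constriction, so arms
#' cannot be told apart; the approximation is that each of a chromosome's
#' four arms occupies half the chromosome length and half its width. Each
#' chromosome row therefore yields two arm records with both dimensions
#' halved, tagged with their provenance.
#'
#' @param data data frame of chromosome measurements.
#' @param length,width column names; defaults `length`, `width`.
#' @return a tibble with two rows per input row, `length` and `width`
#'   halved, plus `arm` (`"a"`/`"b"`) and `derived = "halved"`; rows with
#'   nonpositive dimensions abort.
#' @export
halve_to_arm <- function(data, length = "length", width = "width") {
  L <- data[[length]]; w <- data[[width]]
  if (any(!is.finite(L) | L <= 0 | !is.finite(w) | w <= 0)) {
    stop("nonpositive chromosome dimensions cannot be halved to arms")
  }
  out <- dplyr::bind_rows(
    dplyr::mutate(data, arm = "a"),
    dplyr::mutate(data, arm = "b"))
  out[[length]] <- out[[length]] / 2
  out[[width]] <- out[[width]] / 2
  dplyr::mutate(as_tibble(out), derived = "halved")
}

#' Decile arm lengths per timepoint
#'
#' The 10th through 90th percentile of arm lengths at each timepoint
#' (linear interpolation between order statistics, `stats::quantile`
#' type 7). Timepoints with fewer than 10 arms are flagged and their
#' deciles set to `NA`.
#'
#' @param data data frame of arm records.
#' @param length,timepoint column names; defaults `length`, `timepoint`.
#' @return tibble with `timepoint`, `percentile` (10, ..., 90), `length`,
#'   `n_arms`, `flagged`.
#' @export
percentile_lengths <- function(data, length = "length",
                               timepoint = "timepoint") {
  probs <- seq(0.1, 0.9, by = 0.1)
  data |>
    dplyr::group_by(timepoint = .data[[timepoint]]) |>
    dplyr::group_modify(function(d, key) {
      n <- nrow(d)
      if (n < 10) {
        tibble(percentile = probs * 100, length = NA_real_,
               n_arms = n, flagged = TRUE)
      } else {
        tibble(percentile = probs * 100,
               length = unname(quantile(d[[length]], probs, type = 7)),
               n_arms = n, flagged = FALSE)
      }
    }) |>
    dplyr::ungroup()
}

#' Split arms by roundness and fit per-subset power laws
#'
#' Partitions arm records at a roundness threshold (the late-time median
#' roundness 0.55 by default) into `r > threshold` ("high") and
#' `r <= threshold` ("low") subsets and fits the length-to-width power law
#' in each. A subset with fewer than 3 arms is reported as not applicable
#' (`n.a.`), with `NA` parameters.
#'
#' @param data arm records with `length`, `width` and `roundness` columns.
#' @param threshold roundness threshold in (0, 1).
#' @return tibble with one row per subset: `subset`, `n_arms`,
#'   `prefactor`, `exponent`, `se_exponent`, `conf.low`, `conf.high`,
#'   `applicable`.
#' @export
roundness_split <- function(data, threshold = 0.55) {
  stopifnot(threshold > 0, threshold < 1,
            all(c("length", "width", "roundness") %in% names(data)))
  groups <- list(high = dplyr::filter(data, .data$roundness > threshold),
                 low = dplyr::filter(data, .data$roundness <= threshold))
  purrr::imap_dfr(groups, function(d, nm) {
    if (nrow(d) < 3) {
      tibble(subset = nm, n_arms = nrow(d), prefactor = NA_real_,
             exponent = NA_real_, se_exponent = NA_real_,
             conf.low = NA_real_, conf.high = NA_real_, applicable = FALSE)
    } else {
      f <- fit_power_law(d)
      tibble(subset = nm, n_arms = nrow(d), prefactor = f$prefactor,
             exponent = f$exponent, se_exponent = f$se_exponent,
             conf.low = f$ci_exponent[1], conf.high = f$ci_exponent[2],
             applicable = TRUE)
    }
  })
}
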