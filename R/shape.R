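# Covariance-eigenvalue chain dimensions.

#' Covariance-eigenvalue dimensions of a conformation
#'
#' Length, width and depth of a bead cloud from the eigenvalues of the
#' 3 x 3 covariance matrix of bead positions: with eigenvalues
#' `l1 >= l2 >= l3`, length `L = 2 sqrt(l1)`, width `w = 2 sqrt(l2)`,
#' depth `d = 2 sqrt(l3)`, and roundness `r = w / L`. The covariance is
#' normalised by N (population form): it describes the shape of this point
#' cloud, not an estimator of some parent distribution, and ensemble
#' statistics stay comparable across N.
#'
#' All beads coincident gives L = w = d = 0 and `roundness = NA` (flagged,
#' not NaN). The measure is exactly translation invariant and rotation
#' invariant to eigen-solver precision.
#'
#' @param positions N x 3 coordinate matrix (N >= 2) or a [chain_state()].
#' @return one-row tibble: `length`, `width`, `depth`, `roundness`.
#' @examples
#' covariance_shape(cbind(c(-1, 1), 0, 0))  # L = 2, w = d = 0
#' @export
covariance_shape <- function(positions) {
  if (inherits(positions, "chain_state")) positions <- positions$positions
  positions <- as.matrix(positions)
  if (nrow(positions) < 2L) stop("need at least 2 beads")
  if (!all(is.finite(positions))) stop("non-finite coordinates")
  d <- cpp_covariance_dims(positions)
  tibble(
    length = d[1], width = d[2], depth = d[3],
    roundness = if (d[1] > 0) d[2] / d[1] else NA_real_
  )
}

#' Roundness of a shape record
#'
#' Width divided by length, the chromosome-arm roundness measure. The
#' theoretical random-polymer proportions length:width:depth =
#' 3.44:1.64:1 give `1.64 / 3.44 = 0.48`.
#'
#' @param rec a data frame with `length` and `width` columns (one or more
#'   rows), e.g. from [covariance_shape()].
#' @return numeric vector of `width / length`; `NA` where length is zero.
#' @export
roundness <- function(rec) {
  stopifnot(all(c("length", "width") %in% names(rec)))
  ifelse(rec$length > 0, rec$width / rec$length, NA_real_)
}
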