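# ggplot2 visualisation methods.

#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point labs
#'   scale_x_log10 scale_y_log10 geom_ribbon theme_minimal geom_errorbar
NULL

#' Plot a trajectory's shape time series
#'
#' Length, width and depth against reduced time.
#'
#' @param object a `chain_trajectory`.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot chain_trajectory
#' @export
autoplot.chain_trajectory <- function(object, ...) {
  long <- tidyr::pivot_longer(object$shapes,
                              cols = c("length", "width", "depth"),
                              names_to = "dimension")
  ggplot(long, aes(x = .data$time, y = .data$value,
                   colour = .data$dimension)) +
    geom_line() +
    labs(x = "time (reduced units)", y = "size (bead radii)",
         colour = NULL,
         title = sprintf("N = %d chain", object$params$n_beads)) +
    theme_minimal()
}

#' Plot a power-law fit
#'
#' Data and fitted line on double-logarithmic axes.
#'
#' @param object a `power_law_fit`.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot power_law_fit
#' @export
autoplot.power_law_fit <- function(object, ...) {
  m <- object$model$model
  d <- tibble(L = exp(m[["log(L)"]]), w = exp(m[["log(w)"]]))
  ggplot(d, aes(x = .data$L, y = .data$w)) +
    geom_point() +
    geom_line(aes(y = object$prefactor * .data$L^object$exponent),
              colour = "red") +
    scale_x_log10() + scale_y_log10() +
    labs(x = "length", y = "width",
         title = sprintf("w = %.3g L^%.3g", object$prefactor,
                         object$exponent)) +
    theme_minimal()
}

#' Plot an exponential relaxation fit
#'
#' @param object a `relaxation_fit`.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot relaxation_fit
#' @export
autoplot.relaxation_fit <- function(object, ...) {
  if (is.null(object$model)) stop("no converged model to plot")
  env <- environment(stats::formula(object$model))
  d <- tibble(time = env$t, value = env$v)
  ggplot(d, aes(x = .data$time, y = .data$value)) +
    geom_point(alpha = 0.6) +
    geom_line(aes(y = object$plateau +
                    object$amplitude * exp(-.data$time / object$tau)),
              colour = "red") +
    labs(x = "time", y = "value",
         title = sprintf("plateau %.3g, tau %.3g", object$plateau,
                         object$tau)) +
    theme_minimal()
}

#' Plot the power-law exponent over time
#'
#' alpha(t) with a +/- 1 s.e. ribbon.
#'
#' @param object an `exponent_series`.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot exponent_series
#' @export
autoplot.exponent_series <- function(object, ...) {
  ggplot(object$series, aes(x = .data$time, y = .data$alpha)) +
    geom_ribbon(aes(ymin = .data$alpha - .data$se_alpha,
                    ymax = .data$alpha + .data$se_alpha), alpha = 0.2) +
    geom_line() + geom_point() +
    labs(x = "time", y = "power-law exponent alpha") +
    theme_minimal()
}

#' Plot decile arm lengths over time
#'
#' One line per length decile, the standard way to follow arm-length
#' percentiles through a mitotic time course.
#'
#' @param percentiles output of [percentile_lengths()].
#' @return a ggplot.
#' @export
plot_percentile_lengths <- function(percentiles) {
  ggplot(dplyr::filter(percentiles, !.data$flagged),
         aes(x = .data$timepoint, y = .data$length,
             colour = factor(.data$percentile),
             group = .data$percentile)) +
    geom_line() + geom_point() +
    labs(x = "time (min)", y = "arm length (um)",
         colour = "percentile") +
    theme_minimal()
}
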