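# Estimators: power-law length-to-width fits, exponential relaxation fits,
# scaling-exponent estimation.

#' Power-law fit of width against length
#'
#' Fits `w = c * L^alpha` by ordinary least squares of `log(w)` on
#' `log(L)` (the double-logarithmic regression used throughout for
#' length-to-width relationships): `alpha` is the slope, `c` the
#' exponentiated intercept, and the 95% CI of `alpha` comes from standard
#' linear-regression theory. The power law is a convenient descriptive
#' form over the observed one-decade ranges, not a tested asymptotic law —
#' a proper power-law test would need several orders of magnitude in both
#' variables.
#'
#' @param data data frame of measurements.
#' @param length,width column names (tidy-eval) holding strictly positive
#'   lengths and widths; default `length`, `width`.
#' @return an object of class `power_law_fit`; see [tidy.power_law_fit()].
#'   Nonpositive pairs abort with the offending row indices.
#' @examples
#' d <- tibble::tibble(length = 1:10, width = 2 * (1:10)^0.5)
#' glance(fit_power_law(d))  # recovers c = 2, alpha = 0.5
#' @export
fit_power_law <- function(data, length = "length", width = "width") {
  L <- data[[length]]
  w <- data[[width]]
  bad <- which(!(is.finite(L) & is.finite(w) & L > 0 & w > 0))
  if (length(bad) > 0) {
    stop("nonpositive or non-finite length/width at rows: ",
         paste(bad, collapse = ", "))
  }
  if (base::length(L) < 3) stop("need at least 3 positive (L, w) pairs")
  fit <- lm(log(w) ~ log(L))
  cf <- summary(fit)$coefficients
  ci <- suppressMessages(confint(fit))
  structure(
    list(
      model = fit,
      prefactor = exp(cf[1, 1]),
      exponent = cf[2, 1],
      se_log_prefactor = cf[1, 2],
      se_exponent = cf[2, 2],
      ci_exponent = ci[2, ],
      n = base::length(L)
    ),
    class = "power_law_fit"
  )
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat(sprintf(
    "<power_law_fit> w = %.4g * L^%.4g  (alpha 95%% CI [%.4g, %.4g], n = %d)\n",
    x$prefactor, x$exponent, x$ci_exponent[1], x$ci_exponent[2], x$n))
  invisible(x)
}

#' Tidy a power-law fit
#'
#' @param x a `power_law_fit`.
#' @param ... unused.
#' @return a tibble with one row per parameter (`prefactor`, `exponent`):
#'   estimate, standard error, and the exponent's 95% CI.
#' @method tidy power_law_fit
#' @export
tidy.power_law_fit <- function(x, ...) {
  tibble(
    term = c("prefactor", "exponent"),
    estimate = c(x$prefactor, x$exponent),
    std.error = c(x$prefactor * x$se_log_prefactor, x$se_exponent),
    conf.low = c(NA_real_, x$ci_exponent[1]),
    conf.high = c(NA_real_, x$ci_exponent[2])
  )
}

#' @method glance power_law_fit
#' @export
glance.power_law_fit <- function(x, ...) {
  tibble(
    prefactor = x$prefactor, exponent = x$exponent,
    se_exponent = x$se_exponent,
    conf.low = x$ci_exponent[1], conf.high = x$ci_exponent[2],
    r.squared = summary(x$model)$r.squared, n = x$n
  )
}

#' Exponential relaxation fit
#'
#' Fits `V(t) = plateau + amplitude * exp(-t / tau)` in two stages, the
#' scheme classically used for chain-length relaxation curves: a
#' derivative-free Nelder-Mead simplex minimisation of the squared error,
#' whose optimum then seeds a Levenberg-Marquardt nonlinear least-squares
#' refinement ([minpack.lm::nlsLM]) that supplies parameter standard
#' errors. The steady-state value of a relaxing observable is the fitted
#' `plateau`, not a tail average.
#'
#' `tau` is constrained to (0, 1000 x observation window] to prevent
#' runaway plateaus. If the amplitude is smaller than 2 standard errors the
#' decay is flagged unidentifiable (`identifiable = FALSE`); if the
#' refinement cannot run the result is flagged `converged = FALSE` and the
#' simplex parameters are reported with NA standard errors — no silent
#' fallback.
#'
#' @param data data frame with the time series.
#' @param time,value column names; defaults `time`, `value`.
#' @return an object of class `relaxation_fit`.
#' @examples
#' d <- tibble::tibble(time = 0:30, value = 10 + 40 * exp(-(0:30) / 5))
#' glance(fit_relaxation(d))  # plateau 10, amplitude 40, tau 5
#' @export
fit_relaxation <- function(data, time = "time", value = "value") {
  t <- data[[time]]
  v <- data[[value]]
  keep <- is.finite(t) & is.finite(v)
  t <- t[keep]; v <- v[keep]
  if (length(t) < 5) stop("need at least 5 time points")
  window <- max(t) - min(t)
  tau_max <- 1000 * window
  # moment-based starting values
  v0 <- v[which.min(t)]
  vinf <- mean(v[t >= quantile(t, 0.75)])
  start <- c(plateau = vinf, amplitude = v0 - vinf,
             log_tau = log(max(window / 5, .Machine$double.eps)))
  sse <- function(p) {
    tau <- exp(p[3])
    if (!is.finite(tau) || tau <= 0 || tau > tau_max) return(1e300)
    sum((v - (p[1] + p[2] * exp(-t / tau)))^2)
  }
  nm <- optim(start, sse, method = "Nelder-Mead",
              control = list(maxit = 2000, reltol = 1e-12))
  plateau <- unname(nm$par[1])
  amplitude <- unname(nm$par[2])
  tau <- unname(exp(nm$par[3]))
  refined <- tryCatch({
    fit <- minpack.lm::nlsLM(
      v ~ plateau + amplitude * exp(-t / tau),
      start = list(plateau = plateau, amplitude = amplitude, tau = tau),
      lower = c(-Inf, -Inf, .Machine$double.eps),
      upper = c(Inf, Inf, tau_max),
      control = minpack.lm::nls.lm.control(maxiter = 200))
    cf <- summary(fit)$coefficients
    list(plateau = cf["plateau", 1], amplitude = cf["amplitude", 1],
         tau = cf["tau", 1],
         se = cf[, 2], converged = TRUE, model = fit)
  }, error = function(e) {
    list(plateau = plateau, amplitude = amplitude, tau = tau,
         se = c(plateau = NA_real_, amplitude = NA_real_, tau = NA_real_),
         converged = FALSE, model = NULL)
  })
  identifiable <- refined$converged &&
    is.finite(refined$se["amplitude"]) &&
    abs(refined$amplitude) >= 2 * refined$se["amplitude"]
  structure(
    list(plateau = refined$plateau, amplitude = refined$amplitude,
         tau = refined$tau,
         se_plateau = unname(refined$se["plateau"]),
         se_amplitude = unname(refined$se["amplitude"]),
         se_tau = unname(refined$se["tau"]),
         converged = refined$converged, identifiable = identifiable,
         model = refined$model, n = length(t),
         simplex_value = nm$value),
    class = "relaxation_fit"
  )
}

#' @export
print.relaxation_fit <- function(x, ...) {
  cat(sprintf(
    "<relaxation_fit> V(t) = %.4g + %.4g exp(-t/%.4g)%s%s (n = %d)\n",
    x$plateau, x$amplitude, x$tau,
    if (!x$converged) " [NOT CONVERGED]" else "",
    if (!x$identifiable) " [decay unidentifiable]" else "", x$n))
  invisible(x)
}

#' @method tidy relaxation_fit
#' @export
tidy.relaxation_fit <- function(x, ...) {
  tibble(
    term = c("plateau", "amplitude", "tau"),
    estimate = c(x$plateau, x$amplitude, x$tau),
    std.error = c(x$se_plateau, x$se_amplitude, x$se_tau)
  )
}

#' @method glance relaxation_fit
#' @export
glance.relaxation_fit <- function(x, ...) {
  tibble(plateau = x$plateau, amplitude = x$amplitude, tau = x$tau,
         se_tau = x$se_tau, converged = x$converged,
         identifiable = x$identifiable, n = x$n)
}

#' Flory scaling exponent of size against chain length
#'
#' Log-log regression of ensemble-mean polymer size on chain length N.
#' A 3D self-avoiding chain is expected to scale as `N^0.588`.
#'
#' @param data data frame with one row per chain length.
#' @param n_beads,size column names; defaults `n_beads`, `length`.
#' @return a `power_law_fit` whose `exponent` is the Flory exponent nu.
#' @export
fit_scaling_exponent <- function(data, n_beads = "n_beads",
                                 size = "length") {
  fit_power_law(data, length = n_beads, width = size)
}

#' Power-law exponent of the length-to-width relation over time
#'
#' At each sampled time point, averages length and width over replicates
#' within each chain length N, then fits the power law `w = c L^alpha`
#' across the N values; the error model is the standard error of the mean
#' over replicates. Returns the exponent series together with a Spearman
#' trend test of `alpha` against time (the loop-capture prediction is a
#' non-decreasing exponent as rosettes remodel).
#'
#' @param data data frame of shape records with columns `time`, `n_beads`,
#'   `replicate`, `length`, `width`.
#' @return a list of class `exponent_series`: `$series` (tibble with
#'   `time`, `alpha`, `se_alpha`, `n_chains`) and `$trend` (Spearman rho
#'   and p-value of alpha vs time).
#' @export
exponent_time_series <- function(data) {
  needed <- c("time", "n_beads", "replicate", "length", "width")
  stopifnot(all(needed %in% names(data)))
  means <- data |>
    dplyr::group_by(.data$time, .data$n_beads) |>
    dplyr::summarise(
      n_rep = dplyr::n(),
      sem_length = sd(.data$length) / sqrt(dplyr::n()),
      sem_width = sd(.data$width) / sqrt(dplyr::n()),
      length = mean(.data$length),
      width = mean(.data$width),
      .groups = "drop")
  if (any(means$n_rep < 2)) {
    stop("need >= 2 replicates per (time, n_beads) cell")
  }
  series <- means |>
    dplyr::group_by(.data$time) |>
    dplyr::group_modify(function(d, key) {
      if (nrow(d) < 3) stop("need >= 3 chain lengths per time point")
      f <- fit_power_law(d)
      tibble(alpha = f$exponent, se_alpha = f$se_exponent,
             prefactor = f$prefactor, n_chains = nrow(d))
    }) |>
    dplyr::ungroup()
  trend <- suppressWarnings(
    cor.test(series$time, series$alpha, method = "spearman"))
  structure(
    list(series = series,
         trend = tibble(rho = unname(trend$estimate),
                        p.value = trend$p.value)),
    class = "exponent_series"
  )
}

#' @export
print.exponent_series <- function(x, ...) {
  cat("<exponent_series>", nrow(x$series), "time points | alpha",
      signif(min(x$series$alpha), 3), "->",
      signif(max(x$series$alpha), 3),
      sprintf("| Spearman rho = %.3f (p = %.3g)\n",
              x$trend$rho, x$trend$p.value))
  invisible(x)
}

#' @method tidy exponent_series
#' @export
tidy.exponent_series <- function(x, ...) x$series
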