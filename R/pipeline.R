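# Orchestration of the simulation experiments: equilibrium sweep,
# loop-capture steady state, and the elongated-release timecourse.

#' Steady-state dimension lookup
#'
#' Pilot-run steady-state length and width of loop-capture chains per
#' chain length N, cached in the package (`inst/extdata/
#' steady_state_lookup.csv`, generated with [pilot_steady_state()] at the
#' default capture parameters). These set the elongated initial condition
#' of the timecourse experiment (L0 = 4x steady length, w0 = 1x steady
#' width) and the reduced-time-to-minutes calibration.
#'
#' @param n_beads optional filter on chain length.
#' @return tibble with `n_beads`, `length`, `width`, `tau`.
#' @export
steady_state_lookup <- function(n_beads = NULL) {
  path <- system.file("extdata", "steady_state_lookup.csv",
                      package = "chromoshape")
  tab <- as_tibble(utils::read.csv(path))
  if (!is.null(n_beads)) {
    tab <- dplyr::filter(tab, .data$n_beads %in% !!n_beads)
    missing <- setdiff(n_beads, tab$n_beads)
    if (length(missing) > 0) {
      stop("no cached steady state for N = ",
           paste(missing, collapse = ", "),
           "; run pilot_steady_state() for these chain lengths")
    }
  }
  tab
}

#' Pilot steady-state run for one chain length
#'
#' Runs loop-capture replicates from pivot-equilibrated starts, averages
#' the replicate length series, and extracts the steady-state length and
#' width as relaxation-fit plateaus (tail means as fallback when the decay
#' is unidentifiable, e.g. when the run starts near steady state). Used to
#' populate [steady_state_lookup()].
#'
#' @param n_beads chain length N.
#' @param capture a [capture_params()].
#' @param t_max run duration in reduced time; defaults to a length-scaled
#'   heuristic.
#' @param n_reps replicates.
#' @param seed integer seed.
#' @return one-row tibble: `n_beads`, `length`, `width`, `tau`.
#' @export
pilot_steady_state <- function(n_beads, capture = capture_params(),
                               t_max = NULL, n_reps = 3, seed = 1) {
  params <- engine_params(n_beads)
  if (is.null(t_max)) t_max <- default_horizon(n_beads)
  n_steps <- ceiling(t_max / params$dt)
  sample_every <- max(1L, floor(n_steps / 200))
  runs <- purrr::map(seq_len(n_reps), function(r) {
    run_loop_capture(params, capture, n_steps = n_steps,
                     sample_every = sample_every,
                     seed = derive_seed(seed, 100 * n_beads + r))
  })
  mean_series <- purrr::map_dfr(runs, ~ .x$shapes, .id = "replicate") |>
    dplyr::group_by(.data$time) |>
    dplyr::summarise(length = mean(.data$length), width = mean(.data$width),
                     .groups = "drop")
  fitL <- fit_relaxation(mean_series, value = "length")
  fitw <- fit_relaxation(mean_series, value = "width")
  tail_tbl <- dplyr::filter(mean_series,
                            .data$time >= max(.data$time) * 0.5)
  tibble(
    n_beads = n_beads,
    length = if (fitL$converged && fitL$identifiable) fitL$plateau
             else mean(tail_tbl$length),
    width = if (fitw$converged && fitw$identifiable) fitw$plateau
            else mean(tail_tbl$width),
    tau = if (fitL$converged && fitL$identifiable) fitL$tau else NA_real_
  )
}

# documented default run horizon (reduced time): compaction from a coil
# start slows with chain length
default_horizon <- function(n_beads) {
  round(2500 * (n_beads / 250)^0.3)
}

#' Equilibrium dimensions across chain lengths
#'
#' The unconstrained-chain experiment: for every chain length N, draws
#' replicate ensembles of independent equilibrium conformations
#' ([equilibrium_ensemble()]), records mean length, width and roundness,
#' and fits the Flory scaling exponent of mean size versus N. Defaults are
#' a desk-scale sweep; ten replicates of larger sweeps reproduce the full
#' study conditions.
#'
#' @param n_sweep chain lengths N.
#' @param n_reps replicates per N.
#' @param n_conformations independent conformations per replicate.
#' @param seed integer seed.
#' @return list of class `equilibrium_experiment`: `$table` (per-N means
#'   with s.d. across replicates), `$replicates`, `$scaling_length` and
#'   `$scaling_width` (`power_law_fit`s of size vs N), `$mean_roundness`.
#' @export
experiment_equilibrium <- function(n_sweep = c(100, 250, 500, 1000),
                                   n_reps = 3, n_conformations = 30,
                                   seed = 1) {
  reps <- purrr::map_dfr(n_sweep, function(N) {
    purrr::map_dfr(seq_len(n_reps), function(r) {
      ens <- equilibrium_ensemble(engine_params(N), n_conformations,
                                  seed = derive_seed(seed, 17 * N + r))
      tibble(n_beads = N, replicate = r,
             length = mean(ens$length), width = mean(ens$width),
             depth = mean(ens$depth), roundness = mean(ens$roundness))
    })
  })
  table <- reps |>
    dplyr::group_by(.data$n_beads) |>
    dplyr::summarise(
      dplyr::across(c("length", "width", "depth", "roundness"),
                    list(mean = mean, sd = sd),
                    .names = "{.fn}_{.col}"),
      .groups = "drop")
  means <- dplyr::rename(table, length = "mean_length",
                         width = "mean_width")
  # scaling fits need >= 3 chain lengths
  structure(
    list(table = table, replicates = reps,
         scaling_length = if (length(n_sweep) >= 3)
           fit_scaling_exponent(means),
         scaling_width = if (length(n_sweep) >= 3)
           fit_scaling_exponent(means, size = "width"),
         mean_roundness = mean(reps$roundness)),
    class = "equilibrium_experiment"
  )
}

#' @export
print.equilibrium_experiment <- function(x, ...) {
  cat("<equilibrium_experiment>", nrow(x$table), "chain lengths | nu =",
      if (is.null(x$scaling_length)) "n/a"
      else signif(x$scaling_length$exponent, 3),
      "| mean roundness =", signif(x$mean_roundness, 3), "\n")
  invisible(x)
}

#' Loop-capture steady-state dimensions across chain lengths
#'
#' Runs loop-capture simulations to steady state for each N, summarises
#' the last-half-of-run frames per replicate, and reports per-N
#' steady-state dimensions, the pooled mean roundness, the steady-state
#' length-to-width power law across N, and the size-scaling exponent.
#'
#' Starts are pivot-equilibrated (unstretched) coils; compaction toward
#' steady state is part of each run, and the per-N steady-state length
#' and width are extrapolated as relaxation-fit plateaus of the
#' replicate-mean decay, so chains whose compaction outlives the run
#' horizon (large N) are still estimated honestly rather than read off a
#' drifting tail.
#'
#' @param n_sweep chain lengths N.
#' @param n_reps replicates per N.
#' @param capture a [capture_params()].
#' @param t_max named or unnamed vector of run durations per N (reduced
#'   time); defaults to [default_horizon] of each N.
#' @param seed integer seed.
#' @return list of class `loop_capture_experiment`: `$table` (per-N
#'   tail-frame summaries), `$replicates`, `$plateaus` (per-N
#'   relaxation-fit steady-state length/width and tau), `$shapes` (all
#'   series), `$length_width_fit` (`power_law_fit` across the per-N
#'   plateaus), `$scaling_length`, `$mean_roundness`.
#' @export
experiment_loop_capture_steady <- function(n_sweep = c(250, 500, 1000),
                                           n_reps = 3,
                                           capture = capture_params(),
                                           t_max = NULL, seed = 1) {
  if (is.null(t_max)) t_max <- default_horizon(n_sweep)
  t_max <- rep_len(t_max, length(n_sweep))
  runs <- purrr::map2_dfr(n_sweep, t_max, function(N, tm) {
    params <- engine_params(N)
    n_steps <- ceiling(tm / params$dt)
    sample_every <- max(1L, floor(n_steps / 200))
    purrr::map_dfr(seq_len(n_reps), function(r) {
      tr <- run_loop_capture(params, capture, n_steps = n_steps,
                             sample_every = sample_every,
                             seed = derive_seed(seed, 23 * N + r))
      dplyr::mutate(tr$shapes, n_beads = N, replicate = r)
    })
  })
  reps <- runs |>
    dplyr::group_by(.data$n_beads, .data$replicate) |>
    dplyr::group_modify(function(d, key) {
      tr <- list(shapes = d, params = list(n_beads = key$n_beads))
      steady_state_summary(tr)[, -1]
    }) |>
    dplyr::ungroup()
  # steady-state values as exponential-relaxation plateaus of the
  # replicate-mean decay from the coil start (tail mean as fallback when
  # the decay is unidentifiable, e.g. the run starts at steady state)
  plateaus <- runs |>
    dplyr::group_by(.data$n_beads, .data$time) |>
    dplyr::summarise(length = mean(.data$length),
                     width = mean(.data$width), .groups = "drop") |>
    dplyr::group_by(.data$n_beads) |>
    dplyr::group_modify(function(d, key) {
      fL <- fit_relaxation(d, value = "length")
      fw <- fit_relaxation(d, value = "width")
      tail_tbl <- dplyr::filter(d, .data$time >= max(.data$time) * 0.5)
      tibble(
        length = if (fL$converged && fL$identifiable) fL$plateau
                 else mean(tail_tbl$length),
        width = if (fw$converged && fw$identifiable) fw$plateau
                else mean(tail_tbl$width),
        tau = if (fL$converged && fL$identifiable) fL$tau else NA_real_)
    }) |>
    dplyr::ungroup()
  table <- reps |>
    dplyr::group_by(.data$n_beads) |>
    dplyr::summarise(
      dplyr::across(c("length", "width", "roundness", "n_bonds"),
                    list(mean = mean, sd = sd), .names = "{.fn}_{.col}"),
      sem_roundness_pooled = sd(.data$roundness) / sqrt(dplyr::n()),
      .groups = "drop")
  # cross-N fits need >= 3 chain lengths
  structure(
    list(table = table, replicates = reps, plateaus = plateaus,
         shapes = runs,
         length_width_fit = if (length(n_sweep) >= 3)
           fit_power_law(plateaus),
         scaling_length = if (length(n_sweep) >= 3)
           fit_scaling_exponent(plateaus),
         mean_roundness = mean(reps$roundness)),
    class = "loop_capture_experiment"
  )
}

#' @export
print.loop_capture_experiment <- function(x, ...) {
  cat("<loop_capture_experiment>", nrow(x$table), "chain lengths |",
      "steady alpha =", if (is.null(x$length_width_fit)) "n/a"
      else signif(x$length_width_fit$exponent, 3),
      "| mean roundness =", signif(x$mean_roundness, 3), "\n")
  invisible(x)
}

#' Elongated-release timecourse experiment
#'
#' The shape-relaxation experiment: chains start from an elongated
#' ellipsoidal conformation at 4x their loop-capture steady-state length
#' and 1x steady-state width (from [steady_state_lookup()]), are released
#' into loop-capture dynamics, and their shape is followed over time.
#' Returns per-time replicate means with s.e.m., per-N exponential
#' relaxation fits of length (tau(N)), and the power-law exponent series
#' alpha(t) across N.
#'
#' @param n_sweep chain lengths N (all must be cached in the lookup).
#' @param n_reps replicates per N.
#' @param capture a [capture_params()].
#' @param t_max run duration, reduced time; a single value shared by all
#'   chain lengths so the sampled time grid is identical across N (the
#'   cross-N power-law fit at each time point requires aligned times);
#'   defaults to [default_horizon] of the largest N.
#' @param n_samples shape samples per run.
#' @param L0_factor,w0_factor multipliers on the steady-state dimensions
#'   for the elongated start.
#' @param seed integer seed.
#' @return list of class `timecourse_experiment`: `$shapes` (all replicate
#'   series), `$means` (per time x N means with s.e.m.), `$relaxation`
#'   (per-N tau table), `$alpha_series` (an `exponent_series`, when >= 3
#'   chain lengths are present).
#' @export
experiment_timecourse <- function(n_sweep = c(250, 500, 1000), n_reps = 3,
                                  capture = capture_params(),
                                  t_max = NULL, n_samples = 60,
                                  L0_factor = 4, w0_factor = 1, seed = 1) {
  lookup <- steady_state_lookup(n_sweep)
  if (is.null(t_max)) t_max <- default_horizon(max(n_sweep))
  if (length(t_max) != 1) {
    stop("t_max must be a single horizon shared by all chain lengths")
  }
  shapes <- purrr::map_dfr(n_sweep, function(N) {
    params <- engine_params(N)
    ss <- dplyr::filter(lookup, .data$n_beads == N)
    n_steps <- ceiling(t_max / params$dt)
    sample_every <- max(1L, floor(n_steps / n_samples))
    purrr::map_dfr(seq_len(n_reps), function(r) {
      init <- init_elongated(N, L0 = L0_factor * ss$length,
                             w0 = w0_factor * ss$width,
                             seed = derive_seed(seed, 31 * N + r))
      tr <- run_loop_capture(params, capture, init = init,
                             n_steps = n_steps,
                             sample_every = sample_every,
                             seed = derive_seed(seed, 31 * N + r + 5000))
      dplyr::mutate(tr$shapes, n_beads = N, replicate = r)
    })
  })
  means <- shapes |>
    dplyr::group_by(.data$n_beads, .data$time) |>
    dplyr::summarise(
      sem_length = sd(.data$length) / sqrt(dplyr::n()),
      sem_width = sd(.data$width) / sqrt(dplyr::n()),
      length = mean(.data$length), width = mean(.data$width),
      roundness = mean(.data$roundness), .groups = "drop")
  relaxation <- means |>
    dplyr::group_by(.data$n_beads) |>
    dplyr::group_modify(function(d, key) {
      glance(fit_relaxation(d, value = "length"))
    }) |>
    dplyr::ungroup()
  alpha_series <- if (length(n_sweep) >= 3) {
    exponent_time_series(shapes)
  } else NULL
  structure(
    list(shapes = shapes, means = means, relaxation = relaxation,
         alpha_series = alpha_series),
    class = "timecourse_experiment"
  )
}

#' @export
print.timecourse_experiment <- function(x, ...) {
  cat("<timecourse_experiment>",
      length(unique(x$shapes$n_beads)), "chain lengths | tau:",
      paste(signif(x$relaxation$tau, 3), collapse = ", "), "\n")
  invisible(x)
}

#' Reduced-time to minutes calibration
#'
#' The dynamics-step to wall-clock mapping is not physically determined by
#' the coarse-grained model; it is calibrated so that the N = 250
#' loop-capture chain relaxes in about one minute, anchoring the
#' simulated timecourse to the observed mitotic one. A single constant —
#' clearly a calibration, not a measured quantity — converts reduced time
#' to minutes.
#'
#' @param time reduced time value(s).
#' @param tau_250_minutes wall-clock relaxation time assigned to the
#'   N = 250 chain, minutes.
#' @return time in minutes.
#' @export
reduced_time_to_minutes <- function(time, tau_250_minutes = 1) {
  tau250 <- steady_state_lookup(250)$tau
  time * tau_250_minutes / tau250
}
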