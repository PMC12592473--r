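# Trajectory and result output: XYZ frames, shape CSV, metadata JSON.

#' Write trajectory frames as XYZ
#'
#' One XYZ block per stored frame; the comment line carries the sample
#' time. Requires the trajectory to have been run with
#' `store_frames = TRUE`.
#'
#' @param traj a `chain_trajectory` with frames.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_trajectory_xyz <- function(traj, path) {
  if (is.null(traj$frames)) {
    stop("trajectory holds no frames; rerun with store_frames = TRUE")
  }
  dims <- dim(traj$frames)
  n <- dims[1]
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_len(dims[3])) {
    writeLines(as.character(n), con)
    writeLines(sprintf("t= %.8g", traj$shapes$time[f]), con)
    m <- traj$frames[, , f]
    writeLines(sprintf("C %.8g %.8g %.8g", m[, 1], m[, 2], m[, 3]), con)
  }
  invisible(path)
}

#' Read an XYZ trajectory
#'
#' @param path XYZ file written by [write_trajectory_xyz()].
#' @return list with `frames` (list of N x 3 matrices) and `times`.
#' @export
read_trajectory_xyz <- function(path) {
  lines <- readLines(path)
  frames <- list(); times <- numeric(0)
  i <- 1
  while (i <= length(lines)) {
    n <- as.integer(lines[i])
    times <- c(times, as.numeric(sub("^t=\\s*", "", lines[i + 1])))
    block <- lines[(i + 2):(i + 1 + n)]
    coords <- do.call(rbind, lapply(strsplit(block, "\\s+"), function(p) {
      as.numeric(p[2:4])
    }))
    frames[[length(frames) + 1]] <- coords
    i <- i + 2 + n
  }
  list(frames = frames, times = times)
}

#' Write run metadata sidecar
#'
#' Full engine and capture parameters plus the seed, as JSON, so any run
#' can be reproduced bit-identically.
#'
#' @param traj a `chain_trajectory`.
#' @param path output JSON file.
#' @return the path, invisibly.
#' @export
write_run_metadata <- function(traj, path) {
  meta <- list(
    engine = unclass(traj$params),
    capture = if (!is.null(traj$capture)) unclass(traj$capture),
    seed = traj$seed,
    n_samples = nrow(traj$shapes),
    t_final = max(traj$shapes$time)
  )
  jsonlite::write_json(meta, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Write a shape time series as CSV
#'
#' Columns time, length, width, depth, roundness, n_bonds.
#'
#' @param traj a `chain_trajectory`.
#' @param path output CSV file.
#' @return the path, invisibly.
#' @export
write_shape_csv <- function(traj, path) {
  write.csv(traj$shapes, path, row.names = FALSE)
  invisible(path)
}
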