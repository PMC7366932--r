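# Plain-text interchange: trajectory, frame/sweep labels, events, ground
# truth and session-result CSVs.

#' Read / write a trajectory CSV (\code{time_s,x_cm,y_cm})
#'
#' @param path CSV path.
#' @param fps Frame rate override; inferred from timestamps when NULL.
#' @return \code{read_trajectory_csv} returns a \code{\link{trajectory}}.
#' @export
read_trajectory_csv <- function(path, fps = NULL) {
  d <- utils::read.csv(path)
  trajectory(d$time_s, d$x_cm, d$y_cm, fps = fps)
}

#' @rdname read_trajectory_csv
#' @param traj A \code{\link{trajectory}}.
#' @export
write_trajectory_csv <- function(traj, path) {
  utils::write.csv(as.data.frame(traj)[, c("time_s", "x_cm", "y_cm")], path,
                   row.names = FALSE)
  invisible(path)
}

#' Write staging outputs (frame states and sweep labels) as CSV
#'
#' @param staging A \code{\link{stage_trajectory}} result.
#' @param dir Output directory.
#' @return The directory, invisibly.
#' @export
write_staging_csv <- function(staging, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(staging$frames[, c("time_s", "state", "speed_cm_s")],
                   file.path(dir, "frame_states.csv"), row.names = FALSE)
  utils::write.csv(staging$sweeps, file.path(dir, "sweep_labels.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' Write / read detected events as CSV
#'
#' @param events An \code{\link{swd_events}} data frame.
#' @param path CSV path.
#' @export
write_events_csv <- function(events, path) {
  utils::write.csv(as.data.frame(events), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events_csv
#' @export
read_events_csv <- function(path) {
  out <- utils::read.csv(path)
  class(out) <- c("swd_events", "data.frame")
  out
}

#' Write a sweep table (summed power + artifact flags) as CSV
#'
#' @param sweeps A \code{\link{sweep_set}}.
#' @param path CSV path.
#' @export
write_sweeps_csv <- function(sweeps, path) {
  utils::write.csv(as.data.frame(sweeps)[, c("sweep_index",
                                             "summed_power_mv2hz",
                                             "artifact")],
                   path, row.names = FALSE)
  invisible(path)
}

#' Write the ground truth of a synthetic session as CSV
#'
#' Produces \code{true_events.csv} (\code{start_s,end_s,n_cycles,state})
#' and \code{artifact_sweeps.csv} (\code{sweep_index,artifact}).
#'
#' @param session An \code{\link{simulate_session}} result.
#' @param dir Output directory.
#' @export
write_ground_truth_csv <- function(session, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(session$truth$events, file.path(dir, "true_events.csv"),
                   row.names = FALSE)
  n_sweeps <- floor(eeg_duration_s(session$eeg) / 10)
  art <- data.frame(sweep_index = seq_len(n_sweeps) - 1L)
  art$artifact <- art$sweep_index %in% session$truth$artifact_sweeps
  utils::write.csv(art, file.path(dir, "artifact_sweeps.csv"),
                   row.names = FALSE)
  invisible(dir)
}
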