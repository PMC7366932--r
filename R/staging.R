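# Rule-based behavioral staging from the cleaned trajectory: frame-level
# movement/immobility classification by a speed threshold, removal of
# isolated movement frames, the 30-s sleep-onset rule, and 10-s sweep
# assignment by the 60% dominance rule.

FRAME_STATES <- c("movement", "immobility", "sleep")
SWEEP_STATES <- c("sleep", "waking_immobility", "movement", "mixed")

#' Classify frames as movement or immobility by instant speed
#'
#' A frame with instant speed higher than the threshold (strict) is
#' movement, otherwise immobility.
#'
#' @param speeds Per-frame instant speeds (cm/s).
#' @param speed_thresh_cm_s Threshold, default 0.5 cm/s.
#' @return Character vector of \code{"movement"} / \code{"immobility"}.
#' @export
classify_frames <- function(speeds, speed_thresh_cm_s = 0.5) {
  ifelse(speeds > speed_thresh_cm_s, "movement", "immobility")
}

#' Relabel isolated single movement frames
#'
#' If a single frame of movement is preceded and followed by at least
#' \code{n_flank} frames of immobility, that frame is relabeled immobility.
#' Runs of two or more movement frames are untouched, as are movement frames
#' too close to the recording edges to have full flanks.
#'
#' @param states Frame-state labels (movement/immobility).
#' @param n_flank Required immobility frames on each side, default 10.
#' @return Relabeled frame states.
#' @export
despike_single_movement <- function(states, n_flank = 10L) {
  r <- rle(states)
  k <- length(r$lengths)
  if (k < 3L) return(states)
  for (j in 2:(k - 1L)) {
    if (r$values[j] == "movement" && r$lengths[j] == 1L &&
        r$values[j - 1L] == "immobility" && r$lengths[j - 1L] >= n_flank &&
        r$values[j + 1L] == "immobility" && r$lengths[j + 1L] >= n_flank) {
      r$values[j] <- "immobility"
    }
  }
  inverse.rle(r)
}

#' Apply the sleep-onset rule
#'
#' Within any contiguous immobility period longer than \code{latency_s}
#' (strict), all frames from \code{latency_s} after the period onset until
#' its end are relabeled sleep; shorter periods are untouched.
#'
#' @param states Frame-state labels after despiking.
#' @param fps Video frame rate (frames/s).
#' @param latency_s Sleep-onset latency, default 30 s.
#' @return Frame states with sleep frames assigned.
#' @export
apply_sleep_rule <- function(states, fps, latency_s = 30) {
  r <- rle(states)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  out <- states
  for (j in seq_along(r$lengths)) {
    if (r$values[j] != "immobility") next
    dur <- r$lengths[j] / fps
    if (dur > latency_s) {
      offset <- (seq_len(r$lengths[j]) - 1L) / fps
      idx <- starts[j]:ends[j]
      out[idx[offset >= latency_s]] <- "sleep"
    }
  }
  out
}

#' Build per-frame state labels from a cleaned trajectory
#'
#' Convenience wrapper running speed computation, the speed-threshold
#' classifier, single-frame despiking and the sleep rule in order.
#'
#' @param traj Cleaned \code{\link{trajectory}}.
#' @param speed_thresh_cm_s Movement threshold (cm/s), default 0.5.
#' @param sleep_latency_s Sleep-onset latency (s), default 30.
#' @param despike_flank Immobility frames required around an isolated
#'   movement frame, default 10.
#' @return Data frame of class \code{"frame_states"}: \code{time_s},
#'   \code{speed_cm_s}, \code{state}.
#' @export
frame_states <- function(traj, speed_thresh_cm_s = 0.5, sleep_latency_s = 30,
                         despike_flank = 10L) {
  sp <- instant_speed(traj)
  st <- classify_frames(sp, speed_thresh_cm_s)
  st <- despike_single_movement(st, despike_flank)
  st <- apply_sleep_rule(st, traj_fps(traj), sleep_latency_s)
  out <- data.frame(time_s = traj$time_s, speed_cm_s = sp, state = st)
  class(out) <- c("frame_states", "data.frame")
  out
}

#' Assign 10-s sweeps to behavioral states by the dominance rule
#'
#' The session is cut into consecutive half-open sweeps \code{[start,
#' start + sweep_s)} aligned to time 0; a trailing partial sweep is dropped.
#' Within each sweep, if any single frame state exceeds the dominance
#' fraction (strictly more than 60\% of frames by default) the sweep takes
#' that state (\code{immobility} maps to \code{waking_immobility});
#' otherwise the sweep is a \code{mixed}-state transition epoch.
#'
#' @param frames A \code{\link{frame_states}} data frame covering the
#'   session.
#' @param sweep_s Sweep length in seconds, default 10.
#' @param dominance Dominance fraction, default 0.6 (strict).
#' @return Data frame of class \code{"sweep_labels"}: \code{sweep_index}
#'   (0-based), \code{start_s}, \code{state}.
#' @export
assign_sweeps <- function(frames, sweep_s = 10, dominance = 0.6) {
  tmax <- max(frames$time_s) + 1e-9
  n_sweeps <- floor((tmax + stats::median(diff(frames$time_s))) / sweep_s)
  if (n_sweeps < 1L) stop("session shorter than one sweep")
  sweep_idx <- floor(frames$time_s / sweep_s)
  states <- character(n_sweeps)
  for (s in seq_len(n_sweeps) - 1L) {
    in_sweep <- frames$state[sweep_idx == s]
    if (length(in_sweep) == 0L) stop("empty sweep at index ", s)
    frac <- table(factor(in_sweep, levels = FRAME_STATES)) / length(in_sweep)
    top <- which.max(frac)
    if (frac[top] > dominance + .boundary_eps) {
      st <- names(frac)[top]
      states[s + 1L] <- if (st == "immobility") "waking_immobility" else st
    } else {
      states[s + 1L] <- "mixed"
    }
  }
  out <- data.frame(sweep_index = seq_len(n_sweeps) - 1L,
                    start_s = (seq_len(n_sweeps) - 1L) * sweep_s,
                    state = states)
  attr(out, "sweep_s") <- sweep_s
  class(out) <- c("sweep_labels", "data.frame")
  out
}

#' Stage a raw trajectory end to end
#'
#' Runs the fixed staging pipeline: sharp-turn correction, jump correction,
#' smoothing, instant speed, movement/immobility classification, despiking,
#' the sleep rule, and 10-s sweep assignment.
#'
#' @param traj Raw \code{\link{trajectory}}.
#' @param speed_thresh_cm_s,sleep_latency_s,dominance,sweep_s Staging
#'   parameters (defaults 0.5 cm/s, 30 s, 0.6, 10 s).
#' @param smooth Apply penalized-least-squares smoothing (default TRUE).
#' @return List of class \code{"staging"} with elements \code{trajectory}
#'   (cleaned), \code{frames}, \code{sweeps}.
#' @export
stage_trajectory <- function(traj, speed_thresh_cm_s = 0.5,
                             sleep_latency_s = 30, dominance = 0.6,
                             sweep_s = 10, smooth = TRUE) {
  cleaned <- correct_jumps(correct_sharp_turns(traj))
  if (smooth) cleaned <- smooth_trajectory(cleaned)
  fr <- frame_states(cleaned, speed_thresh_cm_s, sleep_latency_s)
  sw <- assign_sweeps(fr, sweep_s, dominance)
  structure(list(trajectory = cleaned, frames = fr, sweeps = sw),
            class = "staging")
}

#' @export
print.staging <- function(x, ...) {
  tb <- table(factor(x$sweeps$state, levels = SWEEP_STATES))
  cat("Behavioral staging:", nrow(x$frames), "frames,",
      nrow(x$sweeps), "sweeps\n")
  cat("  sweeps by state:",
      paste(names(tb), tb, sep = "=", collapse = ", "), "\n")
  invisible(x)
}
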