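# Video-tracking trajectories and the three cleaning steps applied before
# behavioral staging: sharp-turn correction, star-shaped/non-mouse jump
# correction, and penalized-least-squares smoothing.

#' Construct a trajectory object
#'
#' A trajectory is a data frame of timestamped 2-D arena coordinates at video
#' rate (~20 fps), the raw substrate of behavioral staging.
#'
#' @param time_s Strictly increasing timestamps in seconds.
#' @param x_cm,y_cm Arena coordinates in cm.
#' @param fps Frame rate; inferred from the median timestamp spacing when
#'   omitted.
#' @return A data frame of class \code{"trajectory"} with attribute
#'   \code{fps}.
#' @export
trajectory <- function(time_s, x_cm, y_cm, fps = NULL) {
  if (length(time_s) != length(x_cm) || length(x_cm) != length(y_cm)) {
    stop("time_s, x_cm and y_cm must have equal length")
  }
  if (length(time_s) > 1 && any(diff(time_s) <= 0)) {
    stop("time_s must be strictly increasing")
  }
  if (is.null(fps)) {
    fps <- if (length(time_s) > 1) 1 / stats::median(diff(time_s)) else NA_real_
  }
  if (!is.na(fps) && fps <= 0) stop("fps must be positive")
  out <- data.frame(time_s = time_s, x_cm = x_cm, y_cm = y_cm)
  attr(out, "fps") <- fps
  class(out) <- c("trajectory", "data.frame")
  out
}

traj_fps <- function(traj) attr(traj, "fps")

# Signed turning angle (degrees, in (-180, 180]) between successive
# displacement vectors v1 = p2 - p1 and v2 = p3 - p2.
turning_angle_deg <- function(v1x, v1y, v2x, v2y) {
  atan2(v1x * v2y - v1y * v2x, v1x * v2x + v1y * v2y) * 180 / pi
}

# Strict inequalities at printed boundaries are evaluated with a hair of
# numerical slack so that exactly-constructed boundary geometry is not
# flipped by floating-point rounding.
.boundary_eps <- 1e-9

#' Correct unrealistically sharp turns
#'
#' Scanning forward, wherever the turning angle between consecutive
#' displacement vectors is bigger than +135 degrees or smaller than -135
#' degrees (a sharp turning back), the middle point is replaced by the mean
#' of itself and the following point. The scan operates on the working copy,
#' so a replacement is visible to the next comparison.
#'
#' @param traj A \code{\link{trajectory}}.
#' @param max_turn_deg Turn-angle threshold, default 135 degrees (strict).
#' @return Corrected trajectory.
#' @export
correct_sharp_turns <- function(traj, max_turn_deg = 135) {
  n <- nrow(traj)
  if (n < 3L) {
    warning("fewer than 3 frames; trajectory returned unchanged")
    return(traj)
  }
  x <- traj$x_cm; y <- traj$y_cm
  for (i in 2:(n - 1L)) {
    v1x <- x[i] - x[i - 1L]; v1y <- y[i] - y[i - 1L]
    v2x <- x[i + 1L] - x[i]; v2y <- y[i + 1L] - y[i]
    if ((v1x == 0 && v1y == 0) || (v2x == 0 && v2y == 0)) next
    ang <- turning_angle_deg(v1x, v1y, v2x, v2y)
    if (abs(ang) > max_turn_deg + .boundary_eps) {
      x[i] <- (x[i] + x[i + 1L]) / 2
      y[i] <- (y[i] + y[i + 1L]) / 2
    }
  }
  trajectory(traj$time_s, x, y, fps = traj_fps(traj))
}

#' Correct star-shaped jumps and non-mouse object tracking
#'
#' From each accepted point, the distances to the subsequent four points are
#' compared and the nearest of the four is taken as the next realistic
#' location; correction then continues from that point. Bypassed (spurious)
#' intermediate points are replaced by linear interpolation between the two
#' accepted neighbours, preserving the frame count that fps-based staging
#' requires. Near the end of the recording the lookahead window shrinks.
#'
#' @param traj A \code{\link{trajectory}}.
#' @param lookahead Number of subsequent points compared (default 4).
#' @return Corrected trajectory.
#' @export
correct_jumps <- function(traj, lookahead = 4L) {
  n <- nrow(traj)
  if (n < 2L) return(traj)
  x <- traj$x_cm; y <- traj$y_cm
  i <- 1L
  while (i < n) {
    k <- min(lookahead, n - i)
    idx <- i + seq_len(k)
    d2 <- (x[idx] - x[i])^2 + (y[idx] - y[i])^2
    j <- idx[which.min(d2)]
    if (j > i + 1L) {
      skipped <- (i + 1L):(j - 1L)
      frac <- (skipped - i) / (j - i)
      x[skipped] <- x[i] + frac * (x[j] - x[i])
      y[skipped] <- y[i] + frac * (y[j] - y[i])
    }
    i <- j
  }
  trajectory(traj$time_s, x, y, fps = traj_fps(traj))
}

#' Smooth a trajectory by penalized least squares
#'
#' x and y are smoothed independently with a cubic smoothing spline whose
#' penalty is selected by generalized cross-validation
#' (\code{stats::smooth.spline}) -- the same discretized penalized
#' least-squares / GCV construction used by common trajectory-smoothing
#' routines. Constant or very short trajectories are returned unchanged.
#'
#' @param traj A \code{\link{trajectory}} (already glitch-corrected).
#' @return Smoothed trajectory.
#' @export
smooth_trajectory <- function(traj) {
  n <- nrow(traj)
  if (n < 4L) return(traj)
  # dense knots (one per ~4 frames) so the penalty, not a sparse basis,
  # does the smoothing; the default knot budget smears sub-second
  # stop/start transitions that the staging rules depend on
  nk <- min(n - 4L, max(10L, ceiling(n / 4)))
  smooth1 <- function(v) {
    if (stats::sd(v) == 0) return(v)
    fit <- tryCatch(
      stats::smooth.spline(traj$time_s, v, cv = FALSE, keep.data = FALSE,
                           nknots = nk),
      error = function(e) NULL)
    if (is.null(fit)) return(v)
    stats::predict(fit, traj$time_s)$y
  }
  trajectory(traj$time_s, smooth1(traj$x_cm), smooth1(traj$y_cm),
             fps = traj_fps(traj))
}

#' Instantaneous speed per video frame
#'
#' Speed between every two neighbouring locations: Euclidean distance shift
#' divided by the time lapse. The first frame copies the second frame's
#' speed so every frame carries a value.
#'
#' @param traj A \code{\link{trajectory}} with at least 2 frames.
#' @return Numeric vector of speeds (cm/s), one per frame.
#' @export
instant_speed <- function(traj) {
  n <- nrow(traj)
  if (n < 2L) stop("need at least 2 frames to compute speeds")
  dt <- diff(traj$time_s)
  if (any(dt <= 0)) stop("zero or negative time lapse between frames")
  d <- sqrt(diff(traj$x_cm)^2 + diff(traj$y_cm)^2)
  sp <- c(NA_real_, d / dt)
  sp[1L] <- sp[2L]
  sp
}
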