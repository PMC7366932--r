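# Synthetic video-EEG sessions with known ground truth. A session consists
# of (a) a video trajectory following a bout schedule of movement /
# immobility / sleep, with injectable tracking glitches; (b) a continuous
# EEG built from state-dependent background (1/f noise, delta in slow-wave
# sleep, intermittent 12-15 Hz spindle bursts, REM-like theta epochs, flat
# waking activity) with spike-wave discharge trains and broadband artifact
# bursts injected at known times; and (c) the ground truth for all of it.

#' Session generator configuration
#'
#' Defaults emulate a 3-h recording session: video at 20 fps, EEG digitized
#' at 2000 samples/s, a circular arena of radius 9.25 cm (18.5 cm diameter),
#' and a ~9 Hz spike-wave fundamental inside the 7-23 Hz detection band.
#'
#' @param duration_s Session length in seconds, default 10800 (3 h).
#' @param video_fps Video frame rate, default 20.
#' @param eeg_fs EEG sampling rate, default 2000.
#' @param arena_radius_cm Arena radius, default 9.25.
#' @param state_schedule Data frame (or list of pairs) with columns
#'   \code{state} in {movement, immobility, sleep} and \code{duration_s};
#'   durations must sum to \code{duration_s}. Default: a repeating
#'   movement / immobility / sleep bout pattern filling the session.
#' @param swd_rate_per_state Named events/hour rates for sleep,
#'   waking_immobility and mixed states. Defaults c(100, 40, 40): saline
#'   SWD rates in sleep are on the order of 100 per hour, with fewer events
#'   while awake.
#' @param swd_fundamental_hz Spike-wave fundamental, default 9 Hz.
#' @param swd_cycles_range Integer (min, max) cycles per event, default
#'   c(4, 12).
#' @param swd_amplitude_mv Peak discharge amplitude in mV. Default NULL:
#'   the amplitude is calibrated to \code{swd_snr} times the standard
#'   deviation of the session's own raw background trace, keeping the
#'   discharges clearly above background the way real spike-wave trains
#'   stand out in a raw record.
#' @param swd_snr Amplitude-to-background-SD ratio used by the default
#'   calibration, default 3.
#' @param background_levels Named list of per-state component amplitudes
#'   (mV SD); see Details. Pass partial overrides to change single entries.
#' @param glitch_rates Named per-minute rates c(sharp_turn, jump) of
#'   injected tracking glitches, default c(0.5, 0.5).
#' @param artifact_sweep_fraction Fraction of 10-s sweeps receiving a
#'   broadband artifact burst, default 0.02.
#' @param refractory_s Minimum gap between consecutive true events,
#'   default 2.
#' @param include_emg Also synthesize a movement-modulated EMG channel
#'   (never used by the analysis), default FALSE.
#' @param seed Integer RNG seed.
#'
#' @details Background components (all free parameters of the generator,
#' not claims about real recordings): \code{pink} broadband 1/f noise;
#' \code{delta} 1-4 Hz band noise, strong in slow-wave sleep;
#' \code{theta} 6-9 Hz band noise, elevated in REM-like epochs and during
#' movement; \code{spindle} amplitude of intermittent 12-15 Hz bursts in
#' sleep, with \code{spindle_rate_per_min} and \code{rem_fraction}
#' controlling their rate and the REM share of sleep time.
#'
#' @return List of class \code{"session_config"}.
#' @export
session_config <- function(duration_s = 10800, video_fps = 20, eeg_fs = 2000,
                           arena_radius_cm = 9.25, state_schedule = NULL,
                           swd_rate_per_state = c(sleep = 100,
                                                  waking_immobility = 40,
                                                  mixed = 40),
                           swd_fundamental_hz = 9,
                           swd_cycles_range = c(4L, 12L),
                           swd_amplitude_mv = NULL, swd_snr = 3,
                           background_levels = list(),
                           glitch_rates = c(sharp_turn = 0.5, jump = 0.5),
                           artifact_sweep_fraction = 0.02,
                           refractory_s = 2, include_emg = FALSE, seed = 1L) {
  if (duration_s <= 0 || video_fps <= 0 || eeg_fs <= 0) {
    stop("durations and rates must be positive")
  }
  if (swd_fundamental_hz < 7 || swd_fundamental_hz > 23) {
    stop("swd_fundamental_hz must lie inside the 7-23 Hz detection band")
  }
  if (any(swd_rate_per_state < 0) || artifact_sweep_fraction < 0 ||
      any(glitch_rates < 0)) {
    stop("rates must be non-negative")
  }
  if (is.null(state_schedule)) {
    state_schedule <- default_schedule(duration_s)
  }
  state_schedule <- as.data.frame(state_schedule)
  if (!all(state_schedule$state %in% c("movement", "immobility", "sleep"))) {
    stop("schedule states must be movement, immobility or sleep")
  }
  if (abs(sum(state_schedule$duration_s) - duration_s) > 1e-6) {
    stop("state_schedule durations must sum to duration_s")
  }
  bg <- utils::modifyList(list(
    pink = c(movement = 0.10, immobility = 0.10, sleep = 0.12),
    delta = c(movement = 0.03, immobility = 0.05, sleep = 0.15),
    theta = c(movement = 0.03, immobility = 0.02, sleep = 0.02, rem = 0.06),
    spindle = 0.04, spindle_rate_per_min = 2, spindle_dur_s = c(0.5, 0.8),
    rem_fraction = 0.15), background_levels)
  structure(list(
    duration_s = duration_s, video_fps = video_fps, eeg_fs = eeg_fs,
    arena_radius_cm = arena_radius_cm, state_schedule = state_schedule,
    swd_rate_per_state = swd_rate_per_state,
    swd_fundamental_hz = swd_fundamental_hz,
    swd_cycles_range = as.integer(swd_cycles_range),
    swd_amplitude_mv = swd_amplitude_mv, swd_snr = swd_snr,
    background_levels = bg, glitch_rates = glitch_rates,
    artifact_sweep_fraction = artifact_sweep_fraction,
    refractory_s = refractory_s, include_emg = include_emg,
    seed = as.integer(seed)), class = "session_config")
}

#' Default bout schedule
#'
#' A repeating 10-min pattern of movement, brief waking immobility and long
#' sleep bouts (the last entry is truncated so durations sum exactly to the
#' session length).
#'
#' @param duration_s Session length (s).
#' @return Data frame \code{state}, \code{duration_s}.
#' @export
default_schedule <- function(duration_s) {
  block <- data.frame(
    state = c("movement", "immobility", "sleep",
              "movement", "immobility", "sleep"),
    duration_s = c(60, 20, 300, 30, 30, 160))
  reps <- ceiling(duration_s / sum(block$duration_s))
  sched <- block[rep(seq_len(nrow(block)), reps), ]
  cum <- cumsum(sched$duration_s)
  keep <- which(cum - sched$duration_s < duration_s)
  sched <- sched[keep, ]
  excess <- sum(sched$duration_s) - duration_s
  sched$duration_s[nrow(sched)] <- sched$duration_s[nrow(sched)] - excess
  rownames(sched) <- NULL
  sched
}

#' Synthesize one spike-wave discharge waveform
#'
#' Each cycle is a slow sinusoid at the fundamental plus a narrow Gaussian
#' spike (full width at half maximum of one eighth of the fundamental
#' period) centered on the slow-wave maximum, reproducing the sharp
#' spike-riding-a-wave morphology with a countable number of spikes. The
#' waveform peak equals \code{amplitude_mv}.
#'
#' @param fundamental_hz Fundamental frequency (Hz), inside 7-23 Hz.
#' @param n_cycles Number of spike-wave cycles (>= 1).
#' @param amplitude_mv Peak amplitude (mV).
#' @param fs Sampling rate (samples/s).
#' @return Numeric signal of duration \code{n_cycles / fundamental_hz}.
#' @export
synth_swd_waveform <- function(fundamental_hz = 9, n_cycles = 6,
                               amplitude_mv = 0.3, fs = 2000) {
  stopifnot(n_cycles >= 1, fundamental_hz >= 7, fundamental_hz <= 23)
  period <- 1 / fundamental_hz
  n <- round(n_cycles * period * fs)
  t <- (seq_len(n) - 1) / fs
  slow <- -cos(2 * pi * fundamental_hz * t)      # maxima at cycle centers
  centers <- (seq_len(n_cycles) - 0.5) * period
  sigma <- (period / 8) / (2 * sqrt(2 * log(2))) # FWHM = period / 8
  spikes <- rowSums(vapply(centers, function(c0) exp(-(t - c0)^2 / (2 * sigma^2)),
                           numeric(n)))
  w <- 0.45 * slow + 0.55 * spikes
  amplitude_mv * w / max(w)
}

# sample() without the length-1 surprise
safe_sample <- function(x, size) x[sample.int(length(x), size)]

# Band-limited unit-variance Gaussian noise.
band_noise <- function(n, fs, low, high, stop_low = low / 2,
                       stop_high = high * 1.5) {
  x <- fft_bandpass(stats::rnorm(n), fs, low, high, stop_low, stop_high)
  x / stats::sd(x)
}

# Unit-variance 1/f (pink) noise via spectral shaping.
pink_noise <- function(n, fs) {
  m <- fft_length(n)
  f <- (seq_len(m) - 1) * fs / m
  f <- pmin(f, fs - f)
  shape <- ifelse(f < 1, 0, 1 / sqrt(f))
  x <- Re(stats::fft(stats::fft(stats::rnorm(m)) * shape, inverse = TRUE)) / m
  x <- x[seq_len(n)]
  x / stats::sd(x)
}

# Ground-truth frame states implied by a bout schedule: scheduled movement
# frames are movement; within each contiguous non-movement run, the first
# 30 s are immobility and the remainder sleep (the staging rule's own
# semantics, so truth and a perfect stager agree).
schedule_frame_states <- function(schedule, fps, n_frames,
                                  sleep_latency_s = 30) {
  per_bout <- round(schedule$duration_s * fps)
  moving <- rep(schedule$state == "movement", per_bout)
  length(moving) <- n_frames
  moving[is.na(moving)] <- moving[max(which(!is.na(moving)))]
  states <- ifelse(moving, "movement", "immobility")
  apply_sleep_rule(states, fps, sleep_latency_s)
}

#' Synthesize a video trajectory from a bout schedule
#'
#' Movement bouts are a smooth random walk (wandering heading, speeds well
#' above 0.5 cm/s) reflected at the circular arena wall; immobility and
#' sleep bouts jitter around an anchor point far below the movement
#' threshold. Tracking glitches are injected at the configured per-minute
#' rates: sharp turnbacks (turn angle above 135 degrees) and star-shaped
#' jumps (single-frame displacement to one fixed spurious point and back).
#'
#' @param config A \code{\link{session_config}}. The caller is responsible
#'   for seeding the RNG (or use \code{\link{simulate_session}}).
#' @return List: \code{trajectory} (a \code{\link{trajectory}}),
#'   \code{glitches} (list of injected sharp-turn and jump frame indices).
#' @export
synth_trajectory <- function(config) {
  fps <- config$video_fps
  n <- round(config$duration_s * fps)
  sched <- config$state_schedule
  moving <- rep(sched$state == "movement", round(sched$duration_s * fps))
  length(moving) <- n
  moving[is.na(moving)] <- FALSE
  r <- config$arena_radius_cm

  x <- numeric(n); y <- numeric(n)
  x[1] <- r / 3; y[1] <- 0
  heading <- stats::runif(1, 0, 2 * pi)
  speed <- stats::runif(1, 2, 5)
  jitter_sd <- 0.005
  dhead <- stats::rnorm(n, 0, 0.3)
  dspeed <- stats::rnorm(n, 0, 0.4)
  jx <- stats::rnorm(n, 0, jitter_sd)
  jy <- stats::rnorm(n, 0, jitter_sd)
  ax <- x[1]; ay <- y[1]
  wrap_pi <- function(a) atan2(sin(a), cos(a))
  for (i in 2:n) {
    if (moving[i]) {
      heading <- heading + dhead[i]
      rad0 <- sqrt(x[i - 1]^2 + y[i - 1]^2)
      if (rad0 > 0.85 * r) {
        # steer gently toward the center near the wall, so contacts are
        # grazing rather than head-on turnbacks
        inward <- atan2(-y[i - 1], -x[i - 1])
        heading <- heading + 0.3 * wrap_pi(inward - heading)
      }
      speed <- min(8, max(1.5, speed + dspeed[i]))
      x[i] <- x[i - 1] + cos(heading) * speed / fps
      y[i] <- y[i - 1] + sin(heading) * speed / fps
      rad <- sqrt(x[i]^2 + y[i]^2)
      if (rad > r) {            # specular reflection off the wall
        x[i] <- x[i] * (2 * r - rad) / rad
        y[i] <- y[i] * (2 * r - rad) / rad
        phi <- atan2(y[i], x[i])
        heading <- wrap_pi(2 * phi + pi - heading)
      }
    } else {
      if (moving[i - 1] || i == 2) { ax <- x[i - 1]; ay <- y[i - 1] }
      x[i] <- ax + jx[i]
      y[i] <- ay + jy[i]
    }
  }

  minutes <- config$duration_s / 60
  n_turn <- stats::rpois(1, config$glitch_rates[["sharp_turn"]] * minutes)
  n_jump <- stats::rpois(1, config$glitch_rates[["jump"]] * minutes)
  movable <- which(moving & c(FALSE, moving[-n]) & c(moving[-1], FALSE))
  movable <- movable[movable > 1 & movable < n]
  turn_idx <- sort(safe_sample(movable, min(n_turn, length(movable))))
  if (length(turn_idx) > 1L) turn_idx <- turn_idx[c(TRUE, diff(turn_idx) > 2)]
  for (k in turn_idx) {
    # lateral spike of 3x the local step: turn angle ~143 degrees at the
    # spiked vertex only, and a single mean-replacement restores it
    dx <- (x[k + 1] - x[k - 1]) / 2; dy <- (y[k + 1] - y[k - 1]) / 2
    step <- sqrt(dx^2 + dy^2)
    if (step < 1e-6) next
    x[k] <- (x[k - 1] + x[k + 1]) / 2 - 3 * dy
    y[k] <- (y[k - 1] + y[k + 1]) / 2 + 3 * dx
  }
  eligible <- setdiff(2:(n - 1), c(turn_idx - 1, turn_idx, turn_idx + 1))
  jump_idx <- sort(safe_sample(eligible, min(n_jump, length(eligible))))
  if (length(jump_idx) > 1L) jump_idx <- jump_idx[c(TRUE, diff(jump_idx) > 2)]
  spur <- c(r + 3, r + 3)       # one fixed spurious point, outside the arena
  x[jump_idx] <- spur[1]
  y[jump_idx] <- spur[2]

  list(trajectory = trajectory((seq_len(n) - 1) / fps, x, y, fps = fps),
       glitches = list(sharp_turn = turn_idx, jump = jump_idx))
}

#' Synthesize state-dependent background EEG
#'
#' @param states Per-frame behavioral state labels (movement / immobility /
#'   sleep).
#' @param config A \code{\link{session_config}}.
#' @return List: \code{signal} (mV, length duration * eeg_fs), \code{rem}
#'   (logical per-sample REM-epoch flag), \code{spindles} (data frame of
#'   injected spindle intervals, \code{start_s} / \code{end_s}).
#' @export
synth_background <- function(states, config) {
  fs <- config$eeg_fs
  n <- round(config$duration_s * fs)
  frame_of <- pmin(length(states),
                   floor((seq_len(n) - 1) / fs * config$video_fps) + 1L)
  sample_state <- states[frame_of]
  bg <- config$background_levels

  # REM-like epochs: random sub-bouts inside long sleep runs
  rem <- rep(FALSE, n)
  r <- rle(sample_state)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  for (j in seq_along(r$lengths)) {
    if (r$values[j] != "sleep") next
    len_s <- r$lengths[j] / fs
    if (len_s < 120) next
    target <- bg$rem_fraction * len_s
    placed <- 0
    while (placed < target) {
      dur <- stats::runif(1, 30, 60)
      off <- stats::runif(1, 0, max(0.001, len_s - dur))
      a <- starts[j] + round(off * fs)
      b <- min(ends[j], a + round(dur * fs))
      rem[a:b] <- TRUE
      placed <- placed + dur
    }
  }

  gain_of <- function(component) {
    g <- unname(bg[[component]][sample_state])
    if (component == "theta") g[rem] <- bg$theta[["rem"]]
    g
  }
  sig <- pink_noise(n, fs) * gain_of("pink") +
    band_noise(n, fs, 1, 4, 0.5, 6) * gain_of("delta") +
    band_noise(n, fs, 6, 9, 4, 12) * gain_of("theta")

  # intermittent sleep spindles: 12-15 Hz Hann-windowed packets
  spindle_log <- list()
  sleep_runs <- which(r$values == "sleep")
  for (j in sleep_runs) {
    len_min <- r$lengths[j] / fs / 60
    nb <- stats::rpois(1, bg$spindle_rate_per_min * len_min)
    if (nb == 0) next
    used <- numeric(0)
    for (b in seq_len(nb)) {
      dur <- stats::runif(1, bg$spindle_dur_s[1], bg$spindle_dur_s[2])
      f0 <- stats::runif(1, 12, 15)
      # spindles do not superpose: keep at least 2 s between onsets
      off <- NA
      for (try in 1:50) {
        cand <- stats::runif(1, 0, max(0.001, r$lengths[j] / fs - dur))
        if (all(abs(cand - used) > 2)) { off <- cand; break }
      }
      if (is.na(off)) next
      used <- c(used, off)
      a <- starts[j] + round(off * fs)
      m <- round(dur * fs)
      tt <- (seq_len(m) - 1) / fs
      win <- 0.5 * (1 - cos(2 * pi * (seq_len(m) - 1) / (m - 1)))
      idx <- a:(a + m - 1L)
      sig[idx] <- sig[idx] + bg$spindle * win * sin(2 * pi * f0 * tt)
      spindle_log[[length(spindle_log) + 1L]] <-
        c((a - 1L) / fs, (a - 1L + m) / fs)
    }
  }
  spindles <- if (length(spindle_log)) {
    m <- do.call(rbind, spindle_log)
    data.frame(start_s = m[, 1], end_s = m[, 2])
  } else {
    data.frame(start_s = numeric(0), end_s = numeric(0))
  }
  list(signal = sig, rem = rem, spindles = spindles)
}

#' Simulate a complete labeled session
#'
#' Generates trajectory, EEG and ground truth under one seed. True SWD
#' events are placed as a per-state thinned Poisson process (2-s refractory
#' gap) over the artifact-free sweeps of each behavioral state, never inside
#' an artifact sweep or a movement bout; broadband artifact bursts are
#' scaled so the affected sweep's summed 1-100 Hz power exceeds the 2e4
#' mV^2/Hz exclusion threshold at least twofold, while the clean background
#' stays far below it.
#'
#' @param config A \code{\link{session_config}}.
#' @return List of class \code{"swd_session"}: \code{eeg}
#'   (\code{\link{eeg_record}}), \code{trajectory}, \code{truth} (list with
#'   \code{events}, \code{frame_states}, \code{sweep_states},
#'   \code{artifact_sweeps}, \code{glitches}, \code{swd_amplitude_mv},
#'   \code{background_env_mean}).
#' @export
simulate_session <- function(config) {
  stopifnot(inherits(config, "session_config"))
  set.seed(config$seed)
  fs <- config$eeg_fs
  fps <- config$video_fps
  n <- round(config$duration_s * fs)
  n_frames <- round(config$duration_s * fps)
  sweep_s <- 10
  n_sweeps <- floor(config$duration_s / sweep_s)

  tr <- synth_trajectory(config)
  true_frames <- schedule_frame_states(config$state_schedule, fps, n_frames)
  fr_df <- data.frame(time_s = (seq_len(n_frames) - 1) / fps,
                      state = true_frames)
  true_sweeps <- assign_sweeps(fr_df, sweep_s = sweep_s)

  # artifact sweeps first, so no event can land in one
  n_art <- round(config$artifact_sweep_fraction * n_sweeps)
  artifact_sweeps <- sort(safe_sample(seq_len(n_sweeps) - 1L, n_art))

  bgout <- synth_background(true_frames, config)
  sig <- bgout$signal

  # amplitude calibration against the session's own background: peak
  # discharge amplitude = swd_snr x the raw background SD
  slice <- seq_len(min(n, 60L * fs))
  mu_env <- mean(analytic_envelope(fft_bandpass(sig[slice], fs, 7, 23)))
  amp <- config$swd_amplitude_mv
  if (is.null(amp)) amp <- config$swd_snr * stats::sd(sig)

  events <- place_true_events(config, true_frames, true_sweeps,
                              artifact_sweeps, sweep_s)
  for (i in seq_len(nrow(events))) {
    w <- synth_swd_waveform(config$swd_fundamental_hz, events$n_cycles[i],
                            amp, fs)
    a <- round(events$start_s[i] * fs) + 1L
    b <- min(n, a + length(w) - 1L)
    sig[a:b] <- sig[a:b] + w[seq_len(b - a + 1L)]
  }

  # broadband artifact bursts: white noise sized so the sweep's summed
  # 1-100 Hz power reaches ~2.5x the 2e4 exclusion threshold
  art_target <- 2.5 * 2e4
  art_sd <- sqrt(art_target * fs / 200)
  spw <- sweep_s * fs
  for (s in artifact_sweeps) {
    idx <- (s * spw + 1L):min(n, (s + 1L) * spw)
    sig[idx] <- sig[idx] + stats::rnorm(length(idx), 0, art_sd)
  }

  signal <- matrix(sig, ncol = 1L)
  channels <- "right_frontal"
  if (config$include_emg) {
    frame_of <- pmin(n_frames, floor((seq_len(n) - 1) / fs * fps) + 1L)
    move_gain <- ifelse(true_frames[frame_of] == "movement", 0.3, 0.05)
    signal <- cbind(signal, stats::rnorm(n) * move_gain)
    channels <- c(channels, "emg")
  }

  structure(list(
    eeg = eeg_record(signal, fs = fs, channels = channels),
    trajectory = tr$trajectory,
    truth = list(events = events, frame_states = true_frames,
                 sweep_states = true_sweeps,
                 artifact_sweeps = artifact_sweeps,
                 glitches = tr$glitches, spindles = bgout$spindles,
                 swd_amplitude_mv = amp,
                 background_env_mean = mu_env)),
    class = "swd_session")
}

#' @export
print.swd_session <- function(x, ...) {
  cat(sprintf("Synthetic session: %.0f s EEG at %g Hz, %d true SWD event(s), %d artifact sweep(s)\n",
              eeg_duration_s(x$eeg), x$eeg$fs, nrow(x$truth$events),
              length(x$truth$artifact_sweeps)))
  invisible(x)
}

# Place true events for each behavioral state over its artifact-free sweeps.
# Counts are Poisson at the configured per-hour rate over the eligible time;
# each event is resampled (up to 200 tries) until it respects the refractory
# gap, starts on a frame of the matching state (any non-movement frame for
# mixed sweeps) and overlaps no movement frame.
place_true_events <- function(config, true_frames, true_sweeps,
                              artifact_sweeps, sweep_s) {
  fps <- config$video_fps
  fund <- config$swd_fundamental_hz
  cyc <- config$swd_cycles_range
  placed <- data.frame(start_s = numeric(0), end_s = numeric(0),
                       n_cycles = integer(0), state = character(0))
  frame_state_at <- function(t) true_frames[pmin(length(true_frames),
                                                 floor(t * fps) + 1L)]
  for (st in names(config$swd_rate_per_state)) {
    rate <- config$swd_rate_per_state[[st]]
    if (rate <= 0) next
    elig <- true_sweeps$sweep_index[true_sweeps$state == st]
    elig <- setdiff(elig, artifact_sweeps)
    if (length(elig) == 0L) next
    # contiguous eligible sweep ranges
    brk <- c(0L, which(diff(elig) > 1L), length(elig))
    for (g in seq_len(length(brk) - 1L)) {
      run <- elig[(brk[g] + 1L):brk[g + 1L]]
      t0 <- run[1] * sweep_s
      t1 <- (run[length(run)] + 1L) * sweep_s
      lam <- rate * (t1 - t0) / 3600
      n_ev <- stats::rpois(1, lam)
      for (e in seq_len(n_ev)) {
        nc <- sample(cyc[1]:cyc[2], 1L)
        dur <- nc / fund
        for (try in seq_len(200L)) {
          s0 <- stats::runif(1, t0, max(t0, t1 - dur))
          s1 <- s0 + dur
          if (nrow(placed) > 0 &&
              any(s0 < placed$end_s + config$refractory_s &
                  s1 > placed$start_s - config$refractory_s)) next
          fs_on <- frame_state_at(s0)
          ok_on <- if (st == "mixed") fs_on != "movement" else {
            fs_on == (if (st == "waking_immobility") "immobility" else st)
          }
          if (!ok_on) next
          span <- frame_state_at(seq(s0, s1, by = 1 / fps))
          if (any(span == "movement")) next
          placed <- rbind(placed, data.frame(start_s = s0, end_s = s1,
                                             n_cycles = nc, state = st))
          break
        }
      }
    }
  }
  placed <- placed[order(placed$start_s), , drop = FALSE]
  rownames(placed) <- NULL
  placed
}
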