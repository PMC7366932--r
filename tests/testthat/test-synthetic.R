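# The synthetic-session generator: determinism, dimensions, waveform
# morphology, event-placement statistics and glitch injection.

test_that("identical seeds give identical sessions; sizes match the config", {
  cfg <- clean_session_config(duration_s = 120, eeg_fs = 500, seed = 9)
  a <- simulate_session(cfg)
  b <- simulate_session(cfg)
  expect_identical(a$eeg$signal, b$eeg$signal)
  expect_identical(a$trajectory$x_cm, b$trajectory$x_cm)
  expect_identical(a$truth$events, b$truth$events)

  expect_equal(nrow(a$eeg$signal), 120 * 500)
  expect_equal(nrow(a$trajectory), 120 * 20)

  # a 3-h session at 2 kHz would hold 21.6 M samples per channel
  cfg3h <- session_config()
  expect_equal(cfg3h$duration_s * cfg3h$eeg_fs, 21600000)

  # schedule/duration mismatch is a configuration error
  expect_error(session_config(duration_s = 100,
                              state_schedule = data.frame(
                                state = "sleep", duration_s = 90)),
               "sum")
})

test_that("spike-wave waveform has the right duration, peak and spectrum", {
  w <- synth_swd_waveform(9, 9, 0.3, 2000)
  expect_equal(length(w) / 2000, 1, tolerance = 1e-3)     # 9 cycles at 9 Hz
  expect_equal(max(w), 0.3, tolerance = 1e-9)             # peak = amplitude

  w3 <- synth_swd_waveform(9, 3, 0.3, 2000)
  expect_equal(length(w3) / 2000, 1 / 3, tolerance = 2e-3)  # 333 ms

  p <- welch_psd(rep(w, 10), 2000, seg_len = 2000)
  expect_equal(p$freq[which.max(p$power)], 9)

  # generator round-trip: the cycle counter recovers the cycle count
  for (nc in c(4L, 6L, 9L)) {
    f <- swd_bandpass(synth_swd_waveform(9, nc, 0.3, 2000), 2000)
    expect_equal(count_cycles(f), nc)
  }
})

test_that("background is state-dependent and zero when all levels are zero", {
  cfg <- clean_session_config(duration_s = 240, eeg_fs = 500, seed = 3,
                              state_schedule = data.frame(
                                state = c("movement", "immobility", "sleep"),
                                duration_s = c(110, 20, 110)))
  set.seed(3)
  states <- swdscope:::schedule_frame_states(cfg$state_schedule, 20, 240 * 20)
  bg <- synth_background(states, cfg)
  fs <- 500
  sleep_idx <- (130 * fs):(230 * fs)   # inside the sleep bout
  move_idx <- (5 * fs):(105 * fs)
  delta_power <- function(x) {
    p <- welch_psd(x, fs, seg_len = fs)
    sum(p$power[p$freq >= 1 & p$freq <= 4])
  }
  # equal-variance comparison: delta fraction higher in sleep
  sl <- bg$signal[sleep_idx] / sd(bg$signal[sleep_idx])
  mv <- bg$signal[move_idx] / sd(bg$signal[move_idx])
  expect_gt(delta_power(sl), delta_power(mv))

  zero_cfg <- clean_session_config(duration_s = 60, eeg_fs = 500, seed = 1,
                                   background_levels = list(
                                     pink = c(movement = 0, immobility = 0, sleep = 0),
                                     delta = c(movement = 0, immobility = 0, sleep = 0),
                                     theta = c(movement = 0, immobility = 0,
                                               sleep = 0, rem = 0),
                                     spindle = 0))
  set.seed(1)
  st0 <- swdscope:::schedule_frame_states(zero_cfg$state_schedule, 20, 60 * 20)
  bg0 <- synth_background(st0, zero_cfg)
  expect_equal(max(abs(bg0$signal)), 0)
})

test_that("sleep spindle packets are never accepted as SWDs", {
  # default-condition sessions with a generous spindle rate: any accepted
  # event overlapping a spindle packet must be a genuine SWD, i.e. the
  # spindle itself never satisfies the detector + inclusion rule
  overlaps <- function(a0, a1, b0, b1) {
    any(pmin(a1, b1) > pmax(a0, b0))
  }
  for (seed in c(21, 22)) {
    cfg <- clean_session_config(
      duration_s = 600, eeg_fs = 500, seed = seed,
      background_levels = list(spindle_rate_per_min = 6))
    s <- simulate_session(cfg)
    ev <- detect_swd(s$eeg)
    acc <- ev[ev$accepted, , drop = FALSE]
    sp <- s$truth$spindles
    expect_gt(nrow(sp), 10)
    tru <- s$truth$events
    for (i in seq_len(nrow(acc))) {
      if (overlaps(acc$start_s[i], acc$end_s[i], sp$start_s, sp$end_s)) {
        expect_true(overlaps(acc$start_s[i], acc$end_s[i],
                             tru$start_s, tru$end_s))
      }
    }
  }
})

test_that("true event counts follow the configured Poisson rate", {
  # placement oracle over many seeds: 1 h of ground-truth sleep at
  # 100 events/h; the empirical mean count must sit within 3 SE of 100
  cfg <- clean_session_config(
    duration_s = 3630, eeg_fs = 500, seed = 1,
    state_schedule = data.frame(state = c("immobility", "sleep"),
                                duration_s = c(30, 3600)))
  n_frames <- round(cfg$duration_s * cfg$video_fps)
  frames <- swdscope:::schedule_frame_states(cfg$state_schedule,
                                             cfg$video_fps, n_frames)
  fr_df <- data.frame(time_s = (seq_len(n_frames) - 1) / cfg$video_fps,
                      state = frames)
  sweeps <- assign_sweeps(fr_df)
  expect_equal(sum(sweeps$state == "sleep") * 10, 3600)

  n_seeds <- 200
  counts <- vapply(seq_len(n_seeds), function(sd) {
    set.seed(sd)
    ev <- swdscope:::place_true_events(cfg, frames, sweeps, integer(0), 10)
    sum(ev$state == "sleep")
  }, numeric(1))
  se <- sd(counts) / sqrt(n_seeds)
  expect_lt(abs(mean(counts) - 100), 3 * se)
  # and dispersion consistent with Poisson (variance ~ mean)
  expect_gt(var(counts), 0.6 * mean(counts))
})

test_that("true events never overlap artifact sweeps or movement, and are ordered", {
  cfg <- session_config(duration_s = 600, eeg_fs = 500,
                        artifact_sweep_fraction = 0.1, seed = 14)
  s <- simulate_session(cfg)
  ev <- s$truth$events
  expect_true(all(diff(ev$start_s) > 0))
  expect_true(all(ev$end_s > ev$start_s))
  expect_true(all(ev$start_s >= 0 & ev$end_s <= 600))
  # non-overlap with 2-s refractory
  if (nrow(ev) > 1) {
    expect_true(all(ev$start_s[-1] - ev$end_s[-nrow(ev)] >= 2))
  }
  # no event starts in an artifact sweep
  expect_false(any(floor(ev$start_s / 10) %in% s$truth$artifact_sweeps))
  # onset frame state matches the event state (mixed events: non-movement)
  onset_state <- s$truth$frame_states[floor(ev$start_s * 20) + 1]
  for (i in seq_len(nrow(ev))) {
    if (ev$state[i] == "sleep") expect_equal(onset_state[i], "sleep")
    if (ev$state[i] == "waking_immobility") {
      expect_equal(onset_state[i], "immobility")
    }
    if (ev$state[i] == "mixed") expect_true(onset_state[i] != "movement")
  }
})

test_that("ground truth labels sleep from the 31st second of immobility", {
  cfg <- clean_session_config(
    duration_s = 120, eeg_fs = 500, seed = 2,
    state_schedule = data.frame(state = c("movement", "immobility"),
                                duration_s = c(60, 60)))
  s <- simulate_session(cfg)
  fr <- s$truth$frame_states
  fps <- 20
  # frames in (60, 90] s immobility; (90, 120] s sleep
  expect_true(all(fr[(60 * fps + 1):(90 * fps)] == "immobility"))
  expect_true(all(fr[(90 * fps + 1):(120 * fps)] == "sleep"))
})

test_that("injected glitches are corrected as designed", {
  # zero glitch rates: cleaning leaves the trajectory essentially unchanged
  # (immobility jitter may be micro-adjusted) and staging is unaffected
  cfg <- clean_session_config(duration_s = 120, eeg_fs = 500, seed = 4)
  s <- simulate_session(cfg)
  cleaned <- correct_jumps(correct_sharp_turns(s$trajectory))
  shift <- sqrt((cleaned$x_cm - s$trajectory$x_cm)^2 +
                (cleaned$y_cm - s$trajectory$y_cm)^2)
  expect_lt(stats::quantile(shift, 0.99), 0.05)
  raw_sw <- stage_trajectory(s$trajectory, smooth = FALSE)$sweeps$state
  cln_sw <- stage_trajectory(cleaned, smooth = FALSE)$sweeps$state
  expect_equal(cln_sw, raw_sw)

  # sharp-turn glitches: each injected turnback modifies exactly one point
  cfg2 <- session_config(duration_s = 300, eeg_fs = 500, seed = 6,
                         state_schedule = data.frame(state = "movement",
                                                     duration_s = 300),
                         glitch_rates = c(sharp_turn = 2, jump = 0),
                         artifact_sweep_fraction = 0)
  s2 <- simulate_session(cfg2)
  inj <- s2$truth$glitches$sharp_turn
  expect_gt(length(inj), 0)
  out <- correct_sharp_turns(s2$trajectory)
  modified <- which(out$x_cm != s2$trajectory$x_cm |
                    out$y_cm != s2$trajectory$y_cm)
  expect_setequal(modified, inj)

  # jump glitches go to one fixed spurious point and are bypassed
  cfg3 <- session_config(duration_s = 300, eeg_fs = 500, seed = 8,
                         glitch_rates = c(sharp_turn = 0, jump = 2),
                         artifact_sweep_fraction = 0)
  s3 <- simulate_session(cfg3)
  jmp <- s3$truth$glitches$jump
  expect_gt(length(jmp), 0)
  r <- cfg3$arena_radius_cm
  expect_true(all(s3$trajectory$x_cm[jmp] == r + 3))
  fixed <- correct_jumps(s3$trajectory)
  expect_true(all(abs(fixed$x_cm[jmp]) <= r + 1e-6))
  # all non-glitch positions stay inside the arena
  inside <- sqrt(s3$trajectory$x_cm^2 + s3$trajectory$y_cm^2) <= r + 1e-6
  expect_true(all(inside[-jmp]))
})
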