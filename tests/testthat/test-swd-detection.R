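# The SWD detector: threshold-crossing candidates, cycle counting, the
# inclusion rule, rater review, state assignment and state-normalized rates.

test_that("candidate detection finds injected bursts and nothing in quiet signal", {
  fs <- 500
  set.seed(11)
  base <- 0.05 * rnorm(60 * fs)
  filt <- swd_bandpass(base, fs)
  env <- analytic_envelope(filt)
  thr <- mean(env) + 6 * sd(env)
  expect_equal(nrow(detect_candidates(env, fs, k_sd = 6)), 0)

  # inject a 1-s high-envelope burst
  x <- base
  t <- (0:(fs - 1)) / fs
  x[(30 * fs):(31 * fs - 1)] <- x[(30 * fs):(31 * fs - 1)] + sin(2 * pi * 12 * t)
  env2 <- analytic_envelope(swd_bandpass(x, fs))
  cand <- detect_candidates(env2, fs, k_sd = 6)
  expect_equal(nrow(cand), 1)
  covered <- min(cand$end_s, 31) - max(cand$start_s, 30)
  expect_gte(covered, 0.8)

  expect_warning(detect_candidates(rep(1, 1000), fs, 2.5), "constant")
})

test_that("candidate count is non-increasing in the threshold k_sd", {
  cfg <- clean_session_config(duration_s = 300, eeg_fs = 500, seed = 12)
  s <- simulate_session(cfg)
  env <- analytic_envelope(swd_bandpass(eeg_channel(s$eeg), 500))
  ks <- seq(1.8, 3.4, by = 0.4)
  n_cand <- vapply(ks, function(k) nrow(detect_candidates(env, 500, k)),
                   numeric(1))
  expect_true(all(diff(n_cand) <= 0))
})

test_that("cycle counting: generator round trip, noise and degenerate input", {
  fs <- 2000
  expect_equal(count_cycles(swd_bandpass(synth_swd_waveform(9, 6, 0.3, fs), fs)), 6)
  expect_equal(count_cycles(numeric(0)), 0L)
  expect_equal(count_cycles(numeric(500)), 0)
  # the separation rule does not change counts on genuine spike-wave trains
  for (nc in c(4L, 8L)) {
    f <- swd_bandpass(synth_swd_waveform(9, nc, 0.3, fs), fs)
    expect_equal(count_cycles(f, fs = fs), nc)
  }
  # operational noise candidates (threshold crossings on an event-free
  # record) count few cycles: the overwhelming majority stay at <= 2, so
  # the cycle arm of the inclusion rule rarely fires on background
  set.seed(4)
  x <- 0.05 * rnorm(300 * 500)
  filt <- swd_bandpass(x, 500)
  env <- analytic_envelope(filt)
  cand <- detect_candidates(env, 500, k_sd = 2.5)
  expect_gt(nrow(cand), 20)
  counts <- vapply(seq_len(nrow(cand)), function(i) {
    a <- round(cand$start_s[i] * 500) + 1L
    b <- round(cand$end_s[i] * 500)
    count_cycles(filt[a:b], env[a:b], fs = 500)
  }, numeric(1))
  expect_lte(stats::quantile(counts, 0.9), 2)
  expect_lt(mean(counts > 3), 0.01)
})

test_that("inclusion rule is a strict OR of duration and cycle arms", {
  expect_false(inclusion_predicate(400, 3))
  expect_true(inclusion_predicate(401, 3))
  expect_true(inclusion_predicate(300, 4))
  expect_false(inclusion_predicate(399, 2))
  # largest rejected duration at 3 cycles, swept in 1-ms steps
  durs <- 100:800
  rej <- durs[!inclusion_predicate(durs, 3)]
  expect_equal(max(rej), 400)
})

test_that("rater review round-trip overrides automated acceptance", {
  ev <- data.frame(event_id = 1:4, start_s = c(1, 5, 9, 13),
                   end_s = c(1.5, 5.5, 9.5, 13.5),
                   duration_ms = rep(500, 4), n_cycles = rep(5L, 4),
                   included = rep(TRUE, 4), accepted = rep(TRUE, 4),
                   peak_envelope = rep(1, 4))
  class(ev) <- c("swd_events", "data.frame")

  expect_equal(sum(review_roundtrip(ev)$accepted), 4)
  rejall <- review_roundtrip(ev, data.frame(event_id = 1:4, accept = FALSE))
  expect_equal(sum(rejall$accepted), 0)
  some <- review_roundtrip(ev, data.frame(event_id = c(1, 3), accept = TRUE))
  expect_equal(which(some$accepted), c(1L, 3L))
  expect_error(review_roundtrip(ev, data.frame(event_id = 9, accept = TRUE)),
               "unknown")
  # a decisions file cannot resurrect an event the inclusion rule rejected
  ev$included[2] <- FALSE
  forced <- review_roundtrip(ev, data.frame(event_id = 2, accept = TRUE))
  expect_false(forced$accepted[2])
})

test_that("events take the state of their start sweep; artifact-sweep events drop", {
  frames <- frames_from_runs(sleep = 200, movement = 200, immobility = 200)
  labels <- assign_sweeps(frames)
  ev <- data.frame(event_id = 1:3,
                   start_s = c(5, 9.8, 15), end_s = c(5.6, 10.4, 15.6),
                   duration_ms = rep(600, 3), n_cycles = rep(5L, 3),
                   included = TRUE, accepted = TRUE, peak_envelope = 1)
  class(ev) <- c("swd_events", "data.frame")
  out <- assign_event_states(ev, labels)
  expect_equal(out$state, c("sleep", "sleep", "movement"))
  # boundary-spanning event (9.8-10.4 s) takes the START sweep's state

  sw <- data.frame(sweep_index = 0:2, start_s = c(0, 10, 20),
                   summed_power_mv2hz = 0, artifact = c(TRUE, FALSE, FALSE))
  attr(sw, "sweep_s") <- 10
  class(sw) <- c("sweep_set", "data.frame")
  kept <- assign_event_states(ev, labels, sw)
  expect_equal(nrow(kept), 1)   # events in sweep 0 dropped
  expect_equal(kept$state, "movement")

  far <- ev; far$start_s[1] <- 100
  expect_error(assign_event_states(far, labels), "outside")
})

test_that("per-state rates normalize by artifact-free hours in state", {
  frames <- frames_from_runs(sleep = 200 * 180)  # 1800 s of sleep frames
  labels <- assign_sweeps(frames)
  mk_ev <- function(n) {
    st <- seq(5, by = 10, length.out = n)
    d <- data.frame(event_id = seq_len(n), start_s = st, end_s = st + 1,
                    duration_ms = rep(1000, n), n_cycles = rep(8L, n),
                    included = rep(TRUE, n), accepted = rep(TRUE, n),
                    peak_envelope = rep(1, n), state = rep("sleep", n))
    class(d) <- c("swd_events", "data.frame")
    d
  }
  # 50 events in 0.5 h of sleep -> 100 events/h
  half <- labels[labels$sweep_index < 180, ]
  attr(half, "sweep_s") <- 10
  r <- per_state_rates(mk_ev(50), half)
  expect_equal(r$swd_count_per_hour[r$state == "sleep"], 100)
  expect_equal(r$total_swd_s_per_hour[r$state == "sleep"], 100)
  expect_equal(r$mean_single_duration_s[r$state == "sleep"], 1)
  # no events: zero rates, missing mean duration
  r0 <- per_state_rates(mk_ev(0), half)
  expect_equal(r0$swd_count_per_hour[1], 0)
  expect_true(is.na(r0$mean_single_duration_s[1]))
  # zero hours in a state: rate missing, not zero
  expect_true(is.na(r0$swd_count_per_hour[r0$state == "mixed"]))
})

test_that("detection is invariant to a global gain factor", {
  cfg <- clean_session_config(duration_s = 300, eeg_fs = 500, seed = 13)
  s <- simulate_session(cfg)
  ev1 <- detect_swd(s$eeg)
  scaled <- eeg_record(s$eeg$signal * 7.3, fs = s$eeg$fs)
  ev2 <- detect_swd(scaled)
  expect_equal(ev1$start_s, ev2$start_s)
  expect_equal(ev1$end_s, ev2$end_s)
  expect_equal(ev1$accepted, ev2$accepted)
})

test_that("doubling session length leaves recovered rates unchanged within sampling error", {
  rate_of <- function(dur, seed) {
    cfg <- clean_session_config(duration_s = dur, eeg_fs = 500, seed = seed,
                                state_schedule = sleepy_schedule(dur))
    s <- simulate_session(cfg)
    ana <- analyze_session(s$eeg, s$trajectory)
    ana$rates$swd_count_per_hour[ana$rates$state == "sleep"]
  }
  r1 <- mean(vapply(1:4, function(sd) rate_of(660, sd), numeric(1)))
  r2 <- mean(vapply(5:8, function(sd) rate_of(1320, sd), numeric(1)))
  # both should sit near the configured 100/h; allow generous Poisson noise
  expect_lt(abs(r1 - r2), 35)
  expect_lt(abs(r1 - 100), 35)
})
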