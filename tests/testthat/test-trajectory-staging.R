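# Trajectory cleaning and the behavioral staging rules, with the printed
# rule boundaries recovered by exhaustive sweeps.

test_that("sharp-turn correction modifies only turns beyond 135 degrees", {
  # collinear path untouched
  tr <- turn_trajectory(0)
  expect_equal(correct_sharp_turns(tr)$x_cm, tr$x_cm)

  # exact back-track (180 degrees): middle point replaced by mean of 2nd
  # and 3rd points
  tr <- turn_trajectory(180)
  out <- correct_sharp_turns(tr)
  expect_equal(out$x_cm[2], mean(tr$x_cm[2:3]))
  expect_equal(out$y_cm[2], mean(tr$y_cm[2:3]))

  # exhaustive sweep: the largest unmodified angle is exactly 135
  unchanged <- vapply(0:180, function(a) {
    tr <- turn_trajectory(a)
    out <- correct_sharp_turns(tr)
    isTRUE(all.equal(out$x_cm, tr$x_cm)) && isTRUE(all.equal(out$y_cm, tr$y_cm))
  }, logical(1))
  expect_equal(max(which(unchanged)) - 1L, 135L)
  expect_false(unchanged[137])  # 136 degrees is corrected

  expect_warning(correct_sharp_turns(trajectory(0:1, c(0, 1), c(0, 0))),
                 "fewer than 3")
})

test_that("sharp-turn correction is idempotent on glitchy paths", {
  set.seed(33)
  for (rep in 1:5) {
    n <- 60
    x <- cumsum(rnorm(n, 0.3, 0.05)); y <- cumsum(rnorm(n, 0.1, 0.05))
    # inject lateral turnback spikes (turn angle ~143 degrees)
    for (k in sample(seq(5, n - 5, by = 4), 3)) {
      dx <- (x[k + 1] - x[k - 1]) / 2; dy <- (y[k + 1] - y[k - 1]) / 2
      x[k] <- (x[k - 1] + x[k + 1]) / 2 - 3 * dy
      y[k] <- (y[k - 1] + y[k + 1]) / 2 + 3 * dx
    }
    tr <- trajectory((seq_len(n) - 1) / 20, x, y)
    once <- correct_sharp_turns(tr)
    twice <- correct_sharp_turns(once)
    expect_equal(twice$x_cm, once$x_cm, tolerance = 1e-12)
    expect_equal(twice$y_cm, once$y_cm, tolerance = 1e-12)
  }
})

test_that("jump correction bypasses spurious points via nearest-of-four", {
  # clean path where each next point is nearest: identity
  tr <- trajectory((0:9) / 20, x_cm = (0:9) * 0.3, y_cm = rep(0, 10))
  out <- correct_jumps(tr)
  expect_equal(out$x_cm, tr$x_cm)

  # single-frame jump to a distant point and back: bypassed + interpolated
  x <- c(0, 0.3, 8, 0.6, 0.9)
  tr <- trajectory((0:4) / 20, x, rep(0, 5))
  out <- correct_jumps(tr)
  expect_equal(out$x_cm[3], mean(c(0.3, 0.6)))  # linear interpolation

  # two consecutive spurious points
  x <- c(0, 0.3, 8, -7, 0.6, 0.9, 1.2)
  tr <- trajectory((0:6) / 20, x, rep(0, 7))
  out <- correct_jumps(tr)
  expect_true(all(abs(out$x_cm) < 2))
})

test_that("smoothing preserves straight lines and reduces noise", {
  t <- (0:199) / 20
  line <- trajectory(t, 2 * t, -1 * t)
  out <- smooth_trajectory(line)
  expect_equal(out$x_cm, line$x_cm, tolerance = 1e-6)
  expect_equal(out$y_cm, line$y_cm, tolerance = 1e-6)

  # constant position: unchanged
  flat <- trajectory(t, rep(3, 200), rep(4, 200))
  outf <- smooth_trajectory(flat)
  expect_equal(outf$x_cm, flat$x_cm)

  # Monte-Carlo: smoothing a noisy sinusoid reduces RMS error to the truth
  set.seed(7)
  for (rep in 1:3) {
    xt <- 3 * sin(2 * pi * 0.1 * t); yt <- 3 * cos(2 * pi * 0.1 * t)
    noisy <- trajectory(t, xt + rnorm(200, 0, 0.2), yt + rnorm(200, 0, 0.2))
    sm <- smooth_trajectory(noisy)
    err_before <- sqrt(mean((noisy$x_cm - xt)^2 + (noisy$y_cm - yt)^2))
    err_after <- sqrt(mean((sm$x_cm - xt)^2 + (sm$y_cm - yt)^2))
    expect_lt(err_after, err_before)
  }
})

test_that("instant speed matches hand-computed distances over time lapses", {
  # 1 cm displacement per 0.05 s frame = 20 cm/s
  tr <- trajectory(c(0, 0.05, 0.1), c(0, 1, 2), c(0, 0, 0))
  expect_equal(instant_speed(tr), c(20, 20, 20))

  # stationary
  tr <- trajectory((0:5) / 20, rep(1, 6), rep(2, 6))
  expect_equal(instant_speed(tr), rep(0, 6))

  # unit-square walk brute-force oracle
  xs <- c(0, 1, 1, 0, 0); ys <- c(0, 0, 1, 1, 0)
  tr <- trajectory((0:4) / 20, xs, ys)
  d <- sqrt(diff(xs)^2 + diff(ys)^2)
  expect_equal(instant_speed(tr), c(d[1], d) * 20)

  expect_error(instant_speed(trajectory(0, 0, 0)), "at least 2")
})

test_that("frame classifier threshold is strict at 0.5 cm/s", {
  expect_equal(classify_frames(0.5), "immobility")
  expect_equal(classify_frames(0.51), "movement")
  speeds <- seq(0, 1, by = 0.01)
  lab <- classify_frames(speeds)
  expect_equal(max(speeds[lab == "immobility"]), 0.5)
  expect_equal(min(speeds[lab == "movement"]), 0.51)
})

test_that("single movement frames flanked by >=10 immobility frames are despiked", {
  imm <- function(k) rep("immobility", k)
  mov <- function(k) rep("movement", k)

  st <- c(imm(10), mov(1), imm(10))
  expect_true(all(despike_single_movement(st) == "immobility"))

  st2 <- c(imm(10), mov(2), imm(10))
  expect_equal(sum(despike_single_movement(st2) == "movement"), 2L)

  # only 9 immobility frames before: unchanged
  st3 <- c(mov(1), imm(9), mov(1), imm(10))
  expect_equal(despike_single_movement(st3), st3)
})

test_that("sleep rule relabels from 30 s into immobility runs, strictly", {
  fps <- 20
  imm <- function(s) rep("immobility", s * fps)
  mov <- function(s) rep("movement", s * fps)

  st <- c(mov(5), imm(60))
  out <- apply_sleep_rule(st, fps)
  run <- out[(5 * fps + 1):length(out)]
  expect_equal(sum(run == "immobility"), 30 * fps)
  expect_equal(sum(run == "sleep"), 30 * fps)
  # first sleep frame is exactly 30 s after immobility onset
  expect_equal((which(out == "sleep")[1] - (5 * fps + 1)) / fps, 30)

  # exactly 30.0 s: no sleep ("longer than 30 s" is strict)
  expect_false(any(apply_sleep_rule(c(mov(5), imm(30)), fps) == "sleep"))
  # 29 s: unchanged
  st29 <- c(mov(5), imm(29))
  expect_equal(apply_sleep_rule(st29, fps), st29)
})

test_that("sweep dominance rule is strict at 60%", {
  mk <- function(n_mov) frames_from_runs(movement = n_mov,
                                         immobility = 200 - n_mov)
  expect_equal(assign_sweeps(mk(121))$state, "movement")   # 60.5%
  expect_equal(assign_sweeps(mk(120))$state, "mixed")      # exactly 60%
  expect_equal(assign_sweeps(frames_from_runs(sleep = 200))$state, "sleep")
  expect_equal(assign_sweeps(mk(0))$state, "waking_immobility")

  # exhaustive: largest movement count still labeled mixed is 120/200
  lab <- vapply(0:200, function(k) assign_sweeps(mk(k))$state, character(1))
  expect_equal(max(which(lab == "mixed")) - 1L, 120L)
})

test_that("staging recovers ground-truth sweep states on glitch-free sessions", {
  for (seed in 1:3) {
    cfg <- clean_session_config(duration_s = 900, seed = seed)
    s <- simulate_session(cfg)
    st <- stage_trajectory(s$trajectory)
    acc <- mean(st$sweeps$state == s$truth$sweep_states$state)
    expect_gte(acc, 0.95)
    # state-hour conservation: sweeps tile the session
    expect_equal(nrow(st$sweeps) * 10, 900)
  }
})
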