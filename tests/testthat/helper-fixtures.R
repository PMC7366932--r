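# Shared fixture builders. Everything is generated in code at test time;
# sessions are kept short so the whole suite stays quick.

# A small, fully clean session: no artifacts, no tracking glitches.
clean_session_config <- function(duration_s = 600, eeg_fs = 500, seed = 1,
                                 ...) {
  session_config(duration_s = duration_s, eeg_fs = eeg_fs,
                 artifact_sweep_fraction = 0,
                 glitch_rates = c(sharp_turn = 0, jump = 0), seed = seed, ...)
}

# A sleep-heavy schedule: movement 30 s, immobility 30 s, then one long
# sleep bout. Ground-truth sleep starts exactly 30 s into the non-movement
# run, i.e. at t = 60 s.
sleepy_schedule <- function(duration_s) {
  data.frame(state = c("movement", "immobility", "sleep"),
             duration_s = c(30, 30, duration_s - 60))
}

# Three-point trajectory with a prescribed turning angle (degrees) between
# the two displacement vectors.
turn_trajectory <- function(angle_deg) {
  th <- angle_deg * pi / 180
  trajectory(time_s = c(0, 0.05, 0.1),
             x_cm = c(0, 1, 1 + cos(th)),
             y_cm = c(0, 0, sin(th)), fps = 20)
}

# Frame-state data frame at 20 fps from a run-length description, e.g.
# frames_from_runs(movement = 200, immobility = 400).
frames_from_runs <- function(..., fps = 20) {
  runs <- c(...)
  st <- rep(names(runs), runs)
  data.frame(time_s = (seq_along(st) - 1) / fps, state = st,
             speed_cm_s = NA_real_)
}
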