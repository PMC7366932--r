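# Sweep segmentation and artifact rejection. Each channel is divided into
# 10-s sweeps; a sweep whose summed 1-100 Hz Welch power exceeds the
# exclusion threshold is excluded from all further analysis, manual
# exclusions are unioned in, and a channel qualifies for the database only
# if it has fewer than 60 noisy sweeps (10 min).

#' Summed 1-100 Hz power of one sweep
#'
#' Welch PSD of the sweep (1-s Hann segments, 50\% overlap, hence 1-Hz bins)
#' summed over the bins from \code{band[1]} to \code{band[2]} Hz inclusive.
#'
#' @param sweep Numeric vector holding one 10-s sweep.
#' @param fs Sampling rate (samples/s).
#' @param band Summation band in Hz, default \code{c(1, 100)}.
#' @param sweep_s Expected sweep duration (s), default 10; shorter input is
#'   an error.
#' @return Summed power in mV^2/Hz.
#' @export
sweep_summed_power <- function(sweep, fs, band = c(1, 100), sweep_s = 10) {
  if (length(sweep) < sweep_s * fs) stop("sweep shorter than ", sweep_s, " s")
  p <- welch_psd(sweep, fs, seg_len = as.integer(fs), overlap = 0.5,
                 window = "hann")
  binned <- bin_psd_1hz(p$freq, p$power, bins = band[1]:band[2])
  sum(binned)
}

#' Segment a record into sweeps and compute per-sweep power
#'
#' @param rec An \code{\link{eeg_record}}.
#' @param channel Channel index or name, default first.
#' @param sweep_s Sweep length (s), default 10; a trailing partial sweep is
#'   dropped, matching the behavioral sweep grid.
#' @param band Artifact summation band, default 1-100 Hz.
#' @return Data frame of class \code{"sweep_set"}: \code{sweep_index}
#'   (0-based), \code{start_s}, \code{summed_power_mv2hz}, \code{artifact}
#'   (all FALSE until flagged).
#' @export
sweep_set <- function(rec, channel = 1L, sweep_s = 10, band = c(1, 100)) {
  x <- eeg_channel(rec, channel)
  spw <- as.integer(sweep_s * rec$fs)
  n_sweeps <- floor(length(x) / spw)
  if (n_sweeps < 1L) stop("record shorter than one sweep")
  pow <- vapply(seq_len(n_sweeps), function(i) {
    sweep_summed_power(x[((i - 1L) * spw + 1L):(i * spw)], rec$fs,
                       band = band, sweep_s = sweep_s)
  }, numeric(1))
  out <- data.frame(sweep_index = seq_len(n_sweeps) - 1L,
                    start_s = (seq_len(n_sweeps) - 1L) * sweep_s,
                    summed_power_mv2hz = pow,
                    artifact = FALSE)
  attr(out, "sweep_s") <- sweep_s
  attr(out, "fs") <- rec$fs
  class(out) <- c("sweep_set", "data.frame")
  out
}

#' Flag artifact sweeps by the summed-power rule
#'
#' A sweep is excluded when its summed 1-100 Hz power is strictly higher
#' than the threshold.
#'
#' @param sweeps A \code{\link{sweep_set}}.
#' @param threshold_mv2hz Exclusion threshold, default 2e4 mV^2/Hz.
#' @return The sweep set with \code{artifact} updated.
#' @export
flag_artifact_sweeps <- function(sweeps, threshold_mv2hz = 2e4) {
  sweeps$artifact <- sweeps$artifact |
    (sweeps$summed_power_mv2hz > threshold_mv2hz)
  sweeps
}

#' Union manual exclusions into the artifact mask
#'
#' Mirrors the visual quality check in which noisy sweeps are cut out by
#' hand: the listed sweep indices are excluded in addition to the automatic
#' flags.
#'
#' @param sweeps A \code{\link{sweep_set}}.
#' @param mask Integer vector of 0-based sweep indices, or a path to a CSV
#'   file with a \code{sweep_index} column.
#' @return The sweep set with \code{artifact} updated.
#' @export
apply_manual_mask <- function(sweeps, mask) {
  if (is.character(mask)) {
    mask <- utils::read.csv(mask)$sweep_index
  }
  if (length(mask) == 0L) return(sweeps)
  mask <- as.integer(mask)
  if (any(mask < 0L | mask > max(sweeps$sweep_index))) {
    stop("manual mask contains out-of-range sweep indices")
  }
  sweeps$artifact[sweeps$sweep_index %in% mask] <- TRUE
  sweeps
}

#' Channel qualification rule
#'
#' A channel is qualified into the database only if it has fewer than
#' \code{max_noisy} noisy sweeps (strict; 60 sweeps = 10 min).
#'
#' @param sweeps A \code{\link{sweep_set}} with artifact flags, or a plain
#'   noisy-sweep count.
#' @param max_noisy Disqualification bound, default 60.
#' @return Logical: TRUE if the channel qualifies.
#' @export
qualify_channel <- function(sweeps, max_noisy = 60L) {
  n_noisy <- if (is.numeric(sweeps)) sweeps else sum(sweeps$artifact)
  n_noisy < max_noisy
}

# Per-sample logical mask (TRUE = usable) from the artifact flags; samples
# past the last full sweep are unusable.
artifact_sample_mask <- function(sweeps, n_samples, fs) {
  sweep_s <- attr(sweeps, "sweep_s")
  spw <- as.integer(sweep_s * fs)
  mask <- rep(FALSE, n_samples)
  for (i in seq_len(nrow(sweeps))) {
    if (!sweeps$artifact[i]) {
      a <- sweeps$sweep_index[i] * spw + 1L
      b <- min(n_samples, a + spw - 1L)
      if (a <= n_samples) mask[a:b] <- TRUE
    }
  }
  mask
}
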