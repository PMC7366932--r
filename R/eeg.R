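# Continuous EEG container and gain normalization, plus flat-binary I/O
# (float32 samples with a JSON sidecar header).

#' Construct an EEG record
#'
#' @param signal Numeric vector (one channel) or matrix (samples x channels)
#'   of gain-normalized amplitudes in mV at the electrode.
#' @param fs Sampling rate in samples/s (the recordings this package targets
#'   are digitized at 2000 samples/s per channel).
#' @param channels Channel labels; default \code{"right_frontal"} (the
#'   analyzed channel) plus numbered labels for any extra columns.
#' @param gain Acquisition gain already removed from \code{signal}
#'   (documentation only), default 1000.
#' @return List of class \code{"eeg_record"}.
#' @export
eeg_record <- function(signal, fs, channels = NULL, gain = 1000) {
  if (is.vector(signal)) signal <- matrix(signal, ncol = 1L)
  if (fs <= 0) stop("fs must be positive")
  if (!all(is.finite(signal))) stop("signal must be finite")
  if (is.null(channels)) {
    channels <- c("right_frontal",
                  if (ncol(signal) > 1L) paste0("ch", 2:ncol(signal)))
  }
  colnames(signal) <- channels
  structure(list(signal = signal, fs = fs, channels = channels, gain = gain),
            class = "eeg_record")
}

#' @export
print.eeg_record <- function(x, ...) {
  cat(sprintf("EEG record: %d samples x %d channel(s) at %g Hz (%.1f s)\n",
              nrow(x$signal), ncol(x$signal), x$fs, nrow(x$signal) / x$fs))
  cat("  channels:", paste(x$channels, collapse = ", "), "\n")
  invisible(x)
}

eeg_channel <- function(rec, channel = 1L) as.numeric(rec$signal[, channel])

eeg_duration_s <- function(rec) nrow(rec$signal) / rec$fs

#' Normalize a raw recording to amplification
#'
#' Divides the acquired signal by the amplifier gain so that amplitudes are
#' expressed in mV at the electrode.
#'
#' @param raw Numeric vector/matrix of acquired amplitudes.
#' @param gain Amplifier gain (> 0), default 1000.
#' @param fs Sampling rate, passed through to the record.
#' @return An \code{\link{eeg_record}} in mV.
#' @export
normalize_gain <- function(raw, gain = 1000, fs = 2000) {
  if (gain <= 0) stop("gain must be positive")
  eeg_record(raw / gain, fs = fs, gain = gain)
}

#' Write / read an EEG record as float32 binary plus JSON header
#'
#' Samples are stored interleaved by channel as little-endian float32 in
#' \code{<path>.dat}; \code{<path>.json} holds \code{fs}, \code{n_channels},
#' \code{channels}, \code{unit} and \code{gain}.
#'
#' @param rec An \code{\link{eeg_record}}.
#' @param path Base path (without extension).
#' @return \code{write_eeg_binary} returns \code{path} invisibly;
#'   \code{read_eeg_binary} returns an \code{\link{eeg_record}}.
#' @export
write_eeg_binary <- function(rec, path) {
  hdr <- list(fs = rec$fs, n_channels = ncol(rec$signal),
              channels = rec$channels, unit = "mV", gain = rec$gain,
              n_samples = nrow(rec$signal))
  jsonlite::write_json(hdr, paste0(path, ".json"), auto_unbox = TRUE)
  con <- file(paste0(path, ".dat"), "wb")
  on.exit(close(con))
  writeBin(as.numeric(t(rec$signal)), con, size = 4L, endian = "little")
  invisible(path)
}

#' @rdname write_eeg_binary
#' @export
read_eeg_binary <- function(path) {
  hdr <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  con <- file(paste0(path, ".dat"), "rb")
  on.exit(close(con))
  n <- hdr$n_samples * hdr$n_channels
  x <- readBin(con, "numeric", n = n, size = 4L, endian = "little")
  sig <- matrix(x, ncol = hdr$n_channels, byrow = TRUE)
  eeg_record(sig, fs = hdr$fs, channels = hdr$channels, gain = hdr$gain)
}
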