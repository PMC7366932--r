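# Core signal-processing primitives: Welch power spectral density, zero-phase
# FFT band-pass filtering, the analytic-signal envelope, and prominence-based
# peak finding. These are deliberately small, dependency-free implementations;
# everything downstream (artifact rejection, SWD detection, spectral
# comparisons) is built on them.

#' Welch power spectral density estimate
#'
#' Averaged modified periodogram over (possibly overlapping) windowed
#' segments. Returns a one-sided density so that \code{sum(power) * df}
#' approximates the signal variance for stationary input.
#'
#' @param x Numeric signal vector.
#' @param fs Sampling rate in samples/s.
#' @param seg_len Segment length in samples. Defaults to
#'   \code{floor(length(x) / 8)} (at least 8), mirroring the conventional
#'   default of eight 50\%-overlapping segments. If \code{x} is shorter than
#'   \code{seg_len} a single full-length segment is used.
#' @param overlap Fractional overlap between consecutive segments (0 to <1).
#' @param window Taper: \code{"hann"} or \code{"hamming"}.
#' @param one_sided Return one-sided spectrum (default TRUE).
#' @return List with \code{freq} (Hz), \code{power} (signal units^2 / Hz) and
#'   \code{n_segments}.
#' @export
welch_psd <- function(x, fs, seg_len = NULL, overlap = 0.5,
                      window = c("hann", "hamming"), one_sided = TRUE) {
  window <- match.arg(window)
  n <- length(x)
  if (n < 2L) stop("signal too short for a PSD estimate")
  if (is.null(seg_len)) seg_len <- max(8L, floor(n / 8))
  seg_len <- as.integer(min(seg_len, n))
  step <- max(1L, as.integer(round(seg_len * (1 - overlap))))
  starts <- seq.int(1L, n - seg_len + 1L, by = step)

  k <- (seq_len(seg_len) - 1) / (seg_len - 1)
  w <- switch(window,
    hann    = 0.5 - 0.5 * cos(2 * pi * k),
    hamming = 0.54 - 0.46 * cos(2 * pi * k)
  )
  u <- sum(w^2)

  segs <- vapply(starts, function(s) x[s:(s + seg_len - 1L)] * w,
                 numeric(seg_len))
  segs <- matrix(segs, nrow = seg_len)
  spec <- Mod(stats::mvfft(segs))^2 / (fs * u)
  pxx <- rowMeans(spec)

  if (one_sided) {
    nf <- floor(seg_len / 2) + 1L
    pxx <- pxx[seq_len(nf)]
    # double everything except DC and (for even lengths) Nyquist
    last_dbl <- if (seg_len %% 2 == 0) nf - 1L else nf
    if (nf > 2L) pxx[2:last_dbl] <- 2 * pxx[2:last_dbl]
    freq <- (seq_len(nf) - 1) * fs / seg_len
  } else {
    freq <- (seq_len(seg_len) - 1) * fs / seg_len
  }
  list(freq = freq, power = pxx, n_segments = length(starts))
}

#' Re-bin a PSD onto integer 1-Hz bins
#'
#' Bin b covers [b - 0.5, b + 0.5) Hz; the bin value is the mean of the PSD
#' points falling in the bin (linear interpolation fills bins that contain no
#' point, which can happen when the frequency resolution is coarser than
#' 1 Hz).
#'
#' @param freq Frequencies (Hz) of the PSD estimate.
#' @param power PSD values.
#' @param bins Integer bin centers, default 1:100.
#' @return Numeric vector of binned PSD values named by bin center.
#' @export
bin_psd_1hz <- function(freq, power, bins = 1:100) {
  idx <- findInterval(freq, c(bins - 0.5, bins[length(bins)] + 0.5))
  out <- rep(NA_real_, length(bins))
  inside <- idx >= 1L & idx <= length(bins) &
    freq >= bins[1] - 0.5 & freq < bins[length(bins)] + 0.5
  if (any(inside)) {
    agg <- tapply(power[inside], idx[inside], mean)
    out[as.integer(names(agg))] <- agg
  }
  if (anyNA(out)) {
    fill <- stats::approx(freq, power, xout = bins, rule = 2)$y
    out[is.na(out)] <- fill[is.na(out)]
  }
  names(out) <- bins
  out
}

# Next 2-3-5-smooth length >= n, for fast mixed-radix FFTs.
fft_length <- function(n) stats::nextn(n, c(2L, 3L, 5L))

#' Zero-phase band-pass filter via FFT masking
#'
#' The spectrum is multiplied by a real, symmetric mask: unity in the
#' pass-band, raised-cosine transitions down to zero at \code{stop_low} and
#' \code{stop_high}, zero outside. A real symmetric mask has exactly zero
#' phase, so event boundaries measured on the filtered trace are not lagged.
#' Attenuation at and beyond the stop edges is complete (far in excess of
#' 40 dB).
#'
#' @param x Numeric signal.
#' @param fs Sampling rate (samples/s).
#' @param low,high Pass-band edges in Hz.
#' @param stop_low,stop_high Stop-band edges; defaults \code{low / 2} and
#'   \code{high * 1.5}.
#' @return Filtered signal, same length as \code{x}.
#' @export
fft_bandpass <- function(x, fs, low = 7, high = 23,
                         stop_low = low / 2, stop_high = high * 1.5) {
  if (fs < 2 * high) stop("sampling rate must be at least twice the high band edge")
  if (!(stop_low < low && low < high && high < stop_high)) {
    stop("band edges must satisfy stop_low < low < high < stop_high")
  }
  n <- length(x)
  m <- fft_length(n)
  xp <- c(x, numeric(m - n))
  f <- (seq_len(m) - 1) * fs / m
  f <- pmin(f, fs - f)          # absolute frequency of each FFT bin
  h <- numeric(m)
  h[f >= low & f <= high] <- 1
  lo_ramp <- f > stop_low & f < low
  h[lo_ramp] <- 0.5 * (1 - cos(pi * (f[lo_ramp] - stop_low) / (low - stop_low)))
  hi_ramp <- f > high & f < stop_high
  h[hi_ramp] <- 0.5 * (1 + cos(pi * (f[hi_ramp] - high) / (stop_high - high)))
  y <- Re(stats::fft(stats::fft(xp) * h, inverse = TRUE)) / m
  y[seq_len(n)]
}

#' Hilbert (analytic-signal) envelope
#'
#' Magnitude of the analytic signal \code{x + i H(x)}, computed by one-sided
#' spectrum doubling in the frequency domain.
#'
#' @param x Real signal (typically band-passed).
#' @return Non-negative envelope, same length as \code{x}.
#' @export
analytic_envelope <- function(x) {
  n <- length(x)
  m <- fft_length(n)
  xp <- c(x, numeric(m - n))
  h <- numeric(m)
  if (m %% 2 == 0) {
    h[1] <- 1; h[m / 2 + 1] <- 1
    h[2:(m / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((m + 1) / 2)] <- 2
  }
  z <- stats::fft(stats::fft(xp) * h, inverse = TRUE) / m
  Mod(z[seq_len(n)])
}

# Local maxima (strict sign change of the first difference). Plateau samples
# are collapsed to their first index.
local_maxima <- function(x) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  d <- diff(x)
  # treat zero differences by carrying the previous sign
  s <- sign(d)
  for (i in seq_along(s)) if (s[i] == 0 && i > 1L) s[i] <- s[i - 1L]
  which(diff(s) < 0) + 1L
}

#' Peak prominence
#'
#' For each local maximum, the prominence is the peak height minus the higher
#' of the two base levels, where each base is the minimum of the signal
#' between the peak and the nearest point on that side that exceeds the peak
#' (or the signal end).
#'
#' @param x Numeric signal.
#' @return Data frame with columns \code{index}, \code{height},
#'   \code{prominence}.
#' @export
peak_prominences <- function(x) {
  pk <- local_maxima(x)
  if (length(pk) == 0L) {
    return(data.frame(index = integer(0), height = numeric(0),
                      prominence = numeric(0)))
  }
  n <- length(x)
  prom <- vapply(pk, function(i) {
    h <- x[i]
    j <- i - 1L; lmin <- h
    while (j >= 1L && x[j] <= h) { if (x[j] < lmin) lmin <- x[j]; j <- j - 1L }
    j <- i + 1L; rmin <- h
    while (j <= n && x[j] <= h) { if (x[j] < rmin) rmin <- x[j]; j <- j + 1L }
    h - max(lmin, rmin)
  }, numeric(1))
  data.frame(index = pk, height = x[pk], prominence = prom)
}
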