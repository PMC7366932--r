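# Spectral summaries: Welch PSD of merged SWD events, absolute per-state
# whole-EEG PSD, relative (per-mouse normalized, x5000) PSD, and per-1-Hz-bin
# group comparisons with FDR correction across 1-30 Hz.

# Welch with conventional defaults (Hamming window, eight 50%-overlapping
# segments of the analysis window), binned to 1-Hz bins. Segments are never
# shorter than 1 s so the raw frequency resolution stays at or below ~1 Hz
# even for degenerate short inputs (welch_psd itself caps the segment at
# the input length).
welch_1hz <- function(x, fs, bins = 1:100) {
  p <- welch_psd(x, fs, seg_len = max(as.integer(fs), floor(length(x) / 8)),
                 overlap = 0.5, window = "hamming")
  bin_psd_1hz(p$freq, p$power, bins = bins)
}

psd_result <- function(power, kind, n_contributing = NA_integer_) {
  out <- data.frame(freq_hz = as.integer(names(power)), power = as.numeric(power))
  attr(out, "kind") <- kind
  attr(out, "n_contributing") <- n_contributing
  class(out) <- c("psd_result", "data.frame")
  out
}

#' @export
print.psd_result <- function(x, ...) {
  cat(sprintf("%s PSD: %d 1-Hz bins (%d-%d Hz), peak at %d Hz\n",
              attr(x, "kind"), nrow(x), min(x$freq_hz), max(x$freq_hz),
              x$freq_hz[which.max(x$power)]))
  invisible(x)
}

#' PSD of merged SWD events
#'
#' All accepted SWD segments (by default those occurring during sleep,
#' waking immobility or mixed state) are picked out of the raw trace and
#' concatenated in time order; Welch's averaged modified periodogram is then
#' applied over consecutive 10-s windows of the merged series, and the
#' window PSDs are averaged and binned by 1 Hz. A merged series shorter than
#' one window is analyzed as a single shorter window.
#'
#' @param events Accepted \code{\link{swd_events}} with states assigned.
#' @param rec The \code{\link{eeg_record}} the events were detected in.
#' @param states Behavioral states pooled into the merge; use
#'   \code{"waking_immobility"} alone for an immobility-only pooling.
#' @param channel Channel index, default first.
#' @param window_s Analysis window over the merged series, default 10 s.
#' @param bins 1-Hz bins to report, default 1:100.
#' @return A \code{psd_result} (kind \code{"absolute"}), or an empty result
#'   with a warning when no accepted event matches.
#' @export
merged_swd_psd <- function(events, rec,
                           states = c("sleep", "waking_immobility", "mixed"),
                           channel = 1L, window_s = 10, bins = 1:100) {
  acc <- events[events$accepted, , drop = FALSE]
  if (!is.null(acc$state)) acc <- acc[acc$state %in% states, , drop = FALSE]
  if (nrow(acc) == 0L) {
    warning("no accepted events to merge")
    return(psd_result(stats::setNames(rep(NA_real_, length(bins)), bins),
                      "absolute", 0L))
  }
  x <- eeg_channel(rec, channel)
  acc <- acc[order(acc$start_s), , drop = FALSE]
  segs <- lapply(seq_len(nrow(acc)), function(i) {
    a <- as.integer(round(acc$start_s[i] * rec$fs)) + 1L
    b <- min(length(x), as.integer(round(acc$end_s[i] * rec$fs)))
    x[a:b]
  })
  merged <- unlist(segs)
  wlen <- as.integer(window_s * rec$fs)
  starts <- seq.int(1L, max(1L, length(merged)), by = wlen)
  psds <- lapply(starts, function(s) {
    w <- merged[s:min(length(merged), s + wlen - 1L)]
    if (length(w) < 16L) return(NULL)
    welch_1hz(w, rec$fs, bins = bins)
  })
  psds <- psds[!vapply(psds, is.null, logical(1))]
  avg <- Reduce(`+`, psds) / length(psds)
  psd_result(avg, "absolute", nrow(acc))
}

#' Absolute whole-EEG PSD for one behavioral state
#'
#' Welch PSD per qualifying (state-matching, artifact-free) 10-s sweep,
#' averaged across sweeps and binned by 1 Hz.
#'
#' @param rec An \code{\link{eeg_record}}.
#' @param sweep_labels Behavioral \code{\link{sweep_labels}}.
#' @param state Behavioral state to average over.
#' @param sweeps Optional \code{\link{sweep_set}} with artifact flags.
#' @param channel Channel index, default first.
#' @param bins 1-Hz bins, default 1:100.
#' @return A \code{psd_result} (kind \code{"absolute"}), or NULL when no
#'   sweep qualifies.
#' @export
state_psd_absolute <- function(rec, sweep_labels, state, sweeps = NULL,
                               channel = 1L, bins = 1:100) {
  keep <- sweep_labels$sweep_index[sweep_labels$state == state]
  if (!is.null(sweeps)) {
    keep <- setdiff(keep, sweeps$sweep_index[sweeps$artifact])
  }
  if (length(keep) == 0L) return(NULL)
  x <- eeg_channel(rec, channel)
  sweep_s <- attr(sweep_labels, "sweep_s")
  if (is.null(sweep_s)) sweep_s <- 10
  spw <- as.integer(sweep_s * rec$fs)
  psds <- lapply(keep, function(i) {
    a <- i * spw + 1L
    b <- a + spw - 1L
    if (b > length(x)) return(NULL)
    welch_1hz(x[a:b], rec$fs, bins = bins)
  })
  psds <- psds[!vapply(psds, is.null, logical(1))]
  if (length(psds) == 0L) return(NULL)
  avg <- Reduce(`+`, psds) / length(psds)
  psd_result(avg, "absolute", length(psds))
}

#' Relative PSD: per-mouse normalization scaled by 5000
#'
#' Each 1-Hz bin of the absolute PSD is divided by the summed PSD across
#' 1-30 Hz (of the same mouse) and multiplied 5000 times, so the relative
#' spectrum always sums to exactly 5000 over 1-30 Hz. The normalization is
#' applied per mouse, before any group averaging.
#'
#' @param absolute A \code{psd_result} of kind \code{"absolute"} whose bins
#'   cover 1-30 Hz.
#' @param norm_band Normalization band, default \code{c(1, 30)}.
#' @param scale Scale factor, default 5000.
#' @return A \code{psd_result} of kind \code{"relative"}.
#' @export
state_psd_relative <- function(absolute, norm_band = c(1, 30), scale = 5000) {
  in_band <- absolute$freq_hz >= norm_band[1] & absolute$freq_hz <= norm_band[2]
  if (!any(in_band)) stop("absolute PSD does not cover the normalization band")
  tot <- sum(absolute$power[in_band])
  if (!is.finite(tot) || tot <= 0) stop("zero total power in normalization band")
  psd_result(stats::setNames(scale * absolute$power / tot, absolute$freq_hz),
             "relative", attr(absolute, "n_contributing"))
}

#' Per-bin t-tests between two groups of spectra with FDR correction
#'
#' An independent-samples t-test is run for each 1-Hz bin between the two
#' groups of per-mouse spectra, and Benjamini-Hochberg FDR correction is
#' applied across the tested band (1-30 Hz by default). For
#' treatment-versus-saline comparisons the control group conventionally
#' pools both saline sessions.
#'
#' @param group_a,group_b Matrices (mice x bins) of per-mouse PSD values;
#'   columns named by bin center, or assumed 1..ncol.
#' @param band Tested band, default \code{c(1, 30)}.
#' @param alpha Significance level on the adjusted p-values, default 0.05.
#' @param var_equal Pass-through to \code{t.test}, default TRUE (pooled
#'   variance).
#' @return Data frame \code{freq_hz}, \code{t}, \code{p}, \code{q},
#'   \code{significant}.
#' @export
psd_bin_tests <- function(group_a, group_b, band = c(1, 30), alpha = 0.05,
                          var_equal = TRUE) {
  if (nrow(group_a) < 2L || nrow(group_b) < 2L) {
    stop("need at least 2 mice per group")
  }
  bins <- as.integer(colnames(group_a) %||% seq_len(ncol(group_a)))
  sel <- which(bins >= band[1] & bins <= band[2])
  tp <- vapply(sel, function(j) {
    tt <- stats::t.test(group_a[, j], group_b[, j], var.equal = var_equal)
    c(tt$statistic, tt$p.value)
  }, numeric(2))
  q <- stats::p.adjust(tp[2, ], method = "BH")
  data.frame(freq_hz = bins[sel], t = tp[1, ], p = tp[2, ], q = q,
             significant = q < alpha)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
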