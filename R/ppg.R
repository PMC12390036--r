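#' Zero-phase Butterworth low-pass conditioning of the PPG
#'
#' 8th-order Butterworth low-pass (default cut-off 10 Hz) applied
#' forward-backward; unit DC gain, so the pulse baseline is preserved.
#'
#' @param ppg A [waveform].
#' @param cutoff_hz Cut-off frequency in Hz (default 10).
#' @param order Filter order (default 8).
#' @return A filtered [waveform] of the same length.
#' @export
lowpass_ppg <- function(ppg, cutoff_hz = 10, order = 8) {
  stopifnot(inherits(ppg, "waveform"))
  if (ppg$fs <= 2 * cutoff_hz) {
    stop("sampling rate ", ppg$fs, " Hz too low for a ", cutoff_hz,
         " Hz cut-off", call. = FALSE)
  }
  bf <- signal::butter(order, cutoff_hz / (ppg$fs / 2), type = "low")
  # filter around the mean: keeps the DC level exact despite coefficient
  # round-off in the high-order filter
  m <- mean(ppg$samples)
  ppg$samples <- m + filtfilt_padded(bf, ppg$samples - m, ppg$fs)
  ppg
}

#' Savitzky-Golay polynomial smoothing
#'
#' Local least-squares polynomial smoothing; a polynomial of degree
#' `polyorder` or less passes through unchanged (up to edge effects).
#'
#' @param x A [waveform].
#' @param window_ms Smoothing window in milliseconds (default 250); the
#'   window in samples is forced odd.
#' @param polyorder Polynomial order (default 3); must be smaller than the
#'   window length in samples.
#' @return A smoothed [waveform] of the same length.
#' @export
savgol_smooth <- function(x, window_ms = 250, polyorder = 3) {
  stopifnot(inherits(x, "waveform"))
  n <- round(window_ms / 1000 * x$fs)
  if (n %% 2 == 0) n <- n + 1
  if (n <= polyorder) {
    stop("Savitzky-Golay window (", n, " samples) must exceed the ",
         "polynomial order (", polyorder, ")", call. = FALSE)
  }
  x$samples <- as.numeric(signal::sgolayfilt(x$samples, p = polyorder, n = n))
  x
}

#' Detect systolic peaks and preceding troughs in a smoothed PPG
#'
#' Systolic peaks are local maxima at least `60 / hr_max_bpm` seconds apart
#' (default ceiling 220 beats/min) whose prominence reaches
#' `prominence_frac` of the median peak prominence (the peak-to-trough
#' excursion scale). Each pulse's trough is the signal minimum between the
#' previous peak and the peak itself; the first trough is the minimum over
#' the 0.5 s preceding the first peak.
#'
#' @param ppg_smooth A conditioned PPG [waveform] of at least 2 s.
#' @param hr_max_bpm Physiological ceiling on pulse rate (default 220).
#' @param prominence_frac Prominence gate as a fraction of the median
#'   excursion (default 0.3).
#' @return An object of class `pulse_extrema`: data frame with columns
#'   `peak_idx`, `trough_idx` (1-based sample indices, `trough_idx <
#'   peak_idx`).
#' @export
detect_pulse_extrema <- function(ppg_smooth, hr_max_bpm = 220,
                                 prominence_frac = 0.3) {
  stopifnot(inherits(ppg_smooth, "waveform"))
  x <- ppg_smooth$samples
  fs <- ppg_smooth$fs
  if (length(x) < 2 * fs) stop("need at least 2 s of signal", call. = FALSE)
  min_dist <- round(60 / hr_max_bpm * fs)
  peaks <- find_peaks(x, min_distance = min_dist)
  if (length(peaks) == 0L) {
    return(structure(data.frame(peak_idx = integer(0),
                                trough_idx = integer(0)),
                     class = c("pulse_extrema", "data.frame")))
  }
  prom <- peak_prominence(x, peaks)
  peaks <- peaks[prom >= prominence_frac * stats::median(prom)]
  peaks <- peaks[peaks > 1L]  # a peak needs a preceding trough
  if (length(peaks) == 0L) {
    return(structure(data.frame(peak_idx = integer(0),
                                trough_idx = integer(0)),
                     class = c("pulse_extrema", "data.frame")))
  }
  trough <- integer(length(peaks))
  for (i in seq_along(peaks)) {
    lo <- if (i == 1L) max(1L, peaks[1] - round(0.5 * fs)) else peaks[i - 1L]
    span <- lo:(peaks[i] - 1L)
    trough[i] <- span[which.min(x[span])]
  }
  structure(data.frame(peak_idx = peaks, trough_idx = trough),
            class = c("pulse_extrema", "data.frame"))
}

#' Pulse-amplitude (AM) beat series
#'
#' Per-pulse amplitude `x[peak] - x[trough]` (systolic maximum minus the
#' preceding minimum), timestamped at the systolic peaks. Baseline-robust:
#' invariant to additive constants and equivariant to amplitude scaling.
#'
#' @param ppg_smooth The conditioned PPG [waveform] the extrema were found
#'   on.
#' @param extrema A `pulse_extrema` from [detect_pulse_extrema()].
#' @return A [beat_series] with feature `"ppg_am"`.
#' @export
am_series <- function(ppg_smooth, extrema) {
  stopifnot(inherits(ppg_smooth, "waveform"),
            inherits(extrema, "pulse_extrema"))
  if (nrow(extrema) < 3L) {
    stop("need at least 3 pulses for an AM series", call. = FALSE)
  }
  x <- ppg_smooth$samples
  beat_series("ppg_am",
              times = ppg_smooth$t0 + (extrema$peak_idx - 1) / ppg_smooth$fs,
              values = x[extrema$peak_idx] - x[extrema$trough_idx])
}

#' Beat-interval (FM) series
#'
#' Successive systolic peak-to-peak intervals in seconds, timestamped at the
#' midpoint of each peak pair; the beat-domain trace of respiratory sinus
#' arrhythmia. Invariant to amplitude scaling of the PPG.
#'
#' @param extrema A `pulse_extrema` from [detect_pulse_extrema()].
#' @param fs Sampling rate of the PPG the extrema were found on, in Hz.
#' @param t0 Time of the first PPG sample (default 0).
#' @return A [beat_series] with feature `"ppg_fm"` (values in seconds).
#' @export
fm_series <- function(extrema, fs, t0 = 0) {
  stopifnot(inherits(extrema, "pulse_extrema"))
  if (nrow(extrema) < 4L) {
    stop("need at least 4 pulses for an FM series", call. = FALSE)
  }
  pt <- t0 + (extrema$peak_idx - 1) / fs
  np <- length(pt)
  beat_series("ppg_fm",
              times = (pt[-np] + pt[-1]) / 2,
              values = diff(pt))
}
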