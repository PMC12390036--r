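#' Reconstruct a continuous surrogate respiration from a beat series
#'
#' Natural cubic-spline interpolation through the beat-feature knots,
#' evaluated on a uniform grid at `fs_out` over `[first knot, last knot]`
#' (no extrapolation: extrapolated cubics oscillate and fabricate peaks),
#' then min-max normalized to \[0, 1\].
#'
#' @param series A [beat_series] with at least 3 knots.
#' @param fs_out Output sampling rate in Hz (default 4; Nyquist-safe for
#'   respiratory rates up to 60 breaths/min with a wide margin).
#' @return An object of class `derived_respiration`: a normalized [waveform]
#'   carrying the source feature in `source`.
#' @export
spline_reconstruct <- function(series, fs_out = 4) {
  stopifnot(inherits(series, "beat_series"))
  if (length(series$times) < 3L) {
    stop("need at least 3 knots for spline reconstruction", call. = FALSE)
  }
  if (any(diff(series$times) <= 0)) {
    stop("duplicate or non-increasing knot times", call. = FALSE)
  }
  grid <- seq(series$times[1], series$times[length(series$times)],
              by = 1 / fs_out)
  y <- stats::spline(series$times, series$values, xout = grid,
                     method = "natural")$y
  w <- normalize01(waveform(y, fs = fs_out, t0 = grid[1],
                            label = paste0("resp_", series$feature)))
  structure(c(unclass(w), list(source = series$feature)),
            class = c("derived_respiration", "waveform"))
}

#' @export
print.derived_respiration <- function(x, ...) {
  cat(sprintf("<derived_respiration> from %s: ", x$source))
  NextMethod()
}

#' Detect respiratory peaks
#'
#' Local maxima of a (normalized) respiration waveform with a minimum
#' inter-peak distance of `60 / rr_max_bpm` seconds and prominence at least
#' `min_prominence` in normalized units. The same detector serves reference
#' respiration and derived surrogates.
#'
#' @param resp A [waveform] or `derived_respiration`, normalized to \[0, 1\]
#'   (set `normalize = TRUE` to normalize first).
#' @param rr_max_bpm Ceiling on breathing rate, breaths/min (default 60).
#' @param min_prominence Prominence floor in normalized units (default 0.1).
#' @param normalize Normalize to \[0, 1\] before detection (default `FALSE`;
#'   use `TRUE` for raw reference channels).
#' @return Numeric vector of peak times in seconds (may be empty).
#' @export
detect_resp_peaks <- function(resp, rr_max_bpm = 60, min_prominence = 0.1,
                              normalize = FALSE) {
  stopifnot(inherits(resp, "waveform"))
  if (normalize) resp <- normalize01(resp)
  min_dist <- max(1L, round(60 / rr_max_bpm * resp$fs))
  idx <- find_peaks(resp$samples, min_distance = min_dist,
                    min_prominence = min_prominence)
  resp$t0 + (idx - 1) / resp$fs
}

#' Respiratory rate of one window by peak counting
#'
#' `RR = n_peaks * 60 / T` with `n_peaks` the number of respiratory peaks
#' falling in the half-open window `[start_s, end_s)` of length `T` seconds.
#'
#' @param peak_times Respiratory peak times in seconds.
#' @param start_s,end_s Window boundaries in seconds (`end_s > start_s`).
#' @param window_index Optional window label.
#' @return An object of class `window_rr`: list with `window_index`,
#'   `n_peaks`, `T`, `rr_bpm`.
#' @examples
#' rr_from_window(seq(1.5, 29.5, by = 3), 0, 30)$rr_bpm  # 20 breaths/min
#' @export
rr_from_window <- function(peak_times, start_s, end_s, window_index = 1L) {
  if (end_s <= start_s) stop("window must have positive length", call. = FALSE)
  T <- end_s - start_s
  n_peaks <- sum(peak_times >= start_s & peak_times < end_s)
  structure(list(window_index = window_index, n_peaks = n_peaks, T = T,
                 rr_bpm = n_peaks * 60 / T),
            class = "window_rr")
}

#' Per-window respiratory rate over a window grid
#'
#' Applies [detect_resp_peaks()] once to the whole surrogate and counts peaks
#' per half-open window, so each peak is assigned to exactly one window.
#' Windows extending beyond the surrogate's span simply use the peaks it
#' covers.
#'
#' @param resp A [waveform] or `derived_respiration`.
#' @param grid A `window_grid` from [segment_windows()].
#' @param ... Passed to [detect_resp_peaks()].
#' @return A data frame with columns `window_index`, `start_s`, `end_s`,
#'   `n_peaks`, `rr_bpm`.
#' @export
rr_timeseries <- function(resp, grid, ...) {
  stopifnot(inherits(grid, "window_grid"))
  peaks <- detect_resp_peaks(resp, ...)
  b <- grid$boundaries
  out <- lapply(seq_len(nrow(b)), function(i) {
    wr <- rr_from_window(peaks, b$start_s[i], b$end_s[i], b$window_index[i])
    data.frame(window_index = wr$window_index, start_s = b$start_s[i],
               end_s = b$end_s[i], n_peaks = wr$n_peaks, rr_bpm = wr$rr_bpm)
  })
  do.call(rbind, out)
}
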