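#' Segment a record into fixed analysis windows
#'
#' Tiles `[0, n * T)` with contiguous, non-overlapping, half-open windows of
#' length `window_length_s`; a trailing remainder shorter than one window is
#' discarded. Windows are defined in seconds, so channels of different
#' sampling rates align by time.
#'
#' @param record_duration_s Record duration in seconds.
#' @param window_length_s Window length in seconds (default 30; the pipeline
#'   was designed around 20/30/60 s windows).
#' @return An object of class `window_grid`: list with `window_length_s`,
#'   `n_windows`, and a data frame `boundaries` with columns `window_index`,
#'   `start_s`, `end_s` (half-open `[start_s, end_s)`).
#' @examples
#' segment_windows(300, 30)$n_windows  # 10
#' @export
segment_windows <- function(record_duration_s, window_length_s = 30) {
  if (!is.numeric(record_duration_s) || record_duration_s <= 0) {
    stop("'record_duration_s' must be positive", call. = FALSE)
  }
  if (!is.numeric(window_length_s) || window_length_s <= 0) {
    stop("'window_length_s' must be positive", call. = FALSE)
  }
  if (record_duration_s < window_length_s) {
    stop("record (", record_duration_s, " s) is shorter than one window (",
         window_length_s, " s); use a shorter window", call. = FALSE)
  }
  n <- floor(record_duration_s / window_length_s)
  k <- seq_len(n) - 1
  structure(
    list(window_length_s = window_length_s,
         n_windows = n,
         boundaries = data.frame(window_index = k + 1,
                                 start_s = k * window_length_s,
                                 end_s = (k + 1) * window_length_s)),
    class = "window_grid"
  )
}

#' @export
print.window_grid <- function(x, ...) {
  cat(sprintf("<window_grid> %d windows of %g s covering [0, %g) s\n",
              x$n_windows, x$window_length_s,
              x$n_windows * x$window_length_s))
  invisible(x)
}

#' Extract the samples of one window from a waveform
#'
#' Half-open membership by time: sample `i` belongs to the window if
#' `start <= t_i < end`.
#'
#' @param w A [waveform].
#' @param start_s,end_s Window boundaries in seconds.
#' @return A [waveform] holding the window's samples with `t0 = ` time of its
#'   first retained sample.
#' @export
window_slice <- function(w, start_s, end_s) {
  stopifnot(inherits(w, "waveform"), end_s > start_s)
  tt <- sample_times(w)
  keep <- which(tt >= start_s & tt < end_s)
  if (length(keep) == 0L) stop("window contains no samples", call. = FALSE)
  waveform(w$samples[keep], fs = w$fs, t0 = tt[keep[1]], label = w$label)
}
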