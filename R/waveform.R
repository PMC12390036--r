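#' Uniformly sampled waveform
#'
#' Container for a single uniformly sampled channel. The time of sample `i`
#' (1-based) is `t0 + (i - 1) / fs`.
#'
#' @param samples Numeric vector of finite sample values.
#' @param fs Sampling frequency in Hz (> 0).
#' @param t0 Time of the first sample in seconds (default 0).
#' @param label Channel label.
#' @return An object of class `waveform`: a list with elements `samples`,
#'   `fs`, `t0`, `label`.
#' @examples
#' w <- waveform(sin(2 * pi * 1 * seq(0, 1, by = 0.01)), fs = 100)
#' duration(w)
#' @export
waveform <- function(samples, fs, t0 = 0, label = "signal") {
  if (!is.numeric(samples) || length(samples) == 0L) {
    stop("'samples' must be a non-empty numeric vector", call. = FALSE)
  }
  if (!all(is.finite(samples))) {
    stop("'samples' must be finite", call. = FALSE)
  }
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0) {
    stop("'fs' must be a single positive number", call. = FALSE)
  }
  structure(
    list(samples = as.numeric(samples), fs = as.numeric(fs),
         t0 = as.numeric(t0), label = as.character(label)),
    class = "waveform"
  )
}

#' @export
print.waveform <- function(x, ...) {
  cat(sprintf("<waveform> %s: %d samples @ %g Hz, t = [%g, %g] s\n",
              x$label, length(x$samples), x$fs, x$t0,
              x$t0 + (length(x$samples) - 1) / x$fs))
  invisible(x)
}

#' Waveform duration in seconds
#'
#' Duration counted as `n / fs`, i.e. each sample owns one sample period.
#'
#' @param w A [waveform].
#' @return Duration in seconds.
#' @export
duration <- function(w) {
  stopifnot(inherits(w, "waveform"))
  length(w$samples) / w$fs
}

#' Sample times of a waveform
#'
#' @param w A [waveform].
#' @return Numeric vector of sample times in seconds.
#' @export
sample_times <- function(w) {
  stopifnot(inherits(w, "waveform"))
  w$t0 + (seq_along(w$samples) - 1) / w$fs
}

#' Min-max normalization to \[0, 1\]
#'
#' Rescales a waveform as `(x - min) / (max - min)`. A constant input has no
#' range to rescale; it maps to all zeros and a warning is emitted so batch
#' runs survive dead channels.
#'
#' @param w A [waveform].
#' @return A [waveform] with samples in \[0, 1\].
#' @examples
#' normalize01(waveform(c(2, 4, 6), fs = 1))$samples  # 0, 0.5, 1
#' @export
normalize01 <- function(w) {
  stopifnot(inherits(w, "waveform"))
  x <- w$samples
  rng <- range(x)
  if (rng[1] == rng[2]) {
    warning("constant signal: normalize01 returns all zeros", call. = FALSE)
    w$samples <- rep(0, length(x))
  } else {
    w$samples <- (x - rng[1]) / (rng[2] - rng[1])
  }
  w
}

## Zero-phase filtering with symmetric-reflection edge padding, so that
## filter start-up transients land in the discarded pad rather than in the
## record and an extremum touching a record edge keeps its location. The pad
## must outlast the transient of the slowest pole, which for the corner
## frequencies used here is well under 2 s.
filtfilt_padded <- function(bf, x, fs) {
  n <- length(x)
  p <- min(n - 1L, as.integer(round(2 * fs)))
  ext <- c(x[(p + 1):2], x, x[(n - 1):(n - p)])
  y <- as.numeric(signal::filtfilt(bf, ext))
  y[(p + 1):(p + n)]
}

#' Bundle of simultaneously recorded channels
#'
#' @param subject_id Subject identifier.
#' @param ecg,ppg,resp_ref Optional [waveform] channels; at least one must be
#'   present. Channels may differ in sampling rate but must share `t0` and
#'   duration to within one sample period of the coarser channel.
#' @return An object of class `record_bundle`.
#' @export
record_bundle <- function(subject_id, ecg = NULL, ppg = NULL, resp_ref = NULL) {
  chans <- Filter(Negate(is.null), list(ecg = ecg, ppg = ppg, resp_ref = resp_ref))
  if (length(chans) == 0L) {
    stop("record_bundle needs at least one channel", call. = FALSE)
  }
  for (ch in chans) stopifnot(inherits(ch, "waveform"))
  t0s <- vapply(chans, function(ch) ch$t0, numeric(1))
  durs <- vapply(chans, duration, numeric(1))
  tol <- max(vapply(chans, function(ch) 1 / ch$fs, numeric(1)))
  if (diff(range(t0s)) > tol || diff(range(durs)) > tol) {
    stop("channels must share t0 and duration within one sample period",
         call. = FALSE)
  }
  structure(
    list(subject_id = as.character(subject_id),
         ecg = ecg, ppg = ppg, resp_ref = resp_ref),
    class = "record_bundle"
  )
}

#' @export
print.record_bundle <- function(x, ...) {
  cat(sprintf("<record_bundle> subject %s\n", x$subject_id))
  for (nm in c("ecg", "ppg", "resp_ref")) {
    if (!is.null(x[[nm]])) {
      cat("  "); print(x[[nm]])
    }
  }
  invisible(x)
}
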