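#' Per-beat feature series
#'
#' Values of one beat-by-beat feature at strictly increasing beat times; the
#' knot set from which a surrogate respiration waveform is reconstructed.
#'
#' @param feature Feature kind, one of `"r_amp"`, `"qrs_area"`, `"up_slope"`,
#'   `"down_slope"`, `"ppg_am"`, `"ppg_fm"`.
#' @param times Beat times in seconds, strictly increasing.
#' @param values Feature values, same length as `times`.
#' @return An object of class `beat_series`.
#' @export
beat_series <- function(feature, times, values) {
  feature <- match.arg(feature, c("r_amp", "qrs_area", "up_slope",
                                  "down_slope", "ppg_am", "ppg_fm"))
  if (length(times) != length(values)) {
    stop("'times' and 'values' must have equal length", call. = FALSE)
  }
  if (length(times) > 1L && any(diff(times) <= 0)) {
    stop("'times' must be strictly increasing", call. = FALSE)
  }
  structure(list(feature = feature, times = as.numeric(times),
                 values = as.numeric(values)),
            class = "beat_series")
}

#' @export
print.beat_series <- function(x, ...) {
  cat(sprintf("<beat_series> %s: %d beats over [%g, %g] s\n",
              x$feature, length(x$times),
              if (length(x$times)) min(x$times) else NA,
              if (length(x$times)) max(x$times) else NA))
  invisible(x)
}

#' Zero-phase band-pass conditioning of the ECG
#'
#' 4th-order Butterworth band-pass (default passband 5-40 Hz) applied
#' forward-backward, removing baseline wander and P/T-wave energy below the
#' low corner and high-frequency noise above the high corner while leaving
#' QRS timing unshifted.
#'
#' @param ecg A [waveform].
#' @param low_hz,high_hz Passband corners in Hz.
#' @param order Filter order (default 4).
#' @return A filtered [waveform] of the same length.
#' @export
bandpass_ecg <- function(ecg, low_hz = 5, high_hz = 40, order = 4) {
  stopifnot(inherits(ecg, "waveform"))
  if (ecg$fs <= 2 * high_hz) {
    stop("sampling rate ", ecg$fs, " Hz too low for a ", high_hz,
         " Hz passband edge", call. = FALSE)
  }
  bf <- signal::butter(order, c(low_hz, high_hz) / (ecg$fs / 2), type = "pass")
  ecg$samples <- filtfilt_padded(bf, ecg$samples, ecg$fs)
  ecg
}

#' QRS detection (Pan-Tompkins)
#'
#' Classic Pan-Tompkins chain on a band-passed ECG: five-point derivative,
#' squaring, 150 ms moving-window integration, then adaptive dual thresholds
#' on the integrated signal with a 200 ms refractory period and a searchback
#' pass at 1.66 times the running RR average. Each accepted fiducial is
#' refined to the local maximum of the filtered ECG within `refine_ms` of the
#' (delay-compensated) integrator fiducial.
#'
#' @param ecg_filtered A band-passed ECG [waveform] of at least 2 s.
#' @param refine_ms Half-width of the R-refinement window in ms (default 50).
#' @return Integer vector of R-peak sample indices (1-based), strictly
#'   increasing; empty when no beats are found.
#' @export
detect_qrs <- function(ecg_filtered, refine_ms = 50) {
  stopifnot(inherits(ecg_filtered, "waveform"))
  x <- ecg_filtered$samples
  fs <- ecg_filtered$fs
  if (length(x) < 2 * fs) stop("need at least 2 s of signal", call. = FALSE)
  if (all(x == x[1])) return(integer(0))

  # five-point derivative: (2x[n] + x[n-1] - x[n-3] - 2x[n-4]) / 8,
  # clamping indices before the record start to the first sample
  lag <- function(v, k) c(rep(v[1], k), v[seq_len(length(v) - k)])
  d <- (2 * x + lag(x, 1) - lag(x, 3) - 2 * lag(x, 4)) / 8
  sq <- d^2
  # causal moving-window integration with partial-window normalization at
  # the record start, so early beats are not suppressed
  wlen <- max(1L, round(0.150 * fs))
  cs <- cumsum(sq)
  nwin <- pmin(seq_along(sq), wlen)
  mwi <- (cs - c(rep(0, wlen), cs[seq_len(length(sq) - wlen)])) / nwin
  # group delay: 2 samples (derivative) + (wlen - 1) / 2 (integrator)
  delay <- 2 + (wlen - 1) / 2

  refr <- round(0.200 * fs)
  cand <- find_peaks(mwi, min_distance = refr)
  if (length(cand) == 0L) return(integer(0))

  # adaptive thresholds initialised from the first 2 s, with a global floor
  # so that a quiet lead-in cannot arm the detector on filter ripple
  init <- mwi[seq_len(round(2 * fs))]
  spki <- 0.5 * max(init)
  npki <- 0.5 * mean(init)
  thr_floor <- 0.05 * as.numeric(stats::quantile(mwi, 0.99))
  thr <- function() max(npki + 0.25 * (spki - npki), thr_floor)

  qrs <- integer(0)
  rr_hist <- numeric(0)
  last_qrs <- -Inf
  i <- 1L
  while (i <= length(cand)) {
    p <- cand[i]
    accepted <- FALSE
    if (mwi[p] > thr() && (p - last_qrs) > refr) {
      spki <- 0.125 * mwi[p] + 0.875 * spki
      accepted <- TRUE
    } else {
      npki <- 0.125 * mwi[p] + 0.875 * npki
    }
    if (!accepted && length(rr_hist) >= 2L && is.finite(last_qrs)) {
      # searchback: if the expected beat is overdue, accept the largest
      # missed candidate above half threshold
      rr_avg <- mean(utils::tail(rr_hist, 8))
      if ((p - last_qrs) > 1.66 * rr_avg && mwi[p] > 0.5 * thr()) {
        spki <- 0.25 * mwi[p] + 0.75 * spki
        accepted <- TRUE
      }
    }
    if (accepted) {
      if (is.finite(last_qrs)) rr_hist <- c(rr_hist, p - last_qrs)
      last_qrs <- p
      qrs <- c(qrs, p)
    }
    i <- i + 1L
  }
  if (length(qrs) == 0L) return(integer(0))

  # refine to the local maximum of the filtered ECG near the compensated
  # integrator fiducial
  half <- round(refine_ms / 1000 * fs)
  n <- length(x)
  r_idx <- vapply(qrs, function(p) {
    c0 <- max(1L, min(n, as.integer(round(p - delay))))
    lo <- max(1L, c0 - half)
    hi <- min(n, c0 + half)
    as.integer(lo + which.max(x[lo:hi]) - 1L)
  }, integer(1))
  r_idx <- sort(unique(r_idx))
  # enforce refractory after refinement (earlier beat wins)
  if (length(r_idx) > 1L) {
    keep <- c(TRUE, diff(r_idx) > refr)
    while (!all(keep)) {
      r_idx <- r_idx[keep]
      keep <- c(TRUE, diff(r_idx) > refr)
    }
  }
  r_idx
}

#' Locate Q and S troughs around an R peak
#'
#' Q is the minimum of the filtered ECG in the `search_ms` window before the
#' R sample, S the minimum in the window after; windows are clipped at the
#' record edges, and an empty window collapses onto the R sample itself.
#' Ties break toward the earliest index.
#'
#' @param ecg_filtered A band-passed ECG [waveform].
#' @param r_idx R-peak sample index (1-based).
#' @param search_ms Search half-width in milliseconds (default 100).
#' @return An object of class `qrs_complex`: list with `q_idx`, `r_idx`,
#'   `s_idx` satisfying `q_idx <= r_idx <= s_idx`.
#' @export
locate_qs <- function(ecg_filtered, r_idx, search_ms = 100) {
  stopifnot(inherits(ecg_filtered, "waveform"))
  x <- ecg_filtered$samples
  n <- length(x)
  if (r_idx < 1L || r_idx > n) stop("r_idx out of range", call. = FALSE)
  w <- round(search_ms / 1000 * ecg_filtered$fs)
  lo <- max(1L, r_idx - w)
  q_idx <- if (lo < r_idx) {
    cand <- lo:(r_idx - 1L)
    cand[which.min(x[cand])]
  } else r_idx
  hi <- min(n, r_idx + w)
  s_idx <- if (hi > r_idx) {
    cand <- (r_idx + 1L):hi
    cand[which.min(x[cand])]
  } else r_idx
  structure(list(q_idx = as.integer(q_idx), r_idx = as.integer(r_idx),
                 s_idx = as.integer(s_idx)),
            class = "qrs_complex")
}

#' R-peak amplitude of a QRS complex
#'
#' The maximum of the signal over the QRS span `[q_idx, s_idx]` (a signed
#' maximum, not an absolute value).
#'
#' @param x A [waveform].
#' @param qrs A `qrs_complex` from [locate_qs()].
#' @return The feature value.
#' @export
feature_r_amplitude <- function(x, qrs) {
  stopifnot(inherits(x, "waveform"), inherits(qrs, "qrs_complex"))
  max(x$samples[qrs$q_idx:qrs$s_idx])
}

#' QRS up-slope
#'
#' Maximum absolute first difference on the rising limb, over sample pairs
#' `(j - 1, j)` with `j` in `(q_idx, r_idx]`. Units are signal units per
#' sample (multiply by `fs` for units per second); the surrogate-respiration
#' pipeline is invariant to this scaling. Degenerate `q_idx == r_idx`
#' returns 0.
#'
#' @inheritParams feature_r_amplitude
#' @return The feature value.
#' @export
feature_up_slope <- function(x, qrs) {
  stopifnot(inherits(x, "waveform"), inherits(qrs, "qrs_complex"))
  if (qrs$q_idx >= qrs$r_idx) return(0)
  seg <- x$samples[qrs$q_idx:qrs$r_idx]
  max(abs(diff(seg)))
}

#' QRS down-slope
#'
#' Maximum absolute first difference on the falling limb, over sample pairs
#' `(j, j + 1)` with `j` in `[r_idx, s_idx)`. Degenerate `r_idx == s_idx`
#' returns 0.
#'
#' @inheritParams feature_r_amplitude
#' @return The feature value.
#' @export
feature_down_slope <- function(x, qrs) {
  stopifnot(inherits(x, "waveform"), inherits(qrs, "qrs_complex"))
  if (qrs$r_idx >= qrs$s_idx) return(0)
  seg <- x$samples[qrs$r_idx:qrs$s_idx]
  max(abs(diff(seg)))
}

#' QRS area (sum of absolute Q-, R-, and S-wave areas)
#'
#' The QRS span is referenced to a local baseline (the median over
#' `[q_idx, s_idx]`) and partitioned into Q, R, and S lobes at the
#' baseline crossings nearest the R peak on each side (midpoint fallback when
#' a limb never crosses). Each lobe's area is the trapezoidal integral of the
#' baseline-referenced signal over the lobe, in signal-units x seconds; the
#' feature is the sum of their absolute values.
#'
#' @inheritParams feature_r_amplitude
#' @return The feature value (>= 0).
#' @export
feature_qrs_area <- function(x, qrs) {
  stopifnot(inherits(x, "waveform"), inherits(qrs, "qrs_complex"))
  q <- qrs$q_idx; r <- qrs$r_idx; s <- qrs$s_idx
  if (q == s) return(0)
  y <- x$samples[q:s] - stats::median(x$samples[q:s])
  # positions within the segment (1-based)
  rp <- r - q + 1L
  np <- length(y)
  b1 <- crossing_before(y, rp)              # Q | R boundary
  b2 <- crossing_after(y, rp, np)           # R | S boundary
  dt <- 1 / x$fs
  abs(trapz_seg(y, 1L, b1, dt)) + abs(trapz_seg(y, b1, b2, dt)) +
    abs(trapz_seg(y, b2, np, dt))
}

## largest j <= rp with y[j] * y[rp] <= 0 (crossing closest to R on the Q
## side); midpoint fallback
crossing_before <- function(y, rp) {
  for (j in seq(rp, 1L)) {
    if (y[j] * y[rp] <= 0) return(j)
  }
  as.integer(floor((1L + rp) / 2))
}

## smallest j >= rp with y[j] * y[rp] <= 0; midpoint fallback
crossing_after <- function(y, rp, np) {
  for (j in seq(rp, np)) {
    if (y[j] * y[rp] <= 0) return(j)
  }
  as.integer(ceiling((rp + np) / 2))
}

trapz_seg <- function(y, i0, i1, dt) {
  if (i1 <= i0) return(0)
  seg <- y[i0:i1]
  sum((seg[-1] + seg[-length(seg)]) / 2) * dt
}

#' Extract a per-beat morphological feature series from a conditioned ECG
#'
#' Runs [detect_qrs()], locates Q/S around each R peak, and evaluates the
#' chosen feature beat by beat. Beat times are the R-peak sample times.
#'
#' @param ecg_filtered A band-passed ECG [waveform] (see [bandpass_ecg()]).
#' @param feature One of `"r_amp"`, `"qrs_area"`, `"up_slope"`,
#'   `"down_slope"`.
#' @param search_ms Q/S search half-width in ms (default 100).
#' @return A [beat_series].
#' @export
extract_feature_series <- function(ecg_filtered,
                                   feature = c("r_amp", "qrs_area",
                                               "up_slope", "down_slope"),
                                   search_ms = 100) {
  feature <- match.arg(feature)
  r_idx <- detect_qrs(ecg_filtered)
  if (length(r_idx) < 3L) {
    stop("fewer than 3 beats detected; cannot build a feature series",
         call. = FALSE)
  }
  fop <- switch(feature,
                r_amp = feature_r_amplitude,
                qrs_area = feature_qrs_area,
                up_slope = feature_up_slope,
                down_slope = feature_down_slope)
  vals <- vapply(r_idx, function(r) {
    fop(ecg_filtered, locate_qs(ecg_filtered, r, search_ms))
  }, numeric(1))
  beat_series(feature,
              times = ecg_filtered$t0 + (r_idx - 1) / ecg_filtered$fs,
              values = vals)
}
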