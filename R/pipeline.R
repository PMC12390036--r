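#' ECG-derived respiration (EDR)
#'
#' Full ECG branch: zero-phase 5-40 Hz band-pass, Pan-Tompkins QRS detection,
#' per-beat morphological feature extraction, and natural cubic-spline
#' reconstruction of the surrogate respiration.
#'
#' @param ecg A raw ECG [waveform].
#' @param feature One of `"r_amp"`, `"qrs_area"`, `"up_slope"`,
#'   `"down_slope"`.
#' @param fs_out Surrogate sampling rate in Hz (default 4).
#' @param ... Passed to [bandpass_ecg()].
#' @return A `derived_respiration`.
#' @export
derive_edr <- function(ecg, feature = "r_amp", fs_out = 4, ...) {
  filt <- bandpass_ecg(ecg, ...)
  spline_reconstruct(extract_feature_series(filt, feature), fs_out = fs_out)
}

#' PPG-derived respiration (PDR)
#'
#' Full PPG branch: zero-phase 8th-order Butterworth low-pass at 10 Hz,
#' 11-level wavelet smoothing, Savitzky-Golay smoothing, systolic extrema
#' detection, AM (pulse amplitude) or FM (beat interval) series, and natural
#' cubic-spline reconstruction.
#'
#' @param ppg A raw PPG [waveform].
#' @param feature `"am"` or `"fm"`.
#' @param fs_out Surrogate sampling rate in Hz (default 4).
#' @param wavelet_levels Wavelet decomposition depth (default 11).
#' @param savgol_window_ms Savitzky-Golay window in ms (default 250).
#' @return A `derived_respiration`.
#' @export
derive_pdr <- function(ppg, feature = c("am", "fm"), fs_out = 4,
                       wavelet_levels = 11, savgol_window_ms = 250) {
  feature <- match.arg(feature)
  sm <- savgol_smooth(wavelet_smooth(lowpass_ppg(ppg),
                                     levels = wavelet_levels),
                      window_ms = savgol_window_ms)
  ex <- detect_pulse_extrema(sm)
  series <- if (feature == "am") am_series(sm, ex)
            else fm_series(ex, fs = sm$fs, t0 = sm$t0)
  spline_reconstruct(series, fs_out = fs_out)
}

#' Windowed respiratory rate from a raw channel
#'
#' One-call pipeline: derive the surrogate respiration from an ECG or PPG
#' channel (or take a reference respiration channel as-is), segment the
#' record into fixed windows, and count respiratory peaks per window.
#'
#' @param w A raw [waveform].
#' @param method `"r_amp"`, `"qrs_area"`, `"up_slope"`, `"down_slope"` (ECG
#'   features), `"am"`, `"fm"` (PPG features), or `"reference"` (treat `w` as
#'   the respiration signal itself).
#' @param window_length_s Analysis window length in seconds (default 30).
#' @param ... Passed to the deriving function.
#' @return A data frame as from [rr_timeseries()].
#' @examples
#' spec <- modulation_spec(120, fs = 250, hr_bpm = 70, rr_bpm = 15,
#'                         am_depth = 0.2)
#' rec <- generate_ecg(spec)
#' estimate_rr(rec$ecg, method = "r_amp")
#' @export
estimate_rr <- function(w, method = "r_amp", window_length_s = 30, ...) {
  method <- match.arg(method, c("r_amp", "qrs_area", "up_slope", "down_slope",
                                "am", "fm", "reference"))
  resp <- switch(method,
                 am = , fm = derive_pdr(w, feature = method, ...),
                 reference = normalize01(w),
                 derive_edr(w, feature = method, ...))
  grid <- segment_windows(duration(w), window_length_s)
  rr_timeseries(resp, grid)
}
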