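Package: rrwave
Title: Respiratory Rate Estimation from ECG and PPG Waveforms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates respiratory rate from electrocardiogram (ECG) and
    photoplethysmogram (PPG) recordings via beat-by-beat morphological and
    temporal features. Conditions the ECG (5-40 Hz zero-phase band-pass),
    detects QRS complexes with a Pan-Tompkins detector, and extracts four
    per-beat features (R-peak amplitude, QRS up-slope, down-slope, and
    trapezoidal QRS area); conditions the PPG (Butterworth low-pass, wavelet
    and Savitzky-Golay smoothing) and extracts pulse-amplitude (AM) and
    beat-interval (FM) series. Each feature series is turned into a surrogate
    respiration waveform by natural cubic-spline interpolation, and
    respiratory rate is computed per analysis window by peak counting.
    Includes an agreement-evaluation suite (MAE, MAPE, RMSE, Pearson
    correlation with interpretation bands, exact Wilcoxon signed-rank,
    Bland-Altman limits of agreement, intra-/inter-subject aggregation) and a
    synthetic cardiorespiratory signal generator with controllable amplitude,
    baseline-wander, and frequency (respiratory sinus arrhythmia) modulation
    for end-to-end validation against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
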