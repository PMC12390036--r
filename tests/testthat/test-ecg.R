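test_that("band-pass rejects DC and baseline wander, passes the QRS band", {
  fs <- 300
  t <- seq(0, 20, by = 1 / fs)
  # constant input -> ~0
  const <- bandpass_ecg(waveform(rep(2, length(t)), fs))
  expect_lt(max(abs(const$samples)), 1e-6 * 2)
  rms <- function(v) sqrt(mean(v^2))
  # 20 Hz tone passes (evaluate away from edges)
  tone <- sin(2 * pi * 20 * t)
  y <- bandpass_ecg(waveform(tone, fs))$samples
  mid <- seq(2 * fs, length(t) - 2 * fs)
  expect_lt(abs(rms(y[mid]) / rms(tone[mid]) - 1), 0.05)
  # 0.3 Hz baseline attenuated >= 20 dB
  bw <- sin(2 * pi * 0.3 * t)
  yb <- bandpass_ecg(waveform(bw, fs))$samples
  expect_lt(20 * log10(rms(yb[mid]) / rms(bw[mid])), -20)
  expect_error(bandpass_ecg(waveform(tone, fs = 60)), "too low")
})

test_that("QRS detector recovers clean and noisy synthetic beats", {
  fs <- 300
  rec <- quick_ecg(duration_s = 60, hr_bpm = 60, noise_sd = 0)
  r <- detect_qrs(bandpass_ecg(rec$ecg))
  expect_lte(abs(length(r) - 60), 1)
  tt <- (r - 1) / fs
  match_err <- vapply(rec$beat_times_true,
                      function(b) min(abs(tt - b)), numeric(1))
  expect_true(all(match_err <= 0.05))
  # empty results, not errors, on degenerate input
  expect_length(detect_qrs(waveform(rep(0, 10 * fs), fs)), 0)
  # 10% noise: sensitivity and PPV >= 99%
  recn <- quick_ecg(duration_s = 60, hr_bpm = 75, noise_sd = 0.1)
  rn <- detect_qrs(bandpass_ecg(recn$ecg))
  ttn <- (rn - 1) / fs
  truth <- recn$beat_times_true
  se <- mean(vapply(truth, function(b) any(abs(ttn - b) <= 0.1), logical(1)))
  ppv <- mean(vapply(ttn, function(d) any(abs(truth - d) <= 0.1), logical(1)))
  expect_gte(se, 0.99)
  expect_gte(ppv, 0.99)
})

test_that("Q/S localization follows the argmin-in-window convention", {
  fs <- 1000  # 100 ms window = 100 samples
  x <- rep(0, 60)
  x[c(24, 25, 26)] <- c(-0.2, 1.0, -0.3)
  w <- waveform(x, fs = fs)
  qrs <- locate_qs(w, 25, search_ms = 3)
  expect_equal(qrs$q_idx, 24)
  expect_equal(qrs$s_idx, 26)
  # monotone rise into R: q = window start (global min of the window)
  x2 <- c(seq(0, 1, length.out = 30), rep(0, 10))
  qrs2 <- locate_qs(waveform(x2, fs), 30, search_ms = 10)
  expect_equal(qrs2$q_idx, 20)
  # R at sample 1: empty left window collapses to r_idx
  qrs3 <- locate_qs(waveform(c(1, 0.5, 0), fs), 1, search_ms = 2)
  expect_equal(qrs3$q_idx, 1)
  expect_equal(qrs3$r_idx, 1)
})

make_qrs <- function(q, r, s) {
  structure(list(q_idx = q, r_idx = r, s_idx = s), class = "qrs_complex")
}

test_that("feature operators match their hand-computed examples", {
  w <- waveform(c(0, 0.2, 1.0, 0.1, -0.3), fs = 1)
  qrs <- make_qrs(1L, 3L, 5L)
  expect_equal(feature_r_amplitude(w, qrs), 1.0)
  expect_equal(feature_up_slope(w, qrs), 0.8)
  expect_equal(feature_down_slope(w, qrs), 0.9)
  # max, not |max|
  wneg <- waveform(c(-3, -1, -2), fs = 1)
  expect_equal(feature_r_amplitude(wneg, make_qrs(1L, 2L, 3L)), -1)
  # degenerate windows
  expect_equal(feature_up_slope(w, make_qrs(3L, 3L, 5L)), 0)
  expect_equal(feature_down_slope(w, make_qrs(1L, 3L, 3L)), 0)
  # triangle-lobe area example: baseline median is 0, lobes 1 + 2 + 1
  wa <- waveform(c(0, -1, 0, 2, 0, -1, 0), fs = 1)
  expect_equal(feature_qrs_area(wa, make_qrs(1L, 4L, 7L)), 4)
  expect_equal(feature_qrs_area(waveform(rep(0, 7), 1), make_qrs(1L, 4L, 7L)), 0)
})

test_that("feature operators equal brute-force loops on random QRS windows", {
  # independent re-implementations as plain loops
  bf_up <- function(x, q, r) {
    if (q >= r) return(0)
    m <- 0
    for (j in (q + 1):r) m <- max(m, abs(x[j] - x[j - 1]))
    m
  }
  bf_down <- function(x, r, s) {
    if (r >= s) return(0)
    m <- 0
    for (j in r:(s - 1)) m <- max(m, abs(x[j + 1] - x[j]))
    m
  }
  bf_rmax <- function(x, q, s) {
    m <- -Inf
    for (j in q:s) m <- max(m, x[j])
    m
  }
  set.seed(7)
  for (i in 1:300) {
    n <- sample(3:50, 1)
    x <- round(stats::rnorm(n), 3)
    q <- 1L
    s <- as.integer(n)
    r <- sample(seq.int(q, s), 1)
    w <- waveform(x, fs = sample(c(1, 250, 1000), 1))
    qrs <- make_qrs(q, r, s)
    expect_identical(feature_r_amplitude(w, qrs), bf_rmax(x, q, s))
    expect_identical(feature_up_slope(w, qrs), bf_up(x, q, r))
    expect_identical(feature_down_slope(w, qrs), bf_down(x, r, s))
  }
})

test_that("qrs_area scales linearly with amplitude", {
  set.seed(11)
  x <- stats::rnorm(31)
  w1 <- waveform(x, fs = 100)
  w2 <- waveform(3.7 * x, fs = 100)
  qrs <- make_qrs(1L, 16L, 31L)
  expect_equal(feature_qrs_area(w2, qrs), 3.7 * feature_qrs_area(w1, qrs),
               tolerance = 1e-12)
})

test_that("amplitude and time-shift equivariance of the feature pipeline", {
  rec0 <- quick_ecg(duration_s = 31, am_depth = 0.2, noise_sd = 0)
  # slice away the record edges so every beat's template is fully supported
  ecg <- window_slice(rec0$ecg, 0.5, 30.5)
  ecg$t0 <- 0
  filt <- bandpass_ecg(ecg)
  bs1 <- extract_feature_series(filt, "r_amp")
  # scaling the ECG by c scales r_amp by c, fiducials unchanged
  scaled <- filt
  scaled$samples <- 2.5 * scaled$samples
  bs2 <- extract_feature_series(scaled, "r_amp")
  expect_equal(bs2$times, bs1$times)
  expect_equal(bs2$values, 2.5 * bs1$values, tolerance = 1e-9)
  # prepending k seconds of zeros shifts beat times by k (+/- one sample);
  # match each original beat to its nearest shifted counterpart
  k <- 2
  padded <- waveform(c(rep(0, k * ecg$fs), ecg$samples),
                     fs = ecg$fs, label = "ecg")
  bs3 <- extract_feature_series(bandpass_ecg(padded), "r_amp")
  shift_err <- vapply(bs1$times,
                      function(b) min(abs(bs3$times - k - b)), numeric(1))
  expect_true(all(shift_err <= 1 / ecg$fs + 1e-9))
})

test_that("beat-feature series carries the respiratory modulation", {
  rec <- quick_ecg(duration_s = 120, rr_bpm = 15, am_depth = 0.2,
                   noise_sd = 0)
  bs <- extract_feature_series(bandpass_ecg(rec$ecg), "r_amp")
  expect_equal(length(bs$values), length(rec$beat_times_true))
  f <- dominant_freq(bs$times, bs$values)
  expect_lt(abs(f - 0.25), 4 / 120)
  expect_error(extract_feature_series(
    bandpass_ecg(waveform(rep(0, 600), 300))), "fewer than 3")
})

test_that("beat-count recovery holds across heart rates", {
  for (hr in c(50, 75, 100, 120)) {
    rec <- quick_ecg(duration_s = 30, hr_bpm = hr, noise_sd = 0)
    r <- detect_qrs(bandpass_ecg(rec$ecg))
    expect_lte(abs(length(r) - length(rec$beat_times_true)), 1)
  }
})
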