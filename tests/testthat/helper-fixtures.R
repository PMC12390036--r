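# Shared fixtures: small, fast synthetic records.

quick_spec <- function(duration_s = 60, fs = 300, hr_bpm = 70, rr_bpm = 15,
                       am_depth = 0.2, bw_amp = 0, fm_depth = 0,
                       noise_sd = 0, seed = 101, rr_end_bpm = NULL) {
  modulation_spec(duration_s, fs, hr_bpm = hr_bpm, rr_bpm = rr_bpm,
                  am_depth = am_depth, bw_amp = bw_amp, fm_depth = fm_depth,
                  noise_sd = noise_sd, seed = seed, rr_end_bpm = rr_end_bpm)
}

quick_ecg <- function(...) suppressMessages(generate_ecg(quick_spec(...)))
quick_ppg <- function(...) suppressMessages(generate_ppg(quick_spec(...)))

# dominant nonzero frequency of a series sampled at (possibly irregular)
# times: DFT of the values resampled by linear interpolation onto a uniform
# grid; used as an independent spectral oracle
dominant_freq <- function(times, values, fs_grid = 4) {
  g <- seq(min(times), max(times), by = 1 / fs_grid)
  y <- stats::approx(times, values, xout = g)$y
  y <- y - mean(y)
  sp <- Mod(stats::fft(y))^2
  n <- length(y)
  freqs <- (seq_len(n) - 1) * fs_grid / n
  half <- 2:floor(n / 2)
  freqs[half][which.max(sp[half])]
}

# independent enumeration oracle for the exact signed-rank null: two-sided
# p over all 2^m sign assignments of the midranks
wilcoxon_enum <- function(d) {
  d <- d[d != 0]
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  mu <- sum(r) / 2
  m <- length(d)
  hits <- 0L
  for (mask in 0:(2^m - 1)) {
    bits <- as.integer(intToBits(mask))[1:m]
    if (abs(sum(r[bits == 1]) - mu) >= abs(W - mu) - 1e-9) hits <- hits + 1L
  }
  hits / 2^m
}

# brute-force local-extremum enumeration under the same distance/prominence
# rules as find_peaks(); independent reference for detector tests
peaks_bruteforce <- function(x, min_distance = 1, min_prominence = 0) {
  n <- length(x)
  cand <- integer(0)
  i <- 2L
  while (i < n) {
    if (x[i] > x[i - 1L]) {
      j <- i
      while (j < n && x[j + 1L] == x[j]) j <- j + 1L
      if (j < n && x[j + 1L] < x[j]) cand <- c(cand, i)
      i <- j + 1L
    } else i <- i + 1L
  }
  prom <- vapply(cand, function(p) {
    lmin <- x[p]; j <- p - 1L
    while (j >= 1L && x[j] <= x[p]) { lmin <- min(lmin, x[j]); j <- j - 1L }
    rmin <- x[p]; j <- p + 1L
    while (j <= n && x[j] <= x[p]) { rmin <- min(rmin, x[j]); j <- j + 1L }
    x[p] - max(lmin, rmin)
  }, numeric(1))
  ord <- order(-x[cand], cand)
  kept <- integer(0)
  keep <- logical(length(cand))
  for (k in ord) {
    if (all(abs(cand[k] - kept) >= min_distance)) {
      keep[k] <- TRUE
      kept <- c(kept, cand[k])
    }
  }
  sort(cand[keep & prom >= min_prominence])
}
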