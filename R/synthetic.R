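#' Specification of a synthetic cardiorespiratory record
#'
#' Describes the study conditions a synthetic record emulates: a subject with
#' mean heart rate `hr_bpm` breathing at `rr_bpm`, whose respiration modulates
#' the cardiovascular waveforms through three classical routes: amplitude
#' modulation (AM) of beat amplitude, baseline wander (BW), and frequency
#' modulation (FM) of the beat-to-beat period via respiratory sinus
#' arrhythmia.
#'
#' @param duration_s Record duration in seconds (> 0).
#' @param fs Sampling frequency in Hz (>= 100).
#' @param hr_bpm Mean heart rate, beats/min (20-220).
#' @param rr_bpm Respiratory rate, breaths/min (4-60). Must satisfy
#'   `1.5 * rr_bpm < hr_bpm` so the beat-sampled modulation is resolvable.
#' @param am_depth Fractional peak-amplitude modulation in \[0, 1).
#' @param bw_amp Baseline-wander amplitude (signal units).
#' @param fm_depth Fractional modulation of the instantaneous heart period in
#'   \[0, 1).
#' @param noise_sd Additive white Gaussian noise standard deviation.
#' @param seed Integer RNG seed; identical spec + seed gives bit-identical
#'   output.
#' @param rr_end_bpm Optional end respiratory rate: if given, the
#'   instantaneous rate ramps linearly from `rr_bpm` to `rr_end_bpm` over the
#'   record (emulating e.g. an exercise acceleration phase).
#' @return An object of class `modulation_spec`.
#' @export
modulation_spec <- function(duration_s, fs, hr_bpm = 70, rr_bpm = 15,
                            am_depth = 0, bw_amp = 0, fm_depth = 0,
                            noise_sd = 0, seed = 1L, rr_end_bpm = NULL) {
  chk <- function(cond, field, msg) {
    if (!cond) stop("invalid '", field, "': ", msg, call. = FALSE)
  }
  chk(is.numeric(duration_s) && duration_s > 0, "duration_s", "must be > 0")
  chk(is.numeric(fs) && fs >= 100, "fs", "must be >= 100 Hz")
  chk(is.numeric(hr_bpm) && hr_bpm >= 20 && hr_bpm <= 220, "hr_bpm",
      "must be in [20, 220] beats/min")
  rr_chk <- function(r, field) {
    chk(is.numeric(r) && r >= 4 && r <= 60, field,
        "must be in [4, 60] breaths/min")
    chk(r * 1.5 < hr_bpm, field,
        "needs hr_bpm > 1.5 * rr so beats resolve the breathing cycle")
  }
  rr_chk(rr_bpm, "rr_bpm")
  if (!is.null(rr_end_bpm)) rr_chk(rr_end_bpm, "rr_end_bpm")
  chk(is.numeric(am_depth) && am_depth >= 0 && am_depth < 1, "am_depth",
      "must be in [0, 1)")
  chk(is.numeric(bw_amp) && bw_amp >= 0, "bw_amp", "must be >= 0")
  chk(is.numeric(fm_depth) && fm_depth >= 0 && fm_depth < 1, "fm_depth",
      "must be in [0, 1) (period would become non-positive)")
  chk(is.numeric(noise_sd) && noise_sd >= 0, "noise_sd", "must be >= 0")
  chk(is.numeric(seed) && is.finite(seed), "seed", "must be an integer")
  structure(
    list(duration_s = duration_s, fs = fs, hr_bpm = hr_bpm, rr_bpm = rr_bpm,
         am_depth = am_depth, bw_amp = bw_amp, fm_depth = fm_depth,
         noise_sd = noise_sd, seed = as.integer(seed),
         rr_end_bpm = rr_end_bpm),
    class = "modulation_spec"
  )
}

#' @export
print.modulation_spec <- function(x, ...) {
  rr <- if (is.null(x$rr_end_bpm)) sprintf("%g", x$rr_bpm)
        else sprintf("%g -> %g (ramp)", x$rr_bpm, x$rr_end_bpm)
  cat(sprintf(
    "<modulation_spec> %g s @ %g Hz, hr %g bpm, rr %s breaths/min\n",
    x$duration_s, x$fs, x$hr_bpm, rr))
  cat(sprintf("  am %g, bw %g, fm %g, noise sd %g, seed %d\n",
              x$am_depth, x$bw_amp, x$fm_depth, x$noise_sd, x$seed))
  invisible(x)
}

## Respiratory phase in cycles at time t; integral of the instantaneous
## rate (breaths/s). Linear ramp when rr_end_bpm is set.
resp_phase <- function(spec, t) {
  r0 <- spec$rr_bpm / 60
  if (is.null(spec$rr_end_bpm)) {
    r0 * t
  } else {
    r1 <- spec$rr_end_bpm / 60
    r0 * t + (r1 - r0) * t^2 / (2 * spec$duration_s)
  }
}

## Respiration value r(t) = sin(2 pi * phase(t)), in [-1, 1].
resp_value <- function(spec, t) {
  sin(2 * pi * resp_phase(spec, t))
}

#' Ground-truth respiration waveform
#'
#' A unit sinusoid whose instantaneous frequency is the spec's respiratory
#' rate: `r(t) = sin(2 pi * phase(t))`. Exactly `floor(duration * rr / 60)`
#' full cycles begin within the record when the rate is constant.
#'
#' @param spec A [modulation_spec].
#' @return A [waveform] labelled `"resp"`.
#' @export
generate_respiration <- function(spec) {
  stopifnot(inherits(spec, "modulation_spec"))
  t <- seq(0, spec$duration_s - 1 / spec$fs, by = 1 / spec$fs)
  waveform(resp_value(spec, t), fs = spec$fs, t0 = 0, label = "resp")
}

#' Ground-truth beat times under respiratory sinus arrhythmia
#'
#' Beat times start at `t = 0` and advance by the instantaneous heart period
#' `p_k = (60 / hr_bpm) * (1 - fm_depth * r(t_k))`: the heart beats faster
#' when respiration is high (inspiration), the physiological sign of RSA.
#'
#' @param spec A [modulation_spec].
#' @return Strictly increasing numeric vector of beat times in seconds, all
#'   `< duration_s`.
#' @export
generate_beat_times <- function(spec) {
  stopifnot(inherits(spec, "modulation_spec"))
  p0 <- 60 / spec$hr_bpm
  # upper bound on beat count to preallocate
  n_max <- ceiling(spec$duration_s / (p0 * (1 - spec$fm_depth))) + 2L
  times <- numeric(n_max)
  t <- 0
  k <- 0L
  while (t < spec$duration_s) {
    k <- k + 1L
    times[k] <- t
    t <- t + p0 * (1 - spec$fm_depth * resp_value(spec, t))
  }
  times[seq_len(k)]
}

## Place Gaussian bumps around each center: for beat k with scale s_k the
## contribution at time t is sum_b amp_b * s_k * exp(-(t - c_k - off_b)^2 /
## (2 sd_b^2)). Evaluated only within +/- 4 sd of each bump.
place_bumps <- function(n, fs, centers, scales, offsets, sds, amps) {
  y <- numeric(n)
  for (b in seq_along(offsets)) {
    mu <- centers + offsets[b]
    half <- 4 * sds[b]
    i0 <- pmax(1L, as.integer(ceiling((mu - half) * fs)) + 1L)
    i1 <- pmin(n, as.integer(floor((mu + half) * fs)) + 1L)
    for (k in seq_along(centers)) {
      if (i1[k] < i0[k]) next
      idx <- i0[k]:i1[k]
      tt <- (idx - 1) / fs
      y[idx] <- y[idx] +
        amps[b] * scales[k] * exp(-(tt - mu[k])^2 / (2 * sds[b]^2))
    }
  }
  y
}

## ECG beat template: five Gaussians (P, Q, R, S, T).
ecg_template <- function() {
  list(offsets = c(-0.200, -0.025, 0, 0.025, 0.250),
       sds     = c(0.025, 0.010, 0.012, 0.010, 0.040),
       amps    = c(0.12, -0.15, 1.00, -0.25, 0.30))
}

## PPG pulse template: systolic peak + dicrotic bump, scaled to the mean
## heart period so the shape stays physiological across heart rates.
ppg_template <- function(hr_bpm) {
  p <- 60 / hr_bpm
  list(offsets = c(0.25, 0.55) * p,
       sds     = c(0.10, 0.14) * p,
       amps    = c(1.00, 0.30))
}

## Keep beats whose template (last bump center + 2 sd) fits in the record;
## the trailing partial beat is dropped with a message.
keep_full_beats <- function(beat_times, tmpl, duration_s, what) {
  tail_s <- max(tmpl$offsets + 2 * tmpl$sds)
  keep <- beat_times + tail_s <= duration_s
  if (any(!keep)) {
    message(sum(!keep), " trailing partial ", what,
            " beat(s) dropped at record end")
  }
  beat_times[keep]
}

## Evaluate a seeded expression without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

build_channel <- function(spec, tmpl, label, seed_offset) {
  beats_all <- generate_beat_times(spec)
  beats <- keep_full_beats(beats_all, tmpl, spec$duration_s, label)
  # snap template centers to the sample grid so each beat's apex falls
  # exactly on a sample (half-sample jitter is physiologically irrelevant
  # and keeps the zero-modulation amplitude series exactly constant)
  beats <- round(beats * spec$fs) / spec$fs
  n <- as.integer(round(spec$duration_s * spec$fs))
  scales <- 1 + spec$am_depth * resp_value(spec, beats)
  y <- place_bumps(n, spec$fs, beats, scales,
                   tmpl$offsets, tmpl$sds, tmpl$amps)
  t <- (seq_len(n) - 1) / spec$fs
  y <- y + spec$bw_amp * resp_value(spec, t)
  if (spec$noise_sd > 0) {
    y <- y + with_seed(spec$seed + seed_offset,
                       stats::rnorm(n, sd = spec$noise_sd))
  }
  list(wave = waveform(y, fs = spec$fs, t0 = 0, label = label),
       beats = beats)
}

new_synthetic_record <- function(spec, ecg = NULL, ppg = NULL, beats) {
  structure(
    list(ecg = ecg, ppg = ppg,
         resp_ref = generate_respiration(spec),
         beat_times_true = beats,
         rr_true_bpm = spec$rr_bpm,
         spec = spec),
    class = "synthetic_record"
  )
}

#' @export
print.synthetic_record <- function(x, ...) {
  cat(sprintf("<synthetic_record> %d beats, rr_true %g breaths/min%s\n",
              length(x$beat_times_true), x$rr_true_bpm,
              if (is.null(x$spec$rr_end_bpm)) ""
              else sprintf(" (ramp to %g)", x$spec$rr_end_bpm)))
  for (nm in c("ecg", "ppg", "resp_ref")) {
    if (!is.null(x[[nm]])) { cat("  "); print(x[[nm]]) }
  }
  invisible(x)
}

#' Generate a synthetic ECG record
#'
#' Each beat is a sum of five Gaussian bumps (P, Q, R, S, T) at fixed offsets
#' relative to its beat time; beat `k` is scaled by
#' `1 + am_depth * r(t_k)`, a respiratory baseline `bw_amp * r(t)` and seeded
#' white noise are added. R-peak apices coincide with the beat times.
#'
#' @param spec A [modulation_spec].
#' @return A `synthetic_record` with the `ecg` channel, the reference
#'   respiration, the true beat times, and the true respiratory rate.
#' @export
generate_ecg <- function(spec) {
  stopifnot(inherits(spec, "modulation_spec"))
  ch <- build_channel(spec, ecg_template(), "ecg", seed_offset = 0L)
  new_synthetic_record(spec, ecg = ch$wave, beats = ch$beats)
}

#' Generate a synthetic PPG record
#'
#' Each pulse is a two-Gaussian template (systolic peak plus dicrotic bump)
#' placed at the RSA-modulated beat times; pulse `k` is scaled by
#' `1 + am_depth * r(t_k)`; baseline wander and noise as in [generate_ecg()]
#' (the PPG noise stream is drawn from `seed + 1` so each channel is
#' reproducible in isolation).
#'
#' @param spec A [modulation_spec].
#' @return A `synthetic_record` with the `ppg` channel.
#' @export
generate_ppg <- function(spec) {
  stopifnot(inherits(spec, "modulation_spec"))
  ch <- build_channel(spec, ppg_template(spec$hr_bpm), "ppg", seed_offset = 1L)
  new_synthetic_record(spec, ppg = ch$wave, beats = ch$beats)
}

#' Generate a full synthetic record (ECG + PPG + reference respiration)
#'
#' @param spec A [modulation_spec].
#' @return A `synthetic_record` with both channels. `beat_times_true` are the
#'   ECG beat times (the PPG pulse train uses the same underlying beats; its
#'   own trailing-partial rule may drop one more pulse at the record end).
#' @export
generate_record <- function(spec) {
  stopifnot(inherits(spec, "modulation_spec"))
  e <- build_channel(spec, ecg_template(), "ecg", seed_offset = 0L)
  p <- build_channel(spec, ppg_template(spec$hr_bpm), "ppg", seed_offset = 1L)
  rec <- new_synthetic_record(spec, ecg = e$wave, ppg = p$wave,
                              beats = e$beats)
  rec
}

#' True per-window respiratory rate of a synthetic spec
#'
#' The number of respiratory cycles falling in a window is the phase
#' increment over that window; the true windowed RR is that count scaled to
#' breaths/min. Exact for both constant-rate and ramp specs.
#'
#' @param spec A [modulation_spec].
#' @param grid A `window_grid` from [segment_windows()].
#' @return Numeric vector of true RR (breaths/min), one per window.
#' @export
true_rr_windows <- function(spec, grid) {
  stopifnot(inherits(spec, "modulation_spec"), inherits(grid, "window_grid"))
  b <- grid$boundaries
  (resp_phase(spec, b$end_s) - resp_phase(spec, b$start_s)) * 60 /
    grid$window_length_s
}
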