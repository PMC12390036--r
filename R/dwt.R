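## Periodized orthogonal discrete wavelet transform with the classic 4-tap
## Daubechies filter. With periodic (circular) extension and an even signal
## length the analysis operator is orthogonal, so synthesis is its transpose
## and reconstruction is exact to machine precision. Odd lengths are padded
## by repeating the last sample and trimmed on reconstruction.

daub4_filters <- function() {
  s3 <- sqrt(3)
  h <- c(1 + s3, 3 + s3, 3 - s3, 1 - s3) / (4 * sqrt(2))  # low-pass
  g <- rev(h) * c(1, -1, 1, -1)                            # high-pass
  list(h = h, g = g)
}

## One analysis level: returns approximation cA, detail cD, and the original
## (pre-padding) length needed to invert.
dwt_step <- function(x) {
  f <- daub4_filters()
  n0 <- length(x)
  if (n0 %% 2L == 1L) x <- c(x, x[n0])
  n <- length(x)
  half <- n %/% 2L
  base <- 2L * (seq_len(half) - 1L)
  cA <- numeric(half); cD <- numeric(half)
  for (tap in 0:3) {
    j <- ((base + tap) %% n) + 1L
    cA <- cA + f$h[tap + 1L] * x[j]
    cD <- cD + f$g[tap + 1L] * x[j]
  }
  list(cA = cA, cD = cD, n0 = n0)
}

## Inverse of dwt_step (transpose of the orthogonal analysis operator).
idwt_step <- function(cA, cD, n0) {
  f <- daub4_filters()
  n <- 2L * length(cA)
  base <- 2L * (seq_along(cA) - 1L)
  x <- numeric(n)
  for (tap in 0:3) {
    # for a fixed tap the target indices are distinct across k
    j <- ((base + tap) %% n) + 1L
    x[j] <- x[j] + cA * f$h[tap + 1L] + cD * f$g[tap + 1L]
  }
  x[seq_len(n0)]
}

## Multilevel decomposition: list with final approximation and a list of
## detail vectors, details[[1]] = finest level.
dwt_multilevel <- function(x, levels) {
  details <- vector("list", levels)
  lens <- integer(levels)
  for (l in seq_len(levels)) {
    st <- dwt_step(x)
    details[[l]] <- st$cD
    lens[l] <- st$n0
    x <- st$cA
  }
  list(cA = x, details = details, lens = lens)
}

idwt_multilevel <- function(dec) {
  x <- dec$cA
  for (l in rev(seq_along(dec$details))) {
    x <- idwt_step(x, dec$details[[l]], dec$lens[l])
  }
  x
}

## Deepest decomposition the length supports (each level needs >= 4 samples
## after halving).
max_dwt_levels <- function(n) {
  l <- 0L
  while (n >= 8L) {  # next approximation has >= 4 samples
    n <- (n + n %% 2L) %/% 2L
    l <- l + 1L
  }
  l
}

#' Wavelet smoothing of a waveform
#'
#' Multilevel discrete wavelet decomposition (orthogonal Daubechies 4-tap
#' filter, periodic extension) in which the finest `zero_finest` detail
#' levels are zeroed before reconstruction, suppressing high-frequency noise
#' while leaving the pulse morphology in the approximation and coarse-detail
#' bands. Output length equals input length.
#'
#' @param w A [waveform].
#' @param levels Decomposition depth (default 11). If the signal is too short
#'   the depth is reduced to the deepest feasible level, with a message.
#' @param zero_finest How many of the finest detail levels to zero
#'   (default 2; capped at `levels`).
#' @return A smoothed [waveform].
#' @export
wavelet_smooth <- function(w, levels = 11, zero_finest = 2) {
  stopifnot(inherits(w, "waveform"))
  levels <- as.integer(levels)
  feasible <- max_dwt_levels(length(w$samples))
  if (feasible < 1L) return(w)
  if (levels > feasible) {
    message("wavelet_smooth: reducing levels from ", levels, " to ", feasible,
            " for signal length ", length(w$samples))
    levels <- feasible
  }
  dec <- dwt_multilevel(w$samples, levels)
  for (l in seq_len(min(zero_finest, levels))) {
    dec$details[[l]][] <- 0
  }
  w$samples <- idwt_multilevel(dec)
  w
}
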