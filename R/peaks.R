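#' Local-maximum detection with distance and prominence rules
#'
#' Finds strict local maxima (plateau maxima are reported at their first
#' sample), computes each peak's topographic prominence (height above the
#' higher of the two bracketing minima, where each bracket extends to the
#' nearest higher sample or the signal end), then enforces a minimum
#' inter-peak distance by keeping higher peaks first (ties broken toward the
#' earlier index) and finally drops peaks below the prominence floor.
#'
#' @param x Numeric vector.
#' @param min_distance Minimum separation between retained peaks, in samples
#'   (default 1 = no constraint).
#' @param min_prominence Minimum prominence of retained peaks (default 0 = no
#'   constraint).
#' @return Integer vector of peak indices (1-based), increasing.
#' @export
find_peaks <- function(x, min_distance = 1, min_prominence = 0) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  # local maxima; a plateau counts once, at its left edge
  idx <- integer(0)
  i <- 2L
  while (i < n) {
    if (x[i] > x[i - 1L]) {
      j <- i
      while (j < n && x[j + 1L] == x[j]) j <- j + 1L
      if (j < n && x[j + 1L] < x[j]) {
        idx <- c(idx, i)
        i <- j + 1L
      } else {
        i <- j + 1L
      }
    } else {
      i <- i + 1L
    }
  }
  if (length(idx) == 0L) return(integer(0))
  prom <- peak_prominence(x, idx)
  # distance rule: keep higher peaks first, earlier index wins ties
  ord <- order(-x[idx], idx)
  keep <- logical(length(idx))
  taken <- integer(0)
  for (k in ord) {
    if (all(abs(idx[k] - taken) >= min_distance)) {
      keep[k] <- TRUE
      taken <- c(taken, idx[k])
    }
  }
  sel <- keep & prom >= min_prominence
  sort(idx[sel])
}

## Topographic prominence of peaks at indices idx: for each peak, scan left
## and right to the nearest strictly higher sample (or the end); prominence
## is peak height minus the larger of the two interval minima.
peak_prominence <- function(x, idx) {
  n <- length(x)
  vapply(idx, function(i) {
    h <- x[i]
    # left base
    j <- i - 1L
    left_min <- h
    while (j >= 1L && x[j] <= h) {
      if (x[j] < left_min) left_min <- x[j]
      j <- j - 1L
    }
    # right base
    j <- i + 1L
    right_min <- h
    while (j <= n && x[j] <= h) {
      if (x[j] < right_min) right_min <- x[j]
      j <- j + 1L
    }
    h - max(left_min, right_min)
  }, numeric(1))
}
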