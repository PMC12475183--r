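#' Local-maximum detection with distance and prominence constraints
#'
#' Finds local maxima of a 1-d signal and filters them by a minimal
#' inter-peak distance (higher peaks take priority) and a minimal
#' topographic prominence. Prominence of a peak is its height minus the
#' higher of the two minima found while descending from the peak toward the
#' nearest strictly higher sample (or signal edge) on each side — the same
#' convention as the standard find-peaks routines in scientific signal
#' processing libraries.
#'
#' Plateaus (runs of equal samples higher than both neighbours) are
#' reported at their (rounded-down) midpoint.
#'
#' @param x numeric vector
#' @param min_distance minimal distance between retained peaks, in samples
#' @param min_prominence minimal prominence, in signal units
#' @return integer vector of peak indices (1-based), increasing
#' @export
find_peaks <- function(x, min_distance = 1L, min_prominence = 0) {
  n <- length(x)
  if (n < 3L) return(integer(0))

  ## candidate local maxima, plateau-aware
  idx <- integer(0)
  i <- 2L
  while (i < n) {
    if (x[i] > x[i - 1L]) {
      j <- i
      while (j < n && x[j + 1L] == x[i]) j <- j + 1L
      if (j < n && x[j + 1L] < x[i]) {
        idx <- c(idx, (i + j) %/% 2L)
        i <- j
      }
    }
    i <- i + 1L
  }
  if (!length(idx)) return(integer(0))

  ## distance filter: keep higher peaks first, drop neighbours within range
  if (min_distance > 1L && length(idx) > 1L) {
    ord <- idx[order(x[idx], decreasing = TRUE)]
    keep <- logical(n)
    blocked <- logical(n)
    for (p in ord) {
      if (blocked[p]) next
      keep[p] <- TRUE
      lo <- max(1L, p - as.integer(min_distance) + 1L)
      hi <- min(n, p + as.integer(min_distance) - 1L)
      blocked[lo:hi] <- TRUE
    }
    idx <- idx[keep[idx]]
  }

  if (min_prominence > 0 && length(idx)) {
    prom <- vapply(idx, function(p) peak_prominence(x, p), numeric(1))
    idx <- idx[prom >= min_prominence]
  }
  idx
}

## prominence of the peak at index p (see find_peaks for the convention)
peak_prominence <- function(x, p) {
  n <- length(x)
  h <- x[p]
  i <- p; lmin <- h
  while (i > 1L) {
    i <- i - 1L
    if (x[i] > h) break
    if (x[i] < lmin) lmin <- x[i]
  }
  i <- p; rmin <- h
  while (i < n) {
    i <- i + 1L
    if (x[i] > h) break
    if (x[i] < rmin) rmin <- x[i]
  }
  h - max(lmin, rmin)
}
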