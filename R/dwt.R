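# Daubechies-4 (8-tap) analysis filters, standard orthonormal normalization.
DB4_DEC_LO <- c(-0.010597401785069032, 0.032883011666885197,
                0.030841381835560764, -0.18703481171909309,
                -0.027983769416859854, 0.63088076792985892,
                0.71484657055291567, 0.23037781330889651)
DB4_DEC_HI <- c(-0.23037781330889651, 0.71484657055291567,
                -0.63088076792985892, -0.027983769416859854,
                0.18703481171909309, 0.030841381835560764,
                -0.032883011666885197, -0.010597401785069032)

# One analysis step: symmetric (half-sample) boundary extension by
# filter_len - 1 samples on each side, full convolution, dyadic
# downsampling. Output length floor((n + 7) / 2); matches the common
# symmetric-padding DWT convention used across wavelet toolboxes.
convFull <- function(x, f) {
  n <- length(x)
  y <- numeric(n + length(f) - 1L)
  for (j in seq_along(f)) {
    y[j:(j + n - 1L)] <- y[j:(j + n - 1L)] + f[j] * x
  }
  y
}

dwtStep <- function(x) {
  L <- 8L
  n <- length(x)
  if (n < L) stopf("signal too short for db4 analysis (need >= %d samples)", L)
  xp <- c(rev(x[1:(L - 1L)]), x, rev(x[(n - L + 2L):n]))
  ca_full <- convFull(xp, DB4_DEC_LO)
  cd_full <- convFull(xp, DB4_DEC_HI)
  out_len <- (n + L - 1L) %/% 2L
  idx <- seq(L + 1L, by = 2L, length.out = out_len)
  list(approx = ca_full[idx], detail = cd_full[idx])
}

#' Maximum useful db4 decomposition level
#'
#' `floor(log2(n / (filter_len - 1)))` — the deepest level at which the
#' filter still fits inside the signal.
#'
#' @param n Signal length in samples.
#' @return Integer level (possibly 0).
#' @export
dwtMaxLevel <- function(n) {
  if (n < 8L) return(0L)
  as.integer(floor(log2(n / 7)))
}

#' Multi-level db4 discrete wavelet transform
#'
#' Repeatedly splits the approximation band, returning the detail
#' coefficients of levels 1..`level` and the final approximation. Boundary
#' handling is symmetric (half-sample) extension.
#'
#' @param x Numeric signal.
#' @param level Number of decomposition levels.
#' @return List with `details` (list of length `level`, finest first) and
#'   `approx` (level-`level` approximation coefficients).
#' @examples
#' d <- dwtDb4(sin(2 * pi * 3 * (0:999) / 100), level = 5)
#' lengths(d$details)
#' @export
dwtDb4 <- function(x, level = 5L) {
  maxlev <- dwtMaxLevel(length(x))
  if (level > maxlev) {
    stopf("signal of length %d supports at most %d db4 level(s), not %d",
          length(x), maxlev, level)
  }
  details <- vector("list", level)
  a <- x
  for (l in seq_len(level)) {
    s <- dwtStep(a)
    details[[l]] <- s$detail
    a <- s$approx
  }
  list(details = details, approx = a)
}
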