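#' Six time-domain summary statistics
#'
#' Mean, standard deviation (sample, n-1), skewness (`m3 / m2^1.5`), excess
#' kurtosis (`m4 / m2^2 - 3`), minimum and maximum, in that order.
#' Zero-variance input yields skewness 0 and kurtosis 0 by convention.
#'
#' @param x Numeric vector of length >= 2.
#' @return Named numeric vector of length 6.
#' @examples
#' timeStats(c(1, 2, 3, 4))
#' @export
timeStats <- function(x) {
  if (length(x) < 2L) stopf("need at least 2 values")
  m <- mean(x)
  s <- sd(x)
  if (s > 0) {
    sk <- e1071::skewness(x, type = 1)
    ku <- e1071::kurtosis(x, type = 1)
  } else {
    sk <- 0
    ku <- 0
  }
  c(mean = m, sd = s, skew = sk, kurt = ku, min = min(x), max = max(x))
}

#' Wavelet-band statistics of a window
#'
#' db4 DWT to five levels; [timeStats()] of the detail coefficients of each
#' level, ordered level 1 (finest) to level 5. 5 levels x 6 statistics = 30
#' values.
#'
#' @param x Numeric window (>= 224 samples for 5 db4 levels).
#' @param level Decomposition depth.
#' @return Numeric vector of length `6 * level`.
#' @export
dwtStats <- function(x, level = 5L) {
  d <- dwtDb4(x, level = level)
  out <- lapply(seq_len(level), function(l) {
    v <- timeStats(d$details[[l]])
    names(v) <- paste0("d", l, "_", names(v))
    v
  })
  unlist(out)
}

#' Extract the 36-dimensional handcrafted feature vector of a window
#'
#' Concatenation of the six time-domain statistics of the raw window and
#' the six statistics of the db4 detail coefficients at each of five
#' decomposition levels.
#'
#' @param x Numeric window (typically 1000 samples).
#' @return Named numeric vector of length 36.
#' @examples
#' length(extractFeatures(rnorm(1000)))
#' @export
extractFeatures <- function(x) {
  c(timeStats(x), dwtStats(x, level = 5L))
}

#' Feature matrix of a WindowSet
#'
#' @param ws A [WindowSet].
#' @return n-windows x 36 numeric matrix (windows in `ws` column order).
#' @export
featureMatrix <- function(ws) {
  mat <- SummarizedExperiment::assay(ws, "eda")
  t(apply(mat, 2L, extractFeatures))
}

#' Fit / apply the PCA reduction of the feature space
#'
#' `fitPca` centers (no scaling) and keeps the leading `k` components;
#' fit it on training-fold rows only to avoid subject leakage.
#' `applyPca` centers new rows with the training offsets and projects.
#'
#' @param x n x p feature matrix (n >= k rows).
#' @param k Number of components to retain.
#' @return `fitPca`: a [PcaModel]; `applyPca`: an n x k score matrix.
#' @examples
#' m <- matrix(rnorm(600), 50, 12)
#' p <- fitPca(m, k = 3)
#' dim(applyPca(p, m))
#' @export
fitPca <- function(x, k = 12L) {
  x <- as.matrix(x)
  if (nrow(x) < k) stopf("need at least k = %d rows to fit PCA", k)
  pr <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  rank <- sum(pr$sdev > pr$sdev[1] * 1e-12)
  if (k > rank) {
    stopf("k = %d exceeds the achievable rank %d of the feature matrix",
          k, rank)
  }
  ev <- pr$sdev^2
  new("PcaModel",
      rotation = pr$rotation[, seq_len(k), drop = FALSE],
      center = pr$center,
      varExplained = ev[seq_len(k)] / sum(ev),
      totalVariance = sum(ev))
}

#' @rdname fitPca
#' @param model A [PcaModel].
#' @export
applyPca <- function(model, x) {
  x <- if (is.matrix(x)) x else matrix(x, nrow = 1)
  sweep(x, 2L, model@center) %*% model@rotation
}
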