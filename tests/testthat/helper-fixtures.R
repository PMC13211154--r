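# Small, fast fixtures shared across test files. Everything is generated
# in code; seeds are fixed so expected values are stable.

tinyCohortConfig <- function(n_subjects = 2L, seed = 7L, ...) {
  synthConfig(n_subjects = n_subjects, seed = seed, ...)
}

tinyFcnConfig <- function(input_len = 40L,
                          blocks = list(
                            list(out_channels = 4L, kernel_len = 2L,
                                 activation = "relu", batch_norm = TRUE),
                            list(out_channels = 5L, kernel_len = 3L,
                                 activation = "tanh", batch_norm = TRUE)),
                          avgpool_kernel = 3L) {
  fcnConfig(input_len = input_len, conv_blocks = blocks,
            avgpool_kernel = avgpool_kernel)
}

# three well-separated Gaussian blobs in feature space
separableBlobs <- function(n_per_class = 30L, p = 6L, sep = 12, seed = 42L) {
  set.seed(seed)
  centers <- rbind(rep(0, p), c(rep(sep, p %/% 2), rep(0, p - p %/% 2)),
                   rep(-sep, p))
  x <- do.call(rbind, lapply(1:3, function(k) {
    matrix(rnorm(n_per_class * p, sd = 1), n_per_class, p) +
      matrix(centers[k, ], n_per_class, p, byrow = TRUE)
  }))
  y <- factor(rep(c("NoPain", "LowPain", "HighPain"), each = n_per_class),
              levels = c("NoPain", "LowPain", "HighPain"))
  list(x = x, y = y)
}

labelLevels <- c("NoPain", "LowPain", "HighPain")
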