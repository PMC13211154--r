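#' Declarative configuration of the 1-D fully convolutional network
#'
#' The default is the final deployed architecture: two convolutional blocks
#' (conv + batch norm + activation) with 71 ReLU maps then 120 Tanh maps,
#' average pooling of kernel 3, flatten, and a linear classifier to 3
#' logits. Convolutions are valid-mode, stride 1; the kernel lengths (2 and
#' 3) are the unique values consistent with the deployed length chain
#' 1000 -> 999 -> 997. Pooling uses stride = kernel with floor division
#' (997 -> 332), giving a flattened feature vector of 120 x 332 = 39840.
#'
#' @param input_len Window length in samples.
#' @param input_channels Number of input channels (1 for single-lead EDA).
#' @param conv_blocks List of blocks, each a list with `out_channels`,
#'   `kernel_len`, `activation` (`"none"`, `"relu"`, `"sigmoid"`,
#'   `"tanh"`) and `batch_norm` flag.
#' @param avgpool_kernel Average-pooling kernel (= stride).
#' @param n_classes Number of output classes.
#' @param zscore Per-window z-score normalization of the input (off by
#'   default; the filtered conductance is fed directly).
#' @return An `FcnConfig` list.
#' @examples
#' shapeTrace(fcnConfig())
#' @export
fcnConfig <- function(input_len = 1000L, input_channels = 1L,
                      conv_blocks = list(
                        list(out_channels = 71L, kernel_len = 2L,
                             activation = "relu", batch_norm = TRUE),
                        list(out_channels = 120L, kernel_len = 3L,
                             activation = "tanh", batch_norm = TRUE)
                      ),
                      avgpool_kernel = 3L, n_classes = 3L,
                      zscore = FALSE) {
  for (b in conv_blocks) {
    if (b$kernel_len < 1L || b$out_channels < 1L) {
      stopf("conv blocks need kernel_len >= 1 and out_channels >= 1")
    }
    if (!b$activation %in% c("none", "relu", "sigmoid", "tanh")) {
      stopf("unknown activation '%s'", b$activation)
    }
  }
  if (avgpool_kernel < 1L) stopf("avgpool_kernel must be >= 1")
  structure(list(
    input_len = as.integer(input_len),
    input_channels = as.integer(input_channels),
    conv_blocks = conv_blocks,
    avgpool_kernel = as.integer(avgpool_kernel),
    n_classes = as.integer(n_classes),
    zscore = isTRUE(zscore)
  ), class = "FcnConfig")
}

#' Layer-by-layer shape arithmetic of an FCN configuration
#'
#' Valid-mode convolutions shrink the length by `kernel - 1`; average
#' pooling divides it by the kernel with floor division; flatten multiplies
#' channels by pooled length.
#'
#' @param config An [fcnConfig()].
#' @param input_len Input length (defaults to the config's).
#' @return A data.frame (class `ShapeTrace`) with one row per layer:
#'   `layer`, `in_channels`, `in_len`, `out_channels`, `out_len`; the
#'   flattened dimension is `attr(, "flatten_dim")`.
#' @export
shapeTrace <- function(config, input_len = config$input_len) {
  ch <- config$input_channels
  len <- as.integer(input_len)
  rows <- list()
  for (i in seq_along(config$conv_blocks)) {
    b <- config$conv_blocks[[i]]
    out_len <- len - b$kernel_len + 1L
    if (out_len < 1L) {
      stopf("layer conv%d: kernel %d does not fit input length %d",
            i - 1L, b$kernel_len, len)
    }
    rows[[length(rows) + 1L]] <- data.frame(
      layer = sprintf("conv%d", i - 1L), in_channels = ch, in_len = len,
      out_channels = b$out_channels, out_len = out_len
    )
    ch <- b$out_channels
    len <- out_len
  }
  pooled <- len %/% config$avgpool_kernel
  if (pooled < 1L) {
    stopf("layer avgpool: kernel %d does not fit input length %d",
          config$avgpool_kernel, len)
  }
  rows[[length(rows) + 1L]] <- data.frame(
    layer = "avgpool", in_channels = ch, in_len = len,
    out_channels = ch, out_len = pooled
  )
  flat <- ch * pooled
  rows[[length(rows) + 1L]] <- data.frame(
    layer = "flatten", in_channels = ch, in_len = pooled,
    out_channels = flat, out_len = 1L
  )
  rows[[length(rows) + 1L]] <- data.frame(
    layer = "classifier", in_channels = flat, in_len = 1L,
    out_channels = config$n_classes, out_len = 1L
  )
  out <- do.call(rbind, rows)
  attr(out, "flatten_dim") <- flat
  class(out) <- c("ShapeTrace", "data.frame")
  out
}

#' Analytic multiply-accumulate count of an FCN configuration
#'
#' Sum over convolution layers of
#' `out_len * out_channels * kernel_len * in_channels` plus the
#' `in x out` classifier product. Batch norm, activations and pooling are
#' not counted (they contribute no multiply-accumulates in this
#' convention).
#'
#' @param config An [fcnConfig()].
#' @param input_len Input length.
#' @return Integer-valued numeric MAC count per window.
#' @examples
#' countMacs(fcnConfig())  # 25744698
#' @export
countMacs <- function(config, input_len = config$input_len) {
  tr <- shapeTrace(config, input_len)
  total <- 0
  for (i in seq_along(config$conv_blocks)) {
    r <- tr[tr$layer == sprintf("conv%d", i - 1L), ]
    total <- total + r$out_len * r$out_channels *
      config$conv_blocks[[i]]$kernel_len * r$in_channels
  }
  total + attr(tr, "flatten_dim") * config$n_classes
}

#' Instrumented multiply counter: naive forward pass
#'
#' Executes a literal single-window forward pass with explicit loops over
#' output positions and channels, incrementing a counter by the number of
#' scalar products actually computed. Serves as the independent oracle for
#' [countMacs()]; O(MACs), so keep configs small in routine use.
#'
#' @param model An [FcnModel] (use [buildFcn()]).
#' @param x Numeric input window of length `config$input_len`.
#' @return List with `macs` (count of multiplies executed) and `logits`.
#' @export
countMacsInstrumented <- function(model, x) {
  cfg <- model$config
  macs <- 0
  A <- matrix(x, ncol = 1)  # (len, in_ch)
  for (i in seq_along(cfg$conv_blocks)) {
    b <- cfg$conv_blocks[[i]]
    W <- model$params[[sprintf("conv%d_W", i - 1L)]]
    bias <- model$params[[sprintf("conv%d_b", i - 1L)]]
    k <- dim(W)[1]
    in_ch <- dim(W)[2]
    out_len <- nrow(A) - k + 1L
    out <- matrix(0, out_len, b$out_channels)
    for (t in seq_len(out_len)) {
      patch <- A[t:(t + k - 1L), , drop = FALSE]
      for (oc in seq_len(b$out_channels)) {
        prods <- patch * matrix(W[, , oc], k, in_ch)
        macs <- macs + length(prods)
        out[t, oc] <- sum(prods) + bias[oc]
      }
    }
    A <- out  # BN/activation omitted: no multiply-accumulates counted
  }
  p <- cfg$avgpool_kernel
  P <- nrow(A) %/% p
  pooled <- vapply(seq_len(P), function(j) {
    colMeans(A[((j - 1L) * p + 1L):(j * p), , drop = FALSE])
  }, numeric(ncol(A)))
  flat <- as.numeric(pooled)  # (ch, P) column-major: channel fastest,
                              # matching the batched forward's flatten
  Wc <- model$params$cls_W
  logits <- numeric(cfg$n_classes)
  for (oc in seq_len(cfg$n_classes)) {
    prods <- flat * Wc[, oc]
    macs <- macs + length(prods)
    logits[oc] <- sum(prods) + model$params$cls_b[oc]
  }
  list(macs = macs, logits = logits)
}

#' Build an FCN with seeded initial parameters
#'
#' Uniform fan-in initialization (`U(-1/sqrt(fan_in), 1/sqrt(fan_in))`) for
#' convolution and classifier weights and biases; batch-norm gamma 1 /
#' beta 0 with zero running mean and unit running variance.
#'
#' @param config An [fcnConfig()].
#' @param seed Integer seed for the initialization draw.
#' @return An [FcnModel] (untrained).
#' @export
buildFcn <- function(config, seed = 1L) {
  tr <- shapeTrace(config)  # validates the arithmetic
  params <- list()
  state <- list()
  withSeed(seed, {
    in_ch <- config$input_channels
    for (i in seq_along(config$conv_blocks)) {
      b <- config$conv_blocks[[i]]
      fan_in <- b$kernel_len * in_ch
      bound <- 1 / sqrt(fan_in)
      nm <- sprintf("conv%d", i - 1L)
      params[[paste0(nm, "_W")]] <- array(
        runif(b$kernel_len * in_ch * b$out_channels, -bound, bound),
        dim = c(b$kernel_len, in_ch, b$out_channels))
      params[[paste0(nm, "_b")]] <- runif(b$out_channels, -bound, bound)
      if (isTRUE(b$batch_norm)) {
        params[[paste0(nm, "_gamma")]] <- rep(1, b$out_channels)
        params[[paste0(nm, "_beta")]] <- rep(0, b$out_channels)
        state[[paste0(nm, "_rmean")]] <- rep(0, b$out_channels)
        state[[paste0(nm, "_rvar")]] <- rep(1, b$out_channels)
      }
      in_ch <- b$out_channels
    }
    flat <- attr(tr, "flatten_dim")
    bound <- 1 / sqrt(flat)
    params$cls_W <- matrix(runif(flat * config$n_classes, -bound, bound),
                           flat, config$n_classes)
    params$cls_b <- runif(config$n_classes, -bound, bound)
  })
  new("FcnModel", config = unclass(config), params = params, state = state,
      trained = FALSE)
}

# convenience: list-style access used internally ($config, $params, $state)
#' @export
setMethod("$", "FcnModel", function(x, name) slot(x, name))

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.1

ACT_CODES <- c(none = 0L, relu = 1L, sigmoid = 2L, tanh = 3L)

# (k, in_ch, out_ch) array <-> (k*in_ch, out_ch) im2col weight matrix,
# rows ordered channel-fastest within tap
wAsMatrix <- function(W) {
  d <- dim(W)
  matrix(aperm(W, c(2, 1, 3)), d[1] * d[2], d[3])
}

wAsArray <- function(Wmat, k, in_ch, out_ch) {
  aperm(array(Wmat, dim = c(in_ch, k, out_ch)), c(2, 1, 3))
}

# Forward pass. X: win_len x n matrix (single channel). Returns logits
# (n x n_classes); when train = TRUE also layer caches and updated
# batch-norm running stats. Activations are held channel-first as
# (ch, len, n) arrays so per-channel affine ops broadcast down columns via
# R's native vector recycling (no rep() blow-ups).
fcnForward <- function(model, X, train = FALSE) {
  cfg <- model$config
  params <- model$params
  state <- model$state
  n <- ncol(X)
  if (nrow(X) != cfg$input_len) {
    stopf("input windows have %d samples; model expects %d",
          nrow(X), cfg$input_len)
  }
  if (cfg$zscore) {
    mu <- colMeans(X)
    s <- sqrt(pmax(colMeans(X^2) - mu^2, 1e-16))
    X <- (X - rep(mu, each = nrow(X))) / rep(pmax(s, 1e-8), each = nrow(X))
  }
  A <- array(t(X), dim = c(n, cfg$input_len, cfg$input_channels))
  A <- aperm(A, c(3, 2, 1))  # (in_ch, len, n)
  caches <- list()
  for (i in seq_along(cfg$conv_blocks)) {
    b <- cfg$conv_blocks[[i]]
    nm <- sprintf("conv%d", i - 1L)
    W <- params[[paste0(nm, "_W")]]
    use_bn <- isTRUE(b$batch_norm)
    Wmat <- wAsMatrix(W)
    gamma <- if (use_bn) params[[paste0(nm, "_gamma")]] else numeric()
    beta <- if (use_bn) params[[paste0(nm, "_beta")]] else numeric()
    rmean <- if (use_bn) state[[paste0(nm, "_rmean")]] else numeric()
    rvar <- if (use_bn) state[[paste0(nm, "_rvar")]] else numeric()
    res <- .convBlockForward(A, Wmat, params[[paste0(nm, "_b")]],
                             dim(W)[1], ACT_CODES[[b$activation]], use_bn,
                             gamma, beta, rmean, rvar, train,
                             BN_MOMENTUM, BN_EPS)
    if (train) {
      if (use_bn) {
        state[[paste0(nm, "_rmean")]] <- as.numeric(res$rmean)
        state[[paste0(nm, "_rvar")]] <- as.numeric(res$rvar)
      }
      caches[[i]] <- list(A_in = A, Y = res$Y, Wmat = Wmat,
                          k = dim(W)[1], in_ch = dim(W)[2],
                          out_ch = dim(W)[3],
                          xhat = res$xhat, invstd = res$invstd)
    }
    A <- res$Y
  }
  p <- cfg$avgpool_kernel
  ch <- dim(A)[1]
  L <- dim(A)[2]
  P <- L %/% p
  pooled <- A[, seq(1L, p * P, by = p), , drop = FALSE]
  if (p > 1L) {
    for (j in 2:p) {
      pooled <- pooled + A[, seq(j, p * P, by = p), , drop = FALSE]
    }
  }
  pooled <- pooled / p  # (ch, P, n)
  Fm <- pooled
  dim(Fm) <- c(ch * P, n)  # flatten: channel fastest within position
  logits <- crossprod(Fm, params$cls_W) + rep(params$cls_b, each = n)
  if (!train) return(list(logits = logits))
  list(logits = logits, caches = caches, Fm = Fm,
       pool = list(p = p, P = P, L = L, ch = ch, n = n), state = state)
}

# Backward pass from d(loss)/d(logits); returns gradients named like params.
fcnBackward <- function(model, fwd, dlogits) {
  cfg <- model$config
  params <- model$params
  grads <- list()
  grads$cls_W <- fwd$Fm %*% dlogits
  grads$cls_b <- colSums(dlogits)
  dF <- params$cls_W %*% t(dlogits)  # (ch*P, n)
  pl <- fwd$pool
  dPool <- dF / pl$p
  dim(dPool) <- c(pl$ch, pl$P, pl$n)
  dY <- array(0, dim = c(pl$ch, pl$L, pl$n))
  for (j in seq_len(pl$p)) {
    dY[, seq(j, pl$p * pl$P, by = pl$p), ] <- dPool
  }
  for (i in rev(seq_along(cfg$conv_blocks))) {
    b <- cfg$conv_blocks[[i]]
    nm <- sprintf("conv%d", i - 1L)
    cc <- fwd$caches[[i]]
    use_bn <- isTRUE(b$batch_norm)
    need_dA <- i > 1L
    res <- .convBlockBackward(
      dY, cc$Y, cc$A_in, cc$Wmat, cc$k, ACT_CODES[[b$activation]], use_bn,
      if (use_bn) params[[paste0(nm, "_gamma")]] else numeric(),
      if (use_bn) cc$xhat else NULL,
      if (use_bn) as.numeric(cc$invstd) else numeric(),
      need_dA)
    grads[[paste0(nm, "_W")]] <- wAsArray(res$dW, cc$k, cc$in_ch, cc$out_ch)
    grads[[paste0(nm, "_b")]] <- as.numeric(res$db)
    if (use_bn) {
      grads[[paste0(nm, "_gamma")]] <- as.numeric(res$dgamma)
      grads[[paste0(nm, "_beta")]] <- as.numeric(res$dbeta)
    }
    if (need_dA) dY <- res$dA
  }
  grads
}

softmaxProbs <- function(logits) {
  logits <- if (is.matrix(logits)) logits else matrix(logits, nrow = 1)
  z <- logits - apply(logits, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

#' Class and confidence from output logits
#'
#' Softmax probabilities; predicted class is the argmax (lowest index on
#' exact ties), confidence is the maximum probability.
#'
#' @param logits Numeric vector of `n_classes` logits, or an
#'   n x `n_classes` matrix.
#' @return A data.frame with `class` (factor NoPain/LowPain/HighPain for
#'   3-class output, integer index otherwise) and `confidence`.
#' @examples
#' predictWithConfidence(c(10, 0, 0))
#' @export
predictWithConfidence <- function(logits) {
  logits <- if (is.matrix(logits)) logits else matrix(logits, nrow = 1)
  if (any(!is.finite(logits))) stopf("non-finite logits")
  p <- softmaxProbs(logits)
  idx <- max.col(p, ties.method = "first")
  cls <- if (ncol(p) == 3L) painFactor(PAIN_LEVELS[idx]) else idx
  data.frame(class = cls, confidence = p[cbind(seq_len(nrow(p)), idx)])
}

#' Predict class probabilities for a matrix of windows
#'
#' Runs the FCN in inference mode (batch-norm uses running statistics) in
#' batches.
#'
#' @param model A trained [FcnModel].
#' @param X `win_len` x n matrix of (filtered) windows.
#' @param batch_size Forward-pass batch size.
#' @return n x `n_classes` probability matrix.
#' @export
predictFcn <- function(model, X, batch_size = 256L) {
  n <- ncol(X)
  out <- matrix(0, n, model$config$n_classes)
  i <- 1L
  while (i <= n) {
    j <- min(i + batch_size - 1L, n)
    out[i:j, ] <- softmaxProbs(
      fcnForward(model, X[, i:j, drop = FALSE], train = FALSE)$logits)
    i <- j + 1L
  }
  out
}

#' Save / load an FCN checkpoint
#'
#' The checkpoint embeds the architecture config together with all
#' parameters and batch-norm running statistics, so a loaded model is
#' immediately usable for inference or further training.
#'
#' @param model An [FcnModel].
#' @param path File path for the checkpoint.
#' @return `saveFcn` returns `path` invisibly; `loadFcn` returns the
#'   restored [FcnModel].
#' @export
saveFcn <- function(model, path) {
  saveRDS(list(config = model@config, params = model@params,
               state = model@state, trained = model@trained), path)
  invisible(path)
}

#' @rdname saveFcn
#' @export
loadFcn <- function(path) {
  z <- readRDS(path)
  new("FcnModel", config = z$config, params = z$params, state = z$state,
      trained = z$trained)
}
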