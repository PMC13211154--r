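#' Training settings for the FCN
#'
#' Defaults are the reference training schedule of the deployed system: Adam with learning rate
#' 1.94e-4, cross-entropy loss, at most 3000 epochs with early stopping
#' after 500 epochs without a new best validation accuracy, and a
#' reduce-on-plateau learning-rate scheduler (factor 0.5, scheduler
#' patience 50, monitored on validation accuracy). Batch size 32.
#'
#' @param max_epochs Maximum training epochs.
#' @param patience Early-stopping patience (epochs without improvement).
#' @param learning_rate Adam learning rate.
#' @param batch_size Mini-batch size.
#' @param scheduler_factor,scheduler_patience Reduce-on-plateau parameters.
#' @param seed Seed for shuffling and any training randomness.
#' @return A `TrainSettings` list.
#' @export
trainSettings <- function(max_epochs = 3000L, patience = 500L,
                          learning_rate = 1.94e-4, batch_size = 32L,
                          scheduler_factor = 0.5,
                          scheduler_patience = 50L, seed = 1L) {
  if (patience >= max_epochs) stopf("patience must be < max_epochs")
  if (learning_rate <= 0) stopf("learning_rate must be > 0")
  structure(list(
    max_epochs = as.integer(max_epochs), patience = as.integer(patience),
    learning_rate = learning_rate, batch_size = as.integer(batch_size),
    scheduler_factor = scheduler_factor,
    scheduler_patience = as.integer(scheduler_patience),
    seed = as.integer(seed)
  ), class = "TrainSettings")
}

adamInit <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adamStep <- function(params, grads, opt, lr,
                     beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - beta1^opt$t
  bc2 <- 1 - beta2^opt$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    opt$m[[nm]] <- beta1 * opt$m[[nm]] + (1 - beta1) * g
    opt$v[[nm]] <- beta2 * opt$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (opt$m[[nm]] / bc1) / (sqrt(opt$v[[nm]] / bc2) + eps)
  }
  list(params = params, opt = opt)
}

labelsToIndex <- function(y) {
  if (is.factor(y)) as.integer(y) else as.integer(y)
}

# compact architecture description consumed by the fused C++ kernels
fusedConfig <- function(cfg) {
  list(
    kernels = vapply(cfg$conv_blocks, function(b) as.integer(b$kernel_len),
                     integer(1)),
    out_channels = vapply(cfg$conv_blocks,
                          function(b) as.integer(b$out_channels), integer(1)),
    acts = vapply(cfg$conv_blocks,
                  function(b) ACT_CODES[[b$activation]], integer(1)),
    bns = vapply(cfg$conv_blocks, function(b) isTRUE(b$batch_norm),
                 logical(1)),
    pool = cfg$avgpool_kernel, n_classes = cfg$n_classes,
    momentum = BN_MOMENTUM, eps = BN_EPS
  )
}

zscoreCols <- function(X) {
  mu <- colMeans(X)
  s <- sqrt(pmax(colMeans(X^2) - mu^2, 1e-16))
  (X - rep(mu, each = nrow(X))) / rep(pmax(s, 1e-8), each = nrow(X))
}

#' Train an FCN with Adam, cross-entropy and early stopping
#'
#' Mini-batch training with per-epoch validation; the checkpoint with the
#' highest validation accuracy is retained and returned. Training stops at
#' `max_epochs` or once validation accuracy has not improved for
#' `patience` consecutive epochs. The learning rate is halved
#' (`scheduler_factor`) when validation accuracy plateaus for
#' `scheduler_patience` epochs. Subject leakage between the train and
#' validation sets is rejected when subject ids are supplied.
#'
#' @param model An [FcnModel] from [buildFcn()].
#' @param x_train,x_val `win_len` x n window matrices.
#' @param y_train,y_val Label factors (NoPain/LowPain/HighPain).
#' @param settings A [trainSettings()].
#' @param subjects_train,subjects_val Optional subject ids for the leakage
#'   guard.
#' @param verbose Print per-epoch progress.
#' @return List with `model` (best checkpoint, `trained = TRUE`) and
#'   `history` (data.frame epoch / train_loss / val_acc / lr).
#' @export
trainFcn <- function(model, x_train, y_train, x_val, y_val,
                     settings = trainSettings(),
                     subjects_train = NULL, subjects_val = NULL,
                     verbose = FALSE) {
  if (!is.null(subjects_train) && !is.null(subjects_val)) {
    overlap <- intersect(unique(subjects_train), unique(subjects_val))
    if (length(overlap)) {
      stopf("subject leakage between train and validation sets: %s",
            paste(overlap, collapse = ", "))
    }
  }
  n <- ncol(x_train)
  if (n == 0L || ncol(x_val) == 0L) stopf("empty train or validation split")
  y_idx <- labelsToIndex(y_train)
  ncls <- model$config$n_classes
  onehot <- matrix(0, n, ncls)
  onehot[cbind(seq_len(n), y_idx)] <- 1
  y_val_idx <- labelsToIndex(y_val)

  cfg <- model$config
  ccfg <- fusedConfig(cfg)
  if (cfg$zscore) {
    x_train <- zscoreCols(x_train)
    x_val <- zscoreCols(x_val)
  }
  params <- model$params
  state <- model$state
  opt <- adamInit(params)
  lr <- settings$learning_rate
  best_acc <- -Inf
  best_params <- params
  best_state <- state
  best_epoch <- 0L
  since_best <- 0L
  since_sched <- 0L
  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        val_acc = numeric(), lr = numeric())
  bs <- settings$batch_size

  for (epoch in seq_len(settings$max_epochs)) {
    perm <- withSeed(deriveSeed(settings$seed, epoch), sample.int(n))
    total_loss <- 0
    i <- 1L
    while (i <= n) {
      idx <- perm[i:min(i + bs - 1L, n)]
      step <- .fcnTrainBatch(x_train[, idx, drop = FALSE],
                             onehot[idx, , drop = FALSE],
                             params, state, ccfg)
      state <- step$state
      total_loss <- total_loss + step$loss * length(idx)
      upd <- adamStep(params, step$grads, opt, lr)
      params <- upd$params
      opt <- upd$opt
      i <- i + bs
    }
    val_probs <- .fcnPredictBatchF(x_val, params, state, ccfg)
    val_pred <- max.col(val_probs, ties.method = "first")
    val_acc <- mean(val_pred == y_val_idx)
    history <- rbind(history, data.frame(
      epoch = epoch, train_loss = total_loss / n, val_acc = val_acc, lr = lr))
    if (verbose) {
      message(sprintf("epoch %d: loss %.4f val_acc %.4f lr %.2e",
                      epoch, total_loss / n, val_acc, lr))
    }
    if (val_acc > best_acc) {
      best_acc <- val_acc
      best_params <- params
      best_state <- state
      best_epoch <- epoch
      since_best <- 0L
      since_sched <- 0L
    } else {
      since_best <- since_best + 1L
      since_sched <- since_sched + 1L
      if (since_sched >= settings$scheduler_patience) {
        lr <- lr * settings$scheduler_factor
        since_sched <- 0L
      }
      if (since_best >= settings$patience) break
    }
  }
  list(
    model = new("FcnModel", config = model@config, params = best_params,
                state = best_state, trained = TRUE),
    history = history,
    best_epoch = best_epoch,
    best_val_acc = best_acc
  )
}
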