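test_that("default shape trace reproduces the reference length chain", {
  tr <- shapeTrace(fcnConfig())
  expect_identical(tr$out_len[tr$layer == "conv0"], 999L)
  expect_identical(tr$out_len[tr$layer == "conv1"], 997L)
  expect_identical(tr$out_len[tr$layer == "avgpool"], 332L)
  expect_identical(attr(tr, "flatten_dim"), 39840L)
  expect_identical(tr$out_channels[tr$layer == "classifier"], 3L)
})

test_that("shape arithmetic handles small and failing configs", {
  cfg <- fcnConfig(input_len = 4, conv_blocks = list(
    list(out_channels = 2L, kernel_len = 2L, activation = "none",
         batch_norm = FALSE),
    list(out_channels = 3L, kernel_len = 2L, activation = "none",
         batch_norm = FALSE)), avgpool_kernel = 1L)
  tr <- shapeTrace(cfg)
  expect_identical(tr$out_len[1:2], c(3L, 2L))
  expect_identical(attr(tr, "flatten_dim"), 6L)
  expect_error(
    shapeTrace(fcnConfig(input_len = 3, conv_blocks = list(
      list(out_channels = 1L, kernel_len = 4L, activation = "none",
           batch_norm = FALSE)))),
    "conv0")
})

test_that("analytic MAC count matches hand counts and scales linearly", {
  expect_identical(countMacs(fcnConfig()), 25744698)
  # single conv 1->1 kernel 1 on input 10 + classifier 10 -> 1
  cfg <- fcnConfig(input_len = 10, conv_blocks = list(
    list(out_channels = 1L, kernel_len = 1L, activation = "none",
         batch_norm = FALSE)), avgpool_kernel = 1L, n_classes = 1L)
  expect_identical(countMacs(cfg), 20)
  # doubling the last conv's channels doubles that layer's term
  base <- fcnConfig(avgpool_kernel = 997L, n_classes = 3L)  # pool-to-1
  cfg2 <- base; cfg2$conv_blocks[[2]]$out_channels <- 240L
  conv_term <- function(cfg) {
    tr <- shapeTrace(cfg)
    r <- tr[tr$layer == "conv1", ]
    r$out_len * r$out_channels * cfg$conv_blocks[[2]]$kernel_len *
      r$in_channels
  }
  expect_equal(conv_term(cfg2), 2 * conv_term(base))
})

test_that("analytic MACs equal the instrumented multiply counter", {
  # random small configs drawn from the search ranges
  set.seed(21)
  for (rep in 1:4) {
    nconv <- sample(1:2, 1)
    blocks <- lapply(seq_len(nconv), function(i) {
      list(out_channels = sample(4:8, 1), kernel_len = sample(2:4, 1),
           activation = sample(c("none", "relu", "tanh"), 1),
           batch_norm = sample(c(TRUE, FALSE), 1))
    })
    cfg <- fcnConfig(input_len = sample(30:60, 1), conv_blocks = blocks,
                     avgpool_kernel = sample(2:4, 1))
    model <- buildFcn(cfg, seed = rep)
    inst <- countMacsInstrumented(model, rnorm(cfg$input_len))
    expect_identical(inst$macs, countMacs(cfg))
  }
})

test_that("instrumented naive forward agrees with the batched forward", {
  cfg <- fcnConfig(input_len = 30, conv_blocks = list(
    list(out_channels = 3L, kernel_len = 3L, activation = "none",
         batch_norm = FALSE)), avgpool_kernel = 2L)
  m <- buildFcn(cfg, seed = 3)
  x <- rnorm(30)
  inst <- countMacsInstrumented(m, x)
  batched <- edapain:::fcnForward(m, matrix(x, ncol = 1))$logits
  expect_equal(inst$logits, as.numeric(batched), tolerance = 1e-12)
})

test_that("initialization is seeded and the forward pass is finite", {
  m1 <- buildFcn(fcnConfig(), seed = 7)
  m2 <- buildFcn(fcnConfig(), seed = 7)
  m3 <- buildFcn(fcnConfig(), seed = 8)
  expect_identical(m1@params, m2@params)
  expect_false(identical(m1@params$conv0_W, m3@params$conv0_W))
  expect_identical(
    sort(names(m1@params)),
    sort(c("conv0_W", "conv0_b", "conv0_gamma", "conv0_beta",
           "conv1_W", "conv1_b", "conv1_gamma", "conv1_beta",
           "cls_W", "cls_b")))
  p <- predictFcn(m1, matrix(0, 1000, 2))
  expect_true(all(is.finite(p)))
  expect_equal(rowSums(p), c(1, 1), tolerance = 1e-6)
})

test_that("class/confidence prediction follows softmax with low-index ties", {
  r <- predictWithConfidence(c(0, 0, 0))
  expect_identical(as.character(r$class), "NoPain")
  expect_equal(r$confidence, 1 / 3)
  r2 <- predictWithConfidence(c(10, 0, 0))
  expect_identical(as.character(r2$class), "NoPain")
  expect_equal(r2$confidence, exp(10) / (exp(10) + 2), tolerance = 1e-9)
  # shift invariance
  expect_equal(predictWithConfidence(c(1, 5, 2))$confidence,
               predictWithConfidence(c(1, 5, 2) + 100)$confidence)
  expect_error(predictWithConfidence(c(NA, 1, 2)), "finite")
  # softmax sums to one; confidence is at least 1/n_classes
  set.seed(2)
  l <- matrix(rnorm(30), 10, 3)
  r3 <- predictWithConfidence(l)
  expect_true(all(r3$confidence >= 1 / 3 - 1e-12))
})

test_that("shape trace matches an actual forward pass for random configs", {
  set.seed(31)
  for (rep in 1:3) {
    blocks <- lapply(1:2, function(i) {
      list(out_channels = sample(4:16, 1), kernel_len = sample(2:4, 1),
           activation = "relu", batch_norm = TRUE)
    })
    cfg <- fcnConfig(input_len = sample(60:120, 1), conv_blocks = blocks,
                     avgpool_kernel = sample(2:6, 1))
    m <- buildFcn(cfg, seed = rep)
    fwd <- edapain:::fcnForward(m, matrix(rnorm(cfg$input_len * 3), ncol = 3),
                                train = TRUE)
    tr <- shapeTrace(cfg)
    expect_identical(dim(fwd$logits), c(3L, 3L))
    expect_identical(nrow(fwd$Fm), attr(tr, "flatten_dim"))
    last <- fwd$caches[[2]]
    expect_identical(dim(last$Y)[1:2],
                     c(tr$out_channels[tr$layer == "conv1"],
                       tr$out_len[tr$layer == "conv1"]))
  }
})

test_that("analytic backward matches numerical gradients", {
  cfg <- tinyFcnConfig()
  m <- buildFcn(cfg, seed = 5)
  set.seed(2)
  X <- matrix(rnorm(40 * 6), 40, 6)
  y <- sample(1:3, 6, replace = TRUE)
  oh <- matrix(0, 6, 3); oh[cbind(1:6, y)] <- 1
  lossOf <- function(model) {
    fwd <- edapain:::fcnForward(model, X, train = TRUE)
    p <- edapain:::softmaxProbs(fwd$logits)
    -sum(log(p[oh == 1])) / 6
  }
  fwd <- edapain:::fcnForward(m, X, train = TRUE)
  p <- edapain:::softmaxProbs(fwd$logits)
  grads <- edapain:::fcnBackward(m, fwd, (p - oh) / 6)
  eps <- 1e-6
  for (nm in names(grads)) {
    pa <- m@params[[nm]]
    idx <- unique(round(seq(1, length(pa), length.out = min(4, length(pa)))))
    for (ii in idx) {
      m2 <- m; m2@params[[nm]][ii] <- pa[ii] + eps
      m3 <- m; m3@params[[nm]][ii] <- pa[ii] - eps
      num <- (lossOf(m2) - lossOf(m3)) / (2 * eps)
      expect_equal(grads[[nm]][ii], num, tolerance = 1e-4,
                   label = sprintf("grad %s[%d]", nm, ii))
    }
  }
})

test_that("fused single-precision step agrees with the double reference", {
  cfg <- tinyFcnConfig()
  m <- buildFcn(cfg, seed = 5)
  set.seed(2)
  X <- matrix(rnorm(40 * 9), 40, 9)
  y <- sample(1:3, 9, replace = TRUE)
  oh <- matrix(0, 9, 3); oh[cbind(1:9, y)] <- 1
  ccfg <- edapain:::fusedConfig(cfg)
  step <- edapain:::.fcnTrainBatch(X, oh, m@params, m@state, ccfg)
  fwd <- edapain:::fcnForward(m, X, train = TRUE)
  p <- edapain:::softmaxProbs(fwd$logits)
  gd <- edapain:::fcnBackward(m, fwd, (p - oh) / 9)
  expect_equal(step$loss, -sum(log(p[oh == 1])) / 9, tolerance = 1e-6)
  for (nm in names(gd)) {
    scale <- max(1e-3, max(abs(gd[[nm]])))
    expect_lt(max(abs(step$grads[[nm]] - gd[[nm]])) / scale, 1e-4)
  }
  expect_equal(unlist(step$state), unlist(fwd$state), tolerance = 1e-6)
  pf <- edapain:::.fcnPredictBatchF(X, m@params, m@state, ccfg)
  expect_equal(max(abs(pf - predictFcn(m, X))), 0, tolerance = 1e-6)
})

test_that("checkpoints round-trip the model exactly", {
  m <- buildFcn(tinyFcnConfig(), seed = 9)
  f <- withr::local_tempfile(fileext = ".rds")
  saveFcn(m, f)
  m2 <- loadFcn(f)
  expect_identical(m2@params, m@params)
  X <- matrix(rnorm(40 * 3), 40, 3)
  expect_identical(predictFcn(m2, X), predictFcn(m, X))
})
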