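# a fast stand-in classifier: any FcnModel works; use a tiny untrained one
# re-dimensioned to the streaming window length where full-size cost is not
# the point, and the real default where cadence must be exact.

smallStreamModel <- function() {
  buildFcn(fcnConfig(input_len = 1000L, conv_blocks = list(
    list(out_channels = 2L, kernel_len = 2L, activation = "relu",
         batch_norm = TRUE)), avgpool_kernel = 4L), seed = 2)
}

test_that("first event fires when the buffer fills, then every stride", {
  m <- smallStreamModel()
  st <- streamState()
  events <- list()
  x <- 2 + 0.1 * sin(2 * pi * 0.5 * (0:2499) / 100)
  for (i in seq_along(x)) {
    ev <- pushSample(st, x[i], m)
    if (!is.null(ev)) events[[length(events) + 1L]] <- ev
  }
  events <- do.call(rbind, events)
  expect_identical(events$sample_index[1], 1000L)
  expect_true(all(diff(events$sample_index) == 100L))
  expect_identical(nrow(events), 1L + (2500L - 1000L) %/% 100L)
  # 999 samples: no event yet
  st2 <- streamState()
  for (i in 1:999) expect_null(pushSample(st2, 2, m))
  # state boundedness
  expect_lte(length(st@env$buffer), 1000L)
  expect_true(st@env$counter >= 0 && st@env$counter < 100L)
})

test_that("non-finite samples are rejected and leave the state unchanged", {
  m <- smallStreamModel()
  st <- streamState()
  for (i in 1:10) pushSample(st, 2, m)
  n_before <- st@env$n_seen
  expect_error(pushSample(st, NaN, m), "finite")
  expect_error(pushSample(st, Inf, m), "finite")
  expect_identical(st@env$n_seen, n_before)
})

test_that("replay emits the closed-form event count and is deterministic", {
  m <- smallStreamModel()
  rec <- generateRecording(synthConfig(n_low = 0, n_high = 0), "S01",
                           seed = 5)  # 60 s baseline only
  ev <- replayRecording(rec, m)
  expect_identical(nrow(ev), 1L + (6000L - 1000L) %/% 100L)  # 51
  ev2 <- replayRecording(rec, m)
  expect_identical(ev, ev2)
  expect_error(replayRecording(rec, m, fs = 50), "Hz")
})

test_that("replay equals batch inference on the same window boundaries", {
  m <- smallStreamModel()
  rec <- generateRecording(synthConfig(n_low = 1, n_high = 1, rest_dur = 5,
                                       baseline_dur = 20), "S01", seed = 9)
  ev <- replayRecording(rec, m)
  x <- conductance(rec)
  for (r in seq_len(nrow(ev))) {
    e <- ev$sample_index[r]
    w <- butterLowpass(x[(e - 999):e], 100)
    p <- predictFcn(m, matrix(w, ncol = 1))
    expect_identical(as.character(ev$class[r]),
                     labelLevels[max.col(p, ties.method = "first")])
    expect_equal(ev$confidence[r], max(p), tolerance = 1e-12)
  }
})

test_that("ground-truth alignment uses the majority rule with late-start ties", {
  sched <- IRanges::IRanges(start = c(1L, 2001L), width = c(1000L, 1000L))
  S4Vectors::mcols(sched)$label <- factor(c("NoPain", "LowPain"),
                                          levels = labelLevels)
  mkev <- function(idx) data.frame(sample_index = idx,
                                   class = factor("NoPain",
                                                  levels = labelLevels),
                                   confidence = 1)
  # window fully inside the Low trial
  expect_identical(as.character(alignTruth(mkev(3000L), sched)), "LowPain")
  # 600 rest + 400 trial -> majority NoPain
  expect_identical(as.character(alignTruth(mkev(2400L), sched)), "NoPain")
  # exact 500/500 rest -> trial tie resolves to the later-starting trial
  expect_identical(as.character(alignTruth(mkev(2500L), sched)), "LowPain")
  # window beyond the schedule -> NoPain
  expect_identical(as.character(alignTruth(mkev(9000L), sched)), "NoPain")
})

test_that("stream scoring matches event-level agreement", {
  ev <- data.frame(
    sample_index = seq(1000L, by = 100L, length.out = 10L),
    class = factor(rep("NoPain", 10), levels = labelLevels),
    confidence = rep(0.9, 10))
  truth <- factor(rep(c("NoPain", "LowPain"), c(6, 4)), levels = labelLevels)
  r <- scoreStream(ev, truth)
  expect_equal(r$accuracy, 0.6)
  rp <- scoreStream(ev, factor(rep("NoPain", 10), levels = labelLevels))
  expect_equal(rp$accuracy, 1)
  expect_error(scoreStream(ev, truth[1:5]), "truth")
})
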