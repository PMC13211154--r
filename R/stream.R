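#' Initialize the real-time sliding-window estimator state
#'
#' The streaming algorithm keeps a first-in-first-out buffer of the most
#' recent `win_len` samples. Once the buffer first fills, a prediction is
#' emitted, and thereafter one prediction every `stride` samples: each
#' emission filters the current buffer with the causal Butterworth filter
#' and runs the classifier on the filtered window.
#'
#' @param win_len Window length in samples.
#' @param stride Samples between successive predictions.
#' @param fs Sampling rate of the stream, Hz.
#' @param cutoff,order Butterworth filter parameters.
#' @return A [StreamState].
#' @export
streamState <- function(win_len = 1000L, stride = 100L, fs = 100,
                        cutoff = 3, order = 4) {
  e <- new.env(parent = emptyenv())
  e$buffer <- numeric(win_len)
  e$fill <- 0L
  e$window_ready <- FALSE
  e$counter <- 0L
  e$win_len <- as.integer(win_len)
  e$stride <- as.integer(stride)
  e$fs <- fs
  e$cutoff <- cutoff
  e$order <- order
  e$n_seen <- 0L
  new("StreamState", env = e)
}

streamPredict <- function(e, model) {
  w <- butterLowpass(e$buffer, e$fs, e$cutoff, e$order)
  p <- predictFcn(model, matrix(w, ncol = 1))
  idx <- max.col(p, ties.method = "first")
  data.frame(sample_index = e$n_seen,
             class = painFactor(PAIN_LEVELS[idx]),
             confidence = p[1, idx])
}

#' Push one sample through the streaming estimator
#'
#' Appends the sample to the buffer. On the sample that first fills the
#' buffer, and then every `stride` samples, the buffered window is
#' filtered and classified and a prediction event is emitted. Non-finite
#' samples are rejected with an error and leave the state unchanged.
#'
#' @param state A [streamState()].
#' @param x One conductance sample (µS).
#' @param model A trained [FcnModel].
#' @return A one-row data.frame event (`sample_index`, `class`,
#'   `confidence`) or `NULL` when no prediction is due.
#' @export
pushSample <- function(state, x, model) {
  e <- state@env
  if (length(x) != 1L || !is.finite(x)) {
    stopf("sample must be a single finite value")
  }
  e$n_seen <- e$n_seen + 1L
  if (!e$window_ready) {
    e$fill <- e$fill + 1L
    e$buffer[e$fill] <- x
    if (e$fill == e$win_len) {
      e$window_ready <- TRUE
      e$counter <- 0L
      return(streamPredict(e, model))
    }
    return(invisible(NULL))
  }
  e$buffer <- c(e$buffer[-1L], x)  # evict oldest, append newest
  e$counter <- e$counter + 1L
  if (e$counter == e$stride) {
    e$counter <- 0L
    return(streamPredict(e, model))
  }
  invisible(NULL)
}

#' Replay a recording through the streaming estimator
#'
#' Feeds the recording sample-by-sample through [pushSample()] and collects
#' the emitted prediction events. The first event fires at sample
#' `win_len`; subsequent events are exactly `stride` samples apart.
#'
#' @param recording An [EdaRecording].
#' @param model A trained [FcnModel].
#' @param win_len,stride Window length and prediction stride in samples.
#' @param fs Expected sampling rate; a mismatch with the recording is an
#'   error.
#' @return data.frame of events: `sample_index` (1-based index of the
#'   triggering sample), `class`, `confidence`.
#' @export
replayRecording <- function(recording, model, win_len = 1000L,
                            stride = 100L, fs = 100) {
  if (!isTRUE(all.equal(sampleRate(recording), fs))) {
    stopf("recording sampled at %g Hz but the stream expects %g Hz",
          sampleRate(recording), fs)
  }
  st <- streamState(win_len, stride, fs)
  x <- conductance(recording)
  events <- vector("list", max(0L, (length(x) - win_len) %/% stride + 1L))
  n_ev <- 0L
  for (i in seq_along(x)) {
    ev <- pushSample(st, x[i], model)
    if (!is.null(ev)) {
      n_ev <- n_ev + 1L
      events[[n_ev]] <- ev
    }
  }
  if (n_ev == 0L) {
    return(data.frame(sample_index = integer(),
                      class = painFactor(character()),
                      confidence = numeric()))
  }
  do.call(rbind, events[seq_len(n_ev)])
}

#' Ground-truth label for each prediction event
#'
#' Each event's window covers samples `(sample_index - win_len,
#' sample_index]`. The window is labeled by the condition covering the
#' majority of its samples; unannotated stretches (rests, pre-schedule)
#' count as NoPain. Exact ties resolve toward the later-starting
#' condition.
#'
#' @param events Event data.frame from [replayRecording()].
#' @param schedule [IRanges::IRanges] of stimulus events with `label`
#'   mcols (see [buildSchedule()]).
#' @param win_len Window length in samples.
#' @return Factor of truth labels, one per event.
#' @export
alignTruth <- function(events, schedule, win_len = 1000L) {
  lab <- as.character(S4Vectors::mcols(schedule)$label)
  starts <- IRanges::start(schedule)
  ends <- IRanges::end(schedule)
  out <- character(nrow(events))
  for (i in seq_len(nrow(events))) {
    w_end <- events$sample_index[i]
    w_start <- w_end - win_len + 1L
    # per-sample condition over the window; rests and anything outside the
    # schedule count as NoPain
    cond <- rep("NoPain", win_len)
    for (j in which(lab != "NoPain")) {
      a <- max(w_start, starts[j])
      b <- min(w_end, ends[j])
      if (a <= b) cond[(a - w_start + 1L):(b - w_start + 1L)] <- lab[j]
    }
    cover <- table(factor(cond, levels = PAIN_LEVELS))
    cand <- PAIN_LEVELS[cover == max(cover)]
    if (length(cand) == 1L) {
      out[i] <- cand
    } else {
      # tie: the condition whose latest run starts latest in the window
      r <- rle(cond)
      run_starts <- cumsum(c(1L, r$lengths[-length(r$lengths)]))
      latest <- vapply(cand, function(l) max(run_starts[r$values == l]),
                       numeric(1))
      out[i] <- cand[which.max(latest)]
    }
  }
  painFactor(out)
}

#' Score a replayed event stream against ground truth
#'
#' @param events Event data.frame from [replayRecording()].
#' @param truth Factor of per-event truth labels from [alignTruth()].
#' @return A `MetricsReport` (see [evaluateMetrics()]).
#' @export
scoreStream <- function(events, truth) {
  if (nrow(events) != length(truth)) {
    stopf("got %d events but %d truth labels", nrow(events), length(truth))
  }
  evaluateMetrics(truth, events$class)
}
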