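#' Causal low-pass Butterworth filter
#'
#' 4th-order low-pass Butterworth (default cut-off 3 Hz), applied as a
#' single causal forward pass. The filter state is initialised to the
#' steady state of the signal's first value (implemented by prepending a
#' constant run-in that is discarded), so a constant signal passes through
#' unchanged and windows cut from the middle of a recording do not start
#' with a zero-state step transient. The same routine is used offline and
#' inside the streaming loop so training and deployment distributions
#' match.
#'
#' @param x Numeric signal.
#' @param fs Sampling rate, Hz.
#' @param cutoff Cut-off frequency, Hz; must be below the Nyquist rate.
#' @param order Filter order.
#' @return Filtered signal, same length as `x`; DC gain 1.
#' @examples
#' butterLowpass(rep(2, 100), fs = 100)  # constant in, constant out
#' @export
butterLowpass <- function(x, fs, cutoff = 3, order = 4) {
  if (length(x) == 0L) stopf("empty input")
  if (fs <= 2 * cutoff) {
    stopf("cutoff (%g Hz) must be below the Nyquist rate (fs/2 = %g Hz)",
          cutoff, fs / 2)
  }
  bf <- signal::butter(order, cutoff / (fs / 2), type = "low")
  # constant run-in long enough for the step response to settle to ~1e-9
  pad <- min(length(x), as.integer(ceiling(10 * fs / cutoff)))
  pad <- max(pad, 8L)
  y <- signal::filter(bf, c(rep(x[1], pad), x))
  as.numeric(y[-seq_len(pad)])
}

#' Cut a segment into overlapping fixed-length windows
#'
#' Windows start at multiples of `step = win_len * (1 - overlap_fraction)`;
#' trailing samples that do not fill a window are dropped. A 60 s segment at
#' 100 Hz with 50% overlap yields 11 windows of 1000 samples.
#'
#' @param x Numeric segment.
#' @param win_len Window length in samples.
#' @param overlap_fraction Overlap between consecutive windows, in `[0, 1)`.
#' @return A `win_len` x n matrix of windows (zero columns if `x` is
#'   shorter than `win_len`), with attribute `starts` giving 0-based
#'   start offsets.
#' @export
segmentOverlapping <- function(x, win_len = 1000L, overlap_fraction = 0.5) {
  if (overlap_fraction < 0 || overlap_fraction >= 1) {
    stopf("overlap_fraction must be in [0, 1)")
  }
  step <- as.integer(round(win_len * (1 - overlap_fraction)))
  L <- length(x)
  if (L < win_len) {
    out <- matrix(numeric(0), nrow = win_len, ncol = 0)
    attr(out, "starts") <- integer(0)
    return(out)
  }
  n_win <- (L - win_len) %/% step + 1L
  starts <- (seq_len(n_win) - 1L) * step
  out <- vapply(starts, function(s) x[(s + 1L):(s + win_len)],
                numeric(win_len))
  out <- matrix(out, nrow = win_len)
  attr(out, "starts") <- starts
  out
}

#' Extract the non-overlapping trial windows of a recording
#'
#' One window per Low/High pain event, aligned to the event onset. Events
#' shorter than `win_len` are skipped with a warning.
#'
#' @param recording An [EdaRecording] (raw or pre-filtered samples may be
#'   supplied via `x`).
#' @param win_len Window length in samples.
#' @param x Optional replacement sample vector (e.g. the filtered signal).
#' @return List with `windows` (`win_len` x n matrix), `labels` (factor) and
#'   `starts` (0-based offsets).
#' @export
segmentTrials <- function(recording, win_len = 1000L,
                          x = conductance(recording)) {
  ev <- stimulusEvents(recording)
  lab <- as.character(S4Vectors::mcols(ev)$label)
  keep <- lab != "NoPain"
  ev <- ev[keep]
  lab <- lab[keep]
  ok <- IRanges::width(ev) >= win_len
  if (any(!ok)) {
    warning(sprintf("%s: skipping %d trial event(s) shorter than %d samples",
                    subjectId(recording), sum(!ok), win_len))
  }
  ev <- ev[ok]
  lab <- lab[ok]
  starts <- IRanges::start(ev) - 1L
  win <- vapply(starts, function(s) x[(s + 1L):(s + win_len)],
                numeric(win_len))
  list(windows = matrix(win, nrow = win_len),
       labels = painFactor(lab), starts = starts)
}

#' Build the labeled window dataset from a cohort
#'
#' Applies the class-balancing windowing scheme: the baseline (NoPain)
#' segment of each subject is cut with 50%-overlapping windows, while pain
#' trials are kept as single non-overlapping windows aligned to stimulus
#' onsets. With the default durations this yields 11 NoPain + 12 LowPain +
#' 12 HighPain windows per subject. Filtering (when enabled) is applied to
#' the full recording before segmentation.
#'
#' @param cohort An [EdaCohort].
#' @param win_len Window length in samples.
#' @param overlap_fraction Baseline window overlap.
#' @param filter_first Apply [butterLowpass()] to each recording first.
#' @param cutoff,order Filter parameters.
#' @return A [WindowSet].
#' @examples
#' ws <- buildWindowSet(generateCohort(synthConfig(n_subjects = 1)))
#' classCounts(ws)
#' @export
buildWindowSet <- function(cohort, win_len = 1000L, overlap_fraction = 0.5,
                           filter_first = TRUE, cutoff = 3, order = 4) {
  mats <- list()
  subj <- character()
  labs <- character()
  starts <- integer()
  for (r in recordings(cohort)) {
    x <- conductance(r)
    if (filter_first) x <- butterLowpass(x, sampleRate(r), cutoff, order)
    ev <- stimulusEvents(r)
    evlab <- as.character(S4Vectors::mcols(ev)$label)
    base_ev <- ev[evlab == "NoPain"]
    for (i in seq_along(base_ev)) {
      seg <- x[IRanges::start(base_ev)[i]:IRanges::end(base_ev)[i]]
      m <- segmentOverlapping(seg, win_len, overlap_fraction)
      if (ncol(m)) {
        mats[[length(mats) + 1L]] <- m
        subj <- c(subj, rep(subjectId(r), ncol(m)))
        labs <- c(labs, rep("NoPain", ncol(m)))
        starts <- c(starts, attr(m, "starts") + IRanges::start(base_ev)[i] - 1L)
      }
    }
    tr <- segmentTrials(r, win_len, x = x)
    if (ncol(tr$windows)) {
      mats[[length(mats) + 1L]] <- tr$windows
      subj <- c(subj, rep(subjectId(r), ncol(tr$windows)))
      labs <- c(labs, as.character(tr$labels))
      starts <- c(starts, tr$starts)
    }
  }
  mat <- if (length(mats)) do.call(cbind, mats) else
    matrix(numeric(0), nrow = win_len, ncol = 0)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(eda = mat),
    colData = S4Vectors::DataFrame(
      subject_id = subj, label = painFactor(labs), start_sample = starts
    )
  )
  new("WindowSet", se)
}
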