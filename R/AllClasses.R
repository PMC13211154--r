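#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

#' EdaRecording: one subject's annotated EDA stream
#'
#' Container for a single subject's continuous skin-conductance recording
#' together with its stimulus annotations. Conductance is stored in
#' microsiemens at a fixed sampling rate; stimulus events are an
#' [IRanges::IRanges] over sample indices (1-based, inclusive) with a
#' `label` metadata column taking values `NoPain`, `LowPain`, `HighPain`.
#'
#' @slot subjectId Character scalar identifier.
#' @slot fs Sampling rate in Hz.
#' @slot conductance Numeric vector of conductance samples (µS), all > 0.
#' @slot events IRanges of stimulus events with `label` in `mcols`.
#'
#' @aliases EdaRecording-class
#' @exportClass EdaRecording
setClass("EdaRecording",
  representation(
    subjectId = "character",
    fs = "numeric",
    conductance = "numeric",
    events = "IRanges"
  )
)

setValidity("EdaRecording", function(object) {
  msg <- character()
  if (length(object@subjectId) != 1L) msg <- c(msg, "subjectId must be a single string")
  if (length(object@fs) != 1L || object@fs <= 0) msg <- c(msg, "fs must be a positive scalar")
  if (any(!is.finite(object@conductance)) || any(object@conductance <= 0)) {
    msg <- c(msg, "conductance values must be finite and > 0")
  }
  ev <- object@events
  if (length(ev)) {
    lab <- S4Vectors::mcols(ev)$label
    if (is.null(lab) || !all(as.character(lab) %in% PAIN_LEVELS)) {
      msg <- c(msg, "events must carry a 'label' mcols column in NoPain/LowPain/HighPain")
    }
    st <- IRanges::start(ev)
    if (is.unsorted(st, strictly = TRUE)) msg <- c(msg, "events must be sorted by onset")
    if (length(ev) > 1L && any(IRanges::start(ev)[-1L] <= IRanges::end(ev)[-length(ev)])) {
      msg <- c(msg, "events must be non-overlapping")
    }
    if (max(IRanges::end(ev)) > length(object@conductance)) {
      msg <- c(msg, "events extend beyond the recording")
    }
  }
  if (length(msg)) msg else TRUE
})

#' EdaCohort: a list of EdaRecording objects with their generating config
#'
#' @slot recordings List of [EdaRecording] objects with distinct subject ids.
#' @slot config The `SynthConfig` list that generated the cohort (may be
#'   empty for cohorts read from disk that carry no config file).
#'
#' @aliases EdaCohort-class
#' @exportClass EdaCohort
setClass("EdaCohort",
  representation(recordings = "list", config = "list")
)

setValidity("EdaCohort", function(object) {
  if (!all(vapply(object@recordings, is, logical(1), "EdaRecording"))) {
    return("all elements must be EdaRecording objects")
  }
  ids <- vapply(object@recordings, function(r) r@subjectId, character(1))
  if (anyDuplicated(ids)) return("subject ids must be distinct")
  TRUE
})

#' WindowSet: labeled fixed-length EDA windows
#'
#' Extends [SummarizedExperiment::SummarizedExperiment]. The single assay
#' `"eda"` holds one column per window (rows are the `win_len` time samples);
#' `colData` carries `subject_id`, `label` (factor NoPain/LowPain/HighPain)
#' and `start_sample` (0-based offset into the source recording).
#'
#' @aliases WindowSet-class
#' @exportClass WindowSet
setClass("WindowSet", contains = "SummarizedExperiment")

setValidity("WindowSet", function(object) {
  cd <- SummarizedExperiment::colData(object)
  need <- c("subject_id", "label", "start_sample")
  if (!all(need %in% colnames(cd))) {
    return(sprintf("colData must contain %s", paste(need, collapse = ", ")))
  }
  if (!all(levels(cd$label) == PAIN_LEVELS)) {
    return("label must be a factor with levels NoPain, LowPain, HighPain")
  }
  if (!"eda" %in% SummarizedExperiment::assayNames(object)) {
    return("assay 'eda' is required")
  }
  TRUE
})

#' PcaModel: centered principal-component projection of the feature space
#'
#' @slot rotation 36 x k loadings matrix with orthonormal columns.
#' @slot center Per-feature centering offsets (length 36).
#' @slot varExplained Fraction of variance per retained component,
#'   non-increasing.
#' @slot totalVariance Sum of all feature-space eigenvalues.
#'
#' @aliases PcaModel-class
#' @exportClass PcaModel
setClass("PcaModel",
  representation(
    rotation = "matrix",
    center = "numeric",
    varExplained = "numeric",
    totalVariance = "numeric"
  )
)

setValidity("PcaModel", function(object) {
  k <- ncol(object@rotation)
  if (length(object@center) != nrow(object@rotation)) {
    return("center length must match rotation rows")
  }
  gram <- crossprod(object@rotation)
  if (max(abs(gram - diag(k))) > 1e-8) return("rotation columns must be orthonormal")
  if (is.unsorted(rev(object@varExplained))) {
    return("varExplained must be non-increasing")
  }
  TRUE
})

#' FcnModel: a fully convolutional network with its configuration
#'
#' Holds the declarative architecture (see [fcnConfig()]) plus all learnable
#' parameters and batch-norm running statistics. Models are immutable value
#' objects: training returns a new `FcnModel`.
#'
#' @slot config Architecture list from [fcnConfig()].
#' @slot params Named list of parameter arrays (conv weights/biases,
#'   batch-norm gamma/beta, classifier weights).
#' @slot state Named list of batch-norm running means/variances.
#' @slot trained Logical; `TRUE` after [trainFcn()].
#'
#' @aliases FcnModel-class
#' @exportClass FcnModel
setClass("FcnModel",
  representation(
    config = "list",
    params = "list",
    state = "list",
    trained = "logical"
  )
)

#' StreamState: mutable buffer state of the real-time estimator
#'
#' Reference-semantics holder (an environment) for the sliding-window
#' buffer, the ready flag and the stride counter of the streaming
#' algorithm. Create with [streamState()]; advance with [pushSample()].
#'
#' @slot env Environment holding `buffer`, `window_ready`, `counter`,
#'   `n_seen`, `win_len`, `stride`, `fs`.
#'
#' @aliases StreamState-class
#' @exportClass StreamState
setClass("StreamState", representation(env = "environment"))
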