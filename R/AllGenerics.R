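#' Accessors for edapain classes
#'
#' @param x An object.
#' @param ... Ignored.
#' @return The corresponding slot value.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("subjectId", function(x, ...) standardGeneric("subjectId"))

#' @rdname accessors
#' @export
setGeneric("sampleRate", function(x, ...) standardGeneric("sampleRate"))

#' @rdname accessors
#' @export
setGeneric("conductance", function(x, ...) standardGeneric("conductance"))

#' @rdname accessors
#' @export
setGeneric("stimulusEvents", function(x, ...) standardGeneric("stimulusEvents"))

#' @rdname accessors
#' @export
setGeneric("recordings", function(x, ...) standardGeneric("recordings"))

#' @rdname accessors
#' @export
setGeneric("windowLabels", function(x, ...) standardGeneric("windowLabels"))

#' @rdname accessors
#' @export
setGeneric("windowSubjects", function(x, ...) standardGeneric("windowSubjects"))

#' @rdname accessors
#' @export
setGeneric("classCounts", function(x, ...) standardGeneric("classCounts"))

#' @rdname accessors
#' @export
setMethod("subjectId", "EdaRecording", function(x, ...) x@subjectId)

#' @rdname accessors
#' @export
setMethod("sampleRate", "EdaRecording", function(x, ...) x@fs)

#' @rdname accessors
#' @export
setMethod("conductance", "EdaRecording", function(x, ...) x@conductance)

#' @rdname accessors
#' @export
setMethod("stimulusEvents", "EdaRecording", function(x, ...) x@events)

#' @rdname accessors
#' @export
setMethod("recordings", "EdaCohort", function(x, ...) x@recordings)

#' @describeIn accessors Number of recordings in a cohort.
#' @export
setMethod("length", "EdaCohort", function(x) length(x@recordings))

#' @export
setMethod("[[", "EdaCohort", function(x, i) x@recordings[[i]])

#' @rdname accessors
#' @export
setMethod("windowLabels", "WindowSet", function(x, ...) {
  SummarizedExperiment::colData(x)$label
})

#' @rdname accessors
#' @export
setMethod("windowSubjects", "WindowSet", function(x, ...) {
  as.character(SummarizedExperiment::colData(x)$subject_id)
})

#' @rdname accessors
#' @export
setMethod("classCounts", "WindowSet", function(x, ...) {
  table(windowLabels(x))
})

setMethod("show", "EdaRecording", function(object) {
  lab <- table(painFactor(as.character(S4Vectors::mcols(object@events)$label)))
  cat(sprintf(
    "EdaRecording '%s': %d samples @ %g Hz (%.1f s), %d events (%s)\n",
    object@subjectId, length(object@conductance), object@fs,
    length(object@conductance) / object@fs, length(object@events),
    paste(sprintf("%d %s", as.integer(lab), names(lab)), collapse = ", ")
  ))
})

setMethod("show", "EdaCohort", function(object) {
  cat(sprintf("EdaCohort: %d recordings\n", length(object)))
  if (length(object)) show(object[[1]])
})

setMethod("show", "WindowSet", function(object) {
  cc <- classCounts(object)
  cat(sprintf(
    "WindowSet: %d windows of %d samples, %d subjects (%s)\n",
    ncol(object), nrow(object), length(unique(windowSubjects(object))),
    paste(sprintf("%s=%d", names(cc), as.integer(cc)), collapse = ", ")
  ))
})

setMethod("show", "PcaModel", function(object) {
  cat(sprintf(
    "PcaModel: %d features -> %d components (%.1f%% variance retained)\n",
    nrow(object@rotation), ncol(object@rotation),
    100 * sum(object@varExplained)
  ))
})

setMethod("show", "FcnModel", function(object) {
  cfg <- object@config
  cat(sprintf(
    "FcnModel (%s): input [1,%d] -> %d conv blocks -> avgpool %d -> %d classes; %s MACs/window\n",
    if (object@trained) "trained" else "untrained",
    cfg$input_len, length(cfg$conv_blocks), cfg$avgpool_kernel, cfg$n_classes,
    format(countMacs(cfg), big.mark = ",")
  ))
})
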