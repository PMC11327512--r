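#' Accessors for pipeline objects
#'
#' Small generic accessors so user code never touches slots directly:
#' `waveform()` returns the sample data, `sampleRate()` the rate in Hz,
#' `subjectID()` / `phase()` the provenance tags, `duration()` the length in
#' seconds, `melValues()` / `melConfig()` the spectrogram matrix and its
#' front-end configuration, `payload()` / `codec()` the encoded bytes, and
#' `nFolds()` / `foldAssignment()` the cross-validation plan.
#'
#' @param x a pipeline object.
#' @return the corresponding slot value.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("waveform", function(x) standardGeneric("waveform"))
#' @rdname accessors
#' @export
setGeneric("sampleRate", function(x) standardGeneric("sampleRate"))
#' @rdname accessors
#' @export
setGeneric("subjectID", function(x) standardGeneric("subjectID"))
#' @rdname accessors
#' @export
setGeneric("phase", function(x) standardGeneric("phase"))
#' @rdname accessors
#' @export
setGeneric("duration", function(x) standardGeneric("duration"))
#' @rdname accessors
#' @export
setGeneric("melValues", function(x) standardGeneric("melValues"))
#' @rdname accessors
#' @export
setGeneric("melConfig", function(x) standardGeneric("melConfig"))
#' @rdname accessors
#' @export
setGeneric("payload", function(x) standardGeneric("payload"))
#' @rdname accessors
#' @export
setGeneric("codec", function(x) standardGeneric("codec"))
#' @rdname accessors
#' @export
setGeneric("nFolds", function(x) standardGeneric("nFolds"))
#' @rdname accessors
#' @export
setGeneric("foldAssignment", function(x) standardGeneric("foldAssignment"))

#' @rdname accessors
setMethod("waveform", "RawRecording", function(x) {
  if (ncol(x@waveform) == 1L) drop(x@waveform) else x@waveform
})
#' @rdname accessors
setMethod("waveform", "AudioSegment", function(x) x@waveform)
#' @rdname accessors
setMethod("sampleRate", "RawRecording", function(x) x@sample_rate)
#' @rdname accessors
setMethod("sampleRate", "AudioSegment", function(x) x@sample_rate)
#' @rdname accessors
setMethod("sampleRate", "EncodedClip", function(x) x@sample_rate)
#' @rdname accessors
setMethod("sampleRate", "MelConfig", function(x) x@sample_rate)
#' @rdname accessors
setMethod("subjectID", "RawRecording", function(x) x@subject_id)
#' @rdname accessors
setMethod("subjectID", "AudioSegment", function(x) x@subject_id)
#' @rdname accessors
setMethod("subjectID", "EncodedClip", function(x) x@subject_id)
#' @rdname accessors
setMethod("phase", "RawRecording", function(x) x@phase)
#' @rdname accessors
setMethod("phase", "AudioSegment", function(x) x@phase)
#' @rdname accessors
setMethod("phase", "EncodedClip", function(x) x@phase)
#' @rdname accessors
setMethod("duration", "RawRecording",
          function(x) nrow(x@waveform) / x@sample_rate)
#' @rdname accessors
setMethod("duration", "AudioSegment",
          function(x) length(x@waveform) / x@sample_rate)
#' @rdname accessors
setMethod("melValues", "MelSpectrogram", function(x) x@values)
#' @rdname accessors
setMethod("melConfig", "MelSpectrogram", function(x) x@config)
#' @rdname accessors
setMethod("payload", "EncodedClip", function(x) x@payload)
#' @rdname accessors
setMethod("codec", "EncodedClip", function(x) x@codec)
#' @rdname accessors
setMethod("nFolds", "FoldPlan", function(x) x@k)
#' @rdname accessors
setMethod("foldAssignment", "FoldPlan", function(x) x@assignment)

#' Subjects assigned to one fold
#'
#' @param plan a [FoldPlan-class].
#' @param fold fold index in `0:(k-1)`.
#' @return character vector of subject ids in that fold.
#' @export
foldSubjects <- function(plan, fold) {
  stopifnot(is(plan, "FoldPlan"))
  fold <- as.integer(fold)
  if (fold < 0L || fold >= plan@k) stop("fold index out of range")
  names(plan@assignment)[plan@assignment == fold]
}
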