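#' @import methods
#' @importFrom stats rnorm runif sd qt fft mvfft chisq.test setNames
#' @importFrom utils read.csv write.csv head tail
#' @useDynLib vowelscreen, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

.PHASES <- c("pre", "post")
.GROUPS <- c("normal", "aspiration")
.SEXES <- c("male", "female")
.SUBSTANCES <- c("water", "YP", "SF", "SBD", "FT3", "LF")

#' RawRecording: one subject-phase audio capture
#'
#' Holds a single raw voice capture (a sustained "ah" vowel, typically ~5 s)
#' together with its study metadata: anonymized subject identifier, recording
#' phase relative to swallowing, group label, sex, and optionally the
#' swallowed substance and recording device.
#'
#' The waveform is stored as a samples x channels matrix of values in
#' \[-1, 1\]; mono recordings have one column, stereo two.
#'
#' @slot subject_id opaque anonymized subject identifier.
#' @slot phase `"pre"` or `"post"` (relative to swallowing).
#' @slot group_label `"normal"`, `"aspiration"`, or `NA` when unknown.
#' @slot sex `"male"`, `"female"`, or `NA`.
#' @slot substance swallowed substance code or `NA`.
#' @slot device free-text recording device tag or `NA`.
#' @slot waveform numeric matrix, samples x channels.
#' @slot sample_rate sampling rate in Hz.
#'
#' @exportClass RawRecording
setClass("RawRecording",
  representation(
    subject_id = "character",
    phase = "character",
    group_label = "character",
    sex = "character",
    substance = "character",
    device = "character",
    waveform = "matrix",
    sample_rate = "integer"
  )
)

setValidity("RawRecording", function(object) {
  msg <- character()
  if (length(object@subject_id) != 1L || is.na(object@subject_id) ||
      !nzchar(object@subject_id))
    msg <- c(msg, "subject_id must be a single non-empty string")
  if (!(object@phase %in% .PHASES))
    msg <- c(msg, "phase must be 'pre' or 'post'")
  if (!is.na(object@group_label) && !(object@group_label %in% .GROUPS))
    msg <- c(msg, "group_label must be 'normal', 'aspiration' or NA")
  if (!is.na(object@sex) && !(object@sex %in% .SEXES))
    msg <- c(msg, "sex must be 'male', 'female' or NA")
  if (nrow(object@waveform) < 1L)
    msg <- c(msg, "waveform must contain at least one sample")
  if (!all(is.finite(object@waveform)))
    msg <- c(msg, "waveform samples must all be finite")
  if (!(ncol(object@waveform) %in% c(1L, 2L)))
    msg <- c(msg, "waveform must have 1 (mono) or 2 (stereo) channels")
  if (length(object@sample_rate) != 1L || is.na(object@sample_rate) ||
      object@sample_rate <= 0L)
    msg <- c(msg, "sample_rate must be a positive integer")
  if (length(msg)) msg else TRUE
})

#' Construct a RawRecording
#'
#' @param waveform numeric vector (mono) or samples x channels matrix.
#' @param sample_rate sampling rate in Hz.
#' @param subject_id anonymized subject identifier.
#' @param phase `"pre"` or `"post"`.
#' @param group_label optional `"normal"` / `"aspiration"`.
#' @param sex optional `"male"` / `"female"`.
#' @param substance optional swallowed-substance code
#'   (`"water"`, `"YP"`, `"SF"`, `"SBD"`, `"FT3"`, `"LF"`).
#' @param device optional device tag.
#' @return a [RawRecording-class] object.
#' @examples
#' rec <- RawRecording(sin(2 * pi * 440 * seq(0, 1, length.out = 8000)),
#'                     8000, "S01", "pre")
#' duration(rec)
#' @export
RawRecording <- function(waveform, sample_rate, subject_id, phase,
                         group_label = NA_character_, sex = NA_character_,
                         substance = NA_character_, device = NA_character_) {
  if (is.null(dim(waveform))) waveform <- matrix(waveform, ncol = 1L)
  new("RawRecording",
      subject_id = as.character(subject_id), phase = as.character(phase),
      group_label = as.character(group_label), sex = as.character(sex),
      substance = as.character(substance), device = as.character(device),
      waveform = waveform, sample_rate = as.integer(sample_rate))
}

#' AudioSegment: a fixed-length mono analysis segment
#'
#' A standardized slice of a recording: exactly `duration_s * sample_rate`
#' mono samples (default 2 s), ready for pairing and spectrogram extraction.
#'
#' @slot subject_id anonymized subject identifier of the parent recording.
#' @slot phase `"pre"` or `"post"`.
#' @slot segment_index 1-based index of this segment within its recording.
#' @slot waveform mono numeric vector of exactly `duration_s * sample_rate`
#'   samples.
#' @slot sample_rate sampling rate in Hz.
#' @slot duration_s nominal duration in seconds.
#'
#' @exportClass AudioSegment
setClass("AudioSegment",
  representation(
    subject_id = "character",
    phase = "character",
    segment_index = "integer",
    waveform = "numeric",
    sample_rate = "integer",
    duration_s = "numeric"
  )
)

setValidity("AudioSegment", function(object) {
  msg <- character()
  want <- round(object@duration_s * object@sample_rate)
  if (length(object@waveform) != want)
    msg <- c(msg, sprintf("waveform must hold exactly %d samples (%g s at %d Hz), got %d",
                          want, object@duration_s, object@sample_rate,
                          length(object@waveform)))
  if (!all(is.finite(object@waveform)))
    msg <- c(msg, "waveform samples must all be finite")
  if (!(object@phase %in% .PHASES))
    msg <- c(msg, "phase must be 'pre' or 'post'")
  if (length(msg)) msg else TRUE
})

#' EncodedClip: a compressed, storable audio payload
#'
#' The byte-level form of an [AudioSegment-class] as written to the dataset
#' store: a mono payload produced by [transcodeClip()], decodable back to a
#' waveform with [decodeClip()].
#'
#' @slot payload raw vector of encoded bytes.
#' @slot codec `"pcm16"` (16-bit little-endian PCM) or `"mp3"`.
#' @slot bitrate_kbps declared bitrate (64 for mp3; informational for pcm16).
#' @slot channels always 1.
#' @slot sample_rate sampling rate of the encoded audio in Hz.
#' @slot subject_id,phase,segment_index provenance of the source segment.
#'
#' @exportClass EncodedClip
setClass("EncodedClip",
  representation(
    payload = "raw",
    codec = "character",
    bitrate_kbps = "numeric",
    channels = "integer",
    sample_rate = "integer",
    subject_id = "character",
    phase = "character",
    segment_index = "integer"
  )
)

setValidity("EncodedClip", function(object) {
  msg <- character()
  if (length(object@payload) < 1L)
    msg <- c(msg, "payload must be non-empty")
  if (!(object@codec %in% c("pcm16", "mp3")))
    msg <- c(msg, "codec must be 'pcm16' or 'mp3'")
  if (object@channels != 1L)
    msg <- c(msg, "clips are mono (channels == 1)")
  if (length(msg)) msg else TRUE
})

#' MelConfig: Mel-spectrogram front-end parameters
#'
#' The analysis front end is fixed at the pipeline's defaults: 128 mel bands,
#' 32 kHz sampling, 640-sample (20 ms) Hann window, 320-sample (10 ms) hop,
#' 640-point FFT, pre-emphasis coefficient 0.97, Slaney-style mel spacing
#' from 0 Hz to Nyquist, and logarithmic compression floored at `log_eps`.
#'
#' @slot n_mels number of mel bands.
#' @slot sample_rate expected waveform sampling rate, Hz.
#' @slot win_length analysis window length, samples.
#' @slot hop_length hop between frames, samples.
#' @slot n_fft FFT size, samples.
#' @slot preemphasis first-order pre-emphasis coefficient in \[0, 1).
#' @slot htk use HTK mel spacing instead of Slaney.
#' @slot log_eps floor applied before the log.
#'
#' @exportClass MelConfig
setClass("MelConfig",
  representation(
    n_mels = "integer",
    sample_rate = "integer",
    win_length = "integer",
    hop_length = "integer",
    n_fft = "integer",
    preemphasis = "numeric",
    htk = "logical",
    log_eps = "numeric"
  )
)

setValidity("MelConfig", function(object) {
  msg <- character()
  if (object@n_fft < object@win_length)
    msg <- c(msg, "n_fft must be >= win_length")
  if (object@hop_length > object@win_length)
    msg <- c(msg, "hop_length must be <= win_length")
  if (object@n_mels >= object@n_fft / 2 + 1)
    msg <- c(msg, "n_mels must be < n_fft/2 + 1")
  if (object@preemphasis < 0 || object@preemphasis >= 1)
    msg <- c(msg, "preemphasis must lie in [0, 1)")
  if (object@log_eps <= 0)
    msg <- c(msg, "log_eps must be positive")
  if (length(msg)) msg else TRUE
})

#' Construct a MelConfig
#'
#' @param n_mels number of mel bands (default 128).
#' @param sample_rate waveform sampling rate in Hz (default 32000).
#' @param win_length window length in samples (default 640, i.e. 20 ms).
#' @param hop_length hop size in samples (default 320, i.e. 10 ms).
#' @param n_fft FFT size (default 640).
#' @param preemphasis pre-emphasis coefficient (default 0.97).
#' @param htk use HTK mel spacing (default `FALSE`, Slaney spacing).
#' @param log_eps power floor before log compression (default 1e-10).
#' @return a [MelConfig-class] object.
#' @export
MelConfig <- function(n_mels = 128L, sample_rate = 32000L, win_length = 640L,
                      hop_length = 320L, n_fft = 640L, preemphasis = 0.97,
                      htk = FALSE, log_eps = 1e-10) {
  new("MelConfig", n_mels = as.integer(n_mels),
      sample_rate = as.integer(sample_rate),
      win_length = as.integer(win_length),
      hop_length = as.integer(hop_length), n_fft = as.integer(n_fft),
      preemphasis = preemphasis, htk = htk, log_eps = log_eps)
}

#' MelSpectrogram: log-power mel-frequency matrix
#'
#' The network's input representation: an `n_mels` x `n_frames` matrix of
#' log-compressed mel-filterbank power. Under centered framing
#' `n_frames == 1 + floor(n_samples / hop_length)`.
#'
#' @slot values numeric matrix (n_mels x n_frames), log-power units.
#' @slot config the [MelConfig-class] that produced it.
#' @slot source free-text provenance tag.
#'
#' @exportClass MelSpectrogram
setClass("MelSpectrogram",
  representation(values = "matrix", config = "MelConfig", source = "character")
)

setValidity("MelSpectrogram", function(object) {
  msg <- character()
  if (nrow(object@values) != object@config@n_mels)
    msg <- c(msg, "row count must equal config n_mels")
  if (!all(is.finite(object@values)))
    msg <- c(msg, "all spectrogram entries must be finite")
  if (length(msg)) msg else TRUE
})

#' FoldPlan: subject-grouped cross-validation partition
#'
#' Maps every anonymized subject identifier to exactly one of `k` folds, so
#' that no individual's samples ever span a train/test boundary.
#'
#' @slot k number of folds.
#' @slot assignment named integer vector, subject_id -> fold index in
#'   `0:(k-1)`.
#' @slot seed RNG seed the plan was drawn with.
#'
#' @exportClass FoldPlan
setClass("FoldPlan",
  representation(k = "integer", assignment = "integer", seed = "integer")
)

setValidity("FoldPlan", function(object) {
  msg <- character()
  if (object@k < 2L) msg <- c(msg, "k must be >= 2")
  if (is.null(names(object@assignment)) ||
      anyDuplicated(names(object@assignment)))
    msg <- c(msg, "assignment must be named with unique subject ids")
  if (length(object@assignment) &&
      (min(object@assignment) < 0L || max(object@assignment) >= object@k))
    msg <- c(msg, "fold indices must lie in 0:(k-1)")
  if (length(msg)) msg else TRUE
})

setMethod("show", "RawRecording", function(object) {
  cat(sprintf("RawRecording %s [%s] %d ch, %d samples @ %d Hz (%.2f s)\n",
              object@subject_id, object@phase, ncol(object@waveform),
              nrow(object@waveform), object@sample_rate,
              nrow(object@waveform) / object@sample_rate))
  meta <- c(group = object@group_label, sex = object@sex,
            substance = object@substance, device = object@device)
  meta <- meta[!is.na(meta)]
  if (length(meta))
    cat("  ", paste(names(meta), meta, sep = "=", collapse = " "), "\n")
})

setMethod("show", "AudioSegment", function(object) {
  cat(sprintf("AudioSegment %s [%s] #%d: %g s @ %d Hz\n", object@subject_id,
              object@phase, object@segment_index, object@duration_s,
              object@sample_rate))
})

setMethod("show", "EncodedClip", function(object) {
  cat(sprintf("EncodedClip %s [%s] #%d: %d bytes, %s @ %d Hz\n",
              object@subject_id, object@phase, object@segment_index,
              length(object@payload), object@codec, object@sample_rate))
})

setMethod("show", "MelSpectrogram", function(object) {
  cat(sprintf("MelSpectrogram %d x %d (mels x frames), range [%.2f, %.2f]\n",
              nrow(object@values), ncol(object@values), min(object@values),
              max(object@values)))
})

setMethod("show", "FoldPlan", function(object) {
  cat(sprintf("FoldPlan: %d subjects in %d folds (seed %d)\n",
              length(object@assignment), object@k, object@seed))
  print(table(fold = object@assignment))
})
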