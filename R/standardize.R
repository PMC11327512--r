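#' Trim lead-in and tail from a recording
#'
#' Endpoint denoising: removes a caller-specified interval from the head and
#' tail of a recording (where prompts, equipment noise or silence sit) and
#' keeps the central slice. Metadata is preserved.
#'
#' @param rec a [RawRecording-class].
#' @param lead_s seconds to drop from the start.
#' @param trail_s seconds to drop from the end.
#' @return the trimmed [RawRecording-class].
#' @export
trimEndpoints <- function(rec, lead_s = 0, trail_s = 0) {
  stopifnot(is(rec, "RawRecording"), lead_s >= 0, trail_s >= 0)
  n <- nrow(rec@waveform)
  from <- floor(lead_s * rec@sample_rate) + 1L
  to <- n - floor(trail_s * rec@sample_rate)
  if (from > to)
    stop("trim boundaries leave an empty slice (", lead_s, " + ", trail_s,
         " s from a ", round(n / rec@sample_rate, 3), " s recording)")
  initialize(rec, waveform = rec@waveform[from:to, , drop = FALSE])
}

#' Energy-based automatic endpoint trimmer
#'
#' Cuts head and tail frames whose RMS falls below a fraction of the
#' recording's peak frame RMS; an automated stand-in for manual endpoint
#' denoising.
#'
#' @param rec a [RawRecording-class].
#' @param threshold_frac RMS fraction of the peak frame below which head/tail
#'   frames are cut (default 0.01).
#' @param frame_s analysis frame length in seconds (default 0.02).
#' @return the trimmed [RawRecording-class] (unchanged when nothing falls
#'   below threshold).
#' @export
autoTrimEndpoints <- function(rec, threshold_frac = 0.01, frame_s = 0.02) {
  stopifnot(is(rec, "RawRecording"))
  x <- rowMeans(rec@waveform)          # energy gate on the channel mean
  flen <- max(1L, floor(frame_s * rec@sample_rate))
  nf <- length(x) %/% flen
  if (nf < 2L) return(rec)
  frames <- matrix(x[seq_len(nf * flen)], nrow = flen)
  rms <- sqrt(colMeans(frames^2))
  keep <- rms >= threshold_frac * max(rms)
  if (!any(keep)) return(rec)
  first <- which(keep)[1L]
  last <- max(which(keep))
  from <- (first - 1L) * flen + 1L
  to <- min(length(x), last * flen)
  initialize(rec, waveform = rec@waveform[from:to, , drop = FALSE])
}

#' Split a stereo recording into two mono recordings
#'
#' Stereo captures are split into left and right channels, each
#' inheriting the parent metadata plus a channel tag on the device field.
#'
#' @param rec a stereo [RawRecording-class].
#' @return list of two mono [RawRecording-class] objects (left, right).
#' @export
splitStereo <- function(rec) {
  stopifnot(is(rec, "RawRecording"))
  if (ncol(rec@waveform) != 2L)
    stop("splitStereo expects a stereo recording; mono input should be ",
         "passed through unchanged")
  tag <- function(side) {
    dev <- if (is.na(rec@device)) side else paste0(rec@device, ":", side)
    initialize(rec,
               waveform = rec@waveform[, if (side == "L") 1L else 2L,
                                       drop = FALSE],
               device = dev)
  }
  list(left = tag("L"), right = tag("R"))
}

#' Band-limited resampling
#'
#' Rate conversion by polyphase band-limited interpolation
#' (via \pkg{signal}); output length is exactly
#' `round(length(wave) * to_rate / from_rate)`. Identical rates return the
#' input unchanged.
#'
#' @param wave mono numeric vector.
#' @param from_rate,to_rate source and target rates in Hz.
#' @return resampled numeric vector.
#' @export
resampleWave <- function(wave, from_rate, to_rate) {
  if (from_rate <= 0 || to_rate <= 0) stop("rates must be positive")
  if (from_rate == to_rate) return(wave)
  g <- .gcd(as.integer(to_rate), as.integer(from_rate))
  y <- signal::resample(wave, as.integer(to_rate) %/% g,
                        as.integer(from_rate) %/% g)
  n_out <- round(length(wave) * (as.numeric(to_rate) / from_rate))
  if (length(y) >= n_out) y[seq_len(n_out)] else c(y, rep(0, n_out - length(y)))
}

.gcd <- function(a, b) if (b == 0L) a else .gcd(b, a %% b)

#' Cut a mono recording into fixed-length segments
#'
#' Consecutive non-overlapping windows of `seg_len_s` seconds starting at
#' sample 1; a trailing remainder shorter than `seg_len_s` is discarded.
#' Recordings shorter than one window yield an empty list with a warning.
#'
#' @param rec a mono [RawRecording-class].
#' @param seg_len_s segment length in seconds (default 2).
#' @return list of [AudioSegment-class] objects (possibly empty).
#' @export
segmentFixed <- function(rec, seg_len_s = 2) {
  stopifnot(is(rec, "RawRecording"))
  if (ncol(rec@waveform) != 1L)
    stop("segmentFixed expects a mono recording; split stereo first")
  x <- drop(rec@waveform)
  win <- round(seg_len_s * rec@sample_rate)
  nseg <- length(x) %/% win
  if (nseg == 0L) {
    warning(sprintf("recording %s [%s] is shorter than %g s; no segments",
                    rec@subject_id, rec@phase, seg_len_s))
    return(list())
  }
  lapply(seq_len(nseg), function(i) {
    new("AudioSegment", subject_id = rec@subject_id, phase = rec@phase,
        segment_index = i, waveform = x[((i - 1L) * win + 1L):(i * win)],
        sample_rate = rec@sample_rate, duration_s = seg_len_s)
  })
}

#' Encode a segment to a storable mono clip
#'
#' Encodes an [AudioSegment-class] to the byte payload written into the
#' dataset store. Codec `"pcm16"` (default) serializes 16-bit little-endian
#' PCM at the capture bit depth; codec `"mp3"` produces a constant 64-kbps
#' mono mp3 through an external encoder (ffmpeg or lame) and raises an
#' explicit environment error when no encoder is installed.
#'
#' @param seg an [AudioSegment-class].
#' @param codec `"pcm16"` or `"mp3"`.
#' @param bitrate_kbps declared bitrate (used by the mp3 encoder; recorded as
#'   metadata for pcm16).
#' @return an [EncodedClip-class].
#' @export
transcodeClip <- function(seg, codec = c("pcm16", "mp3"), bitrate_kbps = 64) {
  stopifnot(is(seg, "AudioSegment"))
  codec <- match.arg(codec)
  if (codec == "pcm16") {
    ints <- as.integer(pmax(-32768, pmin(32767, round(seg@waveform * 32767))))
    pay <- writeBin(ints, raw(), size = 2, endian = "little")
  } else {
    conv <- audioConverter()
    if (!nzchar(conv))
      stop("mp3 encoding requires an external encoder (ffmpeg or lame) on ",
           "the PATH; none was found in this environment")
    wav <- tempfile(fileext = ".wav"); mp3 <- tempfile(fileext = ".mp3")
    on.exit(unlink(c(wav, mp3)))
    writeWavePCM(seg@waveform, seg@sample_rate, wav)
    args <- if (grepl("ffmpeg", basename(conv)))
      c("-y", "-loglevel", "error", "-i", shQuote(wav), "-ac", "1", "-b:a",
        paste0(bitrate_kbps, "k"), shQuote(mp3))
    else c("-b", bitrate_kbps, "-m", "m", shQuote(wav), shQuote(mp3))
    if (system2(conv, args) != 0L) stop("mp3 encoder failed")
    pay <- readBin(mp3, "raw", file.info(mp3)$size)
  }
  new("EncodedClip", payload = pay, codec = codec,
      bitrate_kbps = bitrate_kbps, channels = 1L,
      sample_rate = seg@sample_rate, subject_id = seg@subject_id,
      phase = seg@phase, segment_index = seg@segment_index)
}

#' Decode a clip back to a waveform
#'
#' @param clip an [EncodedClip-class].
#' @param target_rate optional rate to resample the decoded waveform to.
#' @return mono numeric waveform.
#' @export
decodeClip <- function(clip, target_rate = NULL) {
  stopifnot(is(clip, "EncodedClip"))
  if (clip@codec == "pcm16") {
    if (length(clip@payload) %% 2L != 0L)
      stop("corrupt pcm16 payload (odd byte count)")
    wave <- readBin(clip@payload, "integer", length(clip@payload) %/% 2L,
                    size = 2, endian = "little") / 32768
  } else {
    conv <- audioConverter()
    if (!nzchar(conv) || !grepl("ffmpeg", basename(conv)))
      stop("mp3 decoding requires ffmpeg on the PATH; none was found")
    mp3 <- tempfile(fileext = ".mp3"); wav <- tempfile(fileext = ".wav")
    on.exit(unlink(c(mp3, wav)))
    writeBin(clip@payload, mp3)
    if (system2(conv, c("-y", "-loglevel", "error", "-i", shQuote(mp3),
                        shQuote(wav))) != 0L)
      stop("mp3 decode error (corrupt payload?)")
    wave <- drop(readWavePCM(wav)$waveform)
    # trim codec delay/padding back to the nominal clip duration
  }
  if (!is.null(target_rate) && target_rate != clip@sample_rate)
    wave <- resampleWave(wave, clip@sample_rate, target_rate)
  wave
}

#' Standardize a cohort manifest into encoded 2-s segments
#'
#' Runs the standardization stages over every manifest row: endpoint
#' trimming, stereo split, resampling to the analysis rate, fixed 2-s
#' segmentation, and clip encoding. Stereo recordings contribute their left
#' channel by default (`stereo = "both"` keeps both as separate mono takes).
#'
#' @param manifest data.frame from [readManifest()], or a path to the CSV.
#' @param target_rate analysis sampling rate in Hz (default 32000).
#' @param seg_len_s segment length in seconds (default 2).
#' @param lead_s,trail_s fixed endpoint trims in seconds (default 0).
#' @param auto_trim apply [autoTrimEndpoints()] before segmenting.
#' @param codec clip codec passed to [transcodeClip()].
#' @param stereo `"left"`, `"right"`, or `"both"`.
#' @return a segment table: data.frame with columns `subject_id`, `phase`,
#'   `group_label`, `sex`, `substance`, `segment_index` and a `clip` list
#'   column of [EncodedClip-class] objects.
#' @export
standardizeManifest <- function(manifest, target_rate = 32000L, seg_len_s = 2,
                                lead_s = 0, trail_s = 0, auto_trim = FALSE,
                                codec = "pcm16",
                                stereo = c("left", "right", "both")) {
  stereo <- match.arg(stereo)
  if (is.character(manifest)) manifest <- readManifest(manifest)
  rows <- list()
  for (i in seq_len(nrow(manifest))) {
    m <- manifest[i, ]
    rec <- readRecording(m$path, m$subject_id, m$phase, m$group_label,
                         m$sex, m$substance, m$device)
    if (lead_s > 0 || trail_s > 0) rec <- trimEndpoints(rec, lead_s, trail_s)
    if (auto_trim) rec <- autoTrimEndpoints(rec)
    takes <- if (ncol(rec@waveform) == 2L) {
      lr <- splitStereo(rec)
      switch(stereo, left = lr["left"], right = lr["right"], both = lr)
    } else list(rec)
    for (take in takes) {
      wave <- resampleWave(drop(take@waveform), take@sample_rate, target_rate)
      mono <- initialize(take, waveform = matrix(wave, ncol = 1L),
                         sample_rate = as.integer(target_rate))
      for (seg in segmentFixed(mono, seg_len_s)) {
        rows[[length(rows) + 1L]] <- data.frame(
          subject_id = m$subject_id, phase = m$phase,
          group_label = m$group_label, sex = m$sex,
          substance = if (is.null(m$substance)) NA_character_ else m$substance,
          segment_index = seg@segment_index, stringsAsFactors = FALSE)
        attr(rows[[length(rows)]], "clip") <- transcodeClip(seg, codec)
      }
    }
  }
  if (!length(rows)) stop("manifest produced no segments")
  out <- do.call(rbind, rows)
  out$clip <- I(lapply(rows, attr, "clip"))
  rownames(out) <- NULL
  out
}
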