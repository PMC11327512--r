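#' Read a 16-bit PCM WAV file
#'
#' Minimal RIFF/WAVE reader for the capture format used throughout the
#' pipeline (16-bit integer PCM, mono or stereo). Samples are returned
#' rescaled to \[-1, 1\].
#'
#' @param path path to a .wav file.
#' @return list with `waveform` (samples x channels matrix), `sample_rate`,
#'   and `channels`.
#' @export
readWavePCM <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path)
  invisible(readBin(con, "integer", 1, size = 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path)
  fmt <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0L || !nzchar(id)) stop("no data chunk found in ", path)
    sz <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      raw_fmt <- readBin(con, "raw", sz)
      fmt <- list(
        audio_format = readBin(raw_fmt[1:2], "integer", 1, size = 2,
                               endian = "little", signed = FALSE),
        channels = readBin(raw_fmt[3:4], "integer", 1, size = 2,
                           endian = "little", signed = FALSE),
        sample_rate = readBin(raw_fmt[5:8], "integer", 1, size = 4,
                              endian = "little"),
        bits = readBin(raw_fmt[15:16], "integer", 1, size = 2,
                       endian = "little", signed = FALSE))
    } else if (identical(id, "data")) {
      if (is.null(fmt)) stop("data chunk precedes fmt chunk in ", path)
      if (fmt$audio_format != 1L || fmt$bits != 16L)
        stop("only 16-bit integer PCM is supported, got format ",
             fmt$audio_format, " / ", fmt$bits, " bits")
      n <- sz %/% 2L
      samples <- readBin(con, "integer", n, size = 2, endian = "little")
      mat <- matrix(samples / 32768, ncol = fmt$channels, byrow = TRUE)
      return(list(waveform = mat, sample_rate = fmt$sample_rate,
                  channels = fmt$channels))
    } else {
      invisible(readBin(con, "raw", sz + (sz %% 2L)))
    }
  }
}

#' Write a 16-bit PCM WAV file
#'
#' @param waveform numeric vector (mono) or samples x channels matrix of
#'   values in \[-1, 1\]; values outside are clipped.
#' @param sample_rate sampling rate in Hz.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeWavePCM <- function(waveform, sample_rate, path) {
  if (is.null(dim(waveform))) waveform <- matrix(waveform, ncol = 1L)
  ch <- ncol(waveform)
  x <- as.integer(pmax(-32768, pmin(32767, round(t(waveform) * 32767))))
  data_size <- length(x) * 2L
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_size), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")            # PCM
  writeBin(as.integer(ch), con, size = 2, endian = "little")
  writeBin(as.integer(sample_rate), con, size = 4, endian = "little")
  writeBin(as.integer(sample_rate * ch * 2L), con, size = 4,
           endian = "little")                               # byte rate
  writeBin(as.integer(ch * 2L), con, size = 2, endian = "little")
  writeBin(16L, con, size = 2, endian = "little")           # bits
  writeChar("data", con, eos = NULL)
  writeBin(data_size, con, size = 4, endian = "little")
  writeBin(x, con, size = 2, endian = "little")
  invisible(path)
}

#' Locate an external audio converter
#'
#' mp3 and m4a support delegates to an external encoder/decoder. Returns the
#' first of `ffmpeg`, `lame` found on the PATH, or `""` when none exists.
#'
#' @return path to the converter binary, or `""`.
#' @export
audioConverter <- function() {
  for (bin in c("ffmpeg", "lame")) {
    hit <- Sys.which(bin)
    if (nzchar(hit)) return(unname(hit))
  }
  ""
}

#' Read a recording with its study metadata
#'
#' Reads one audio file (wav natively; mp3/m4a through an external converter
#' when one is installed) and wraps it as a [RawRecording-class].
#'
#' @param path audio file path.
#' @param subject_id,phase,group_label,sex,substance,device study metadata;
#'   see [RawRecording()].
#' @return a [RawRecording-class].
#' @export
readRecording <- function(path, subject_id, phase,
                          group_label = NA_character_, sex = NA_character_,
                          substance = NA_character_, device = NA_character_) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "wav") {
    w <- readWavePCM(path)
  } else if (ext %in% c("mp3", "m4a")) {
    conv <- audioConverter()
    if (!nzchar(conv) || !grepl("ffmpeg", conv))
      stop("reading .", ext, " requires an external converter (ffmpeg) ",
           "on the PATH; none was found")
    tmp <- tempfile(fileext = ".wav")
    on.exit(unlink(tmp))
    status <- system2(conv, c("-y", "-loglevel", "error", "-i",
                              shQuote(path), shQuote(tmp)))
    if (status != 0L) stop("converter failed on ", path)
    w <- readWavePCM(tmp)
  } else {
    stop("unsupported audio format: .", ext)
  }
  RawRecording(w$waveform, w$sample_rate, subject_id, phase, group_label,
               sex, substance, device)
}

#' Read a cohort manifest
#'
#' The manifest is a CSV with columns `subject_id`, `phase`, `group_label`,
#' `sex`, `substance`, `device`, `path` (paths relative to the manifest's
#' directory are resolved against it).
#'
#' @param manifest_csv path to the manifest file.
#' @return data.frame with the manifest columns and absolute paths.
#' @export
readManifest <- function(manifest_csv) {
  m <- read.csv(manifest_csv, stringsAsFactors = FALSE)
  required <- c("subject_id", "phase", "group_label", "sex", "path")
  missing <- setdiff(required, names(m))
  if (length(missing))
    stop("manifest lacks required columns: ", paste(missing, collapse = ", "))
  if (is.null(m$substance)) m$substance <- NA_character_
  if (is.null(m$device)) m$device <- NA_character_
  rel <- !file.exists(m$path)
  m$path[rel] <- file.path(dirname(normalizePath(manifest_csv)), m$path[rel])
  m
}
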