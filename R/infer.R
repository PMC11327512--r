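#' Infer aspiration risk for one pre/post recording pair
#'
#' End-to-end inference: decodes both audio files, mixes to mono,
#' resamples to the front-end rate, segments into 2-s windows, computes
#' standardized Mel spectrograms, runs the detector and reports the top
#' label with both class probabilities. By default only the first 2-s
#' segment of each file is used; `aggregate = "mean"` averages the
#' aspiration probability over all pre x post segment combinations.
#'
#' @param pre_path,post_path audio files (wav; mp3/m4a via an external
#'   converter) of the pre- and post-swallow vowels.
#' @param checkpoint a checkpoint path from [saveCheckpoint()], or a
#'   detector object (then `mel_config` must be supplied).
#' @param aggregate `"first"` or `"mean"`.
#' @param mel_config front-end configuration; defaults to the one stored
#'   in the checkpoint.
#' @return list with `label`, `prob_aspiration`, `prob_normal`, and the
#'   per-segment probabilities.
#' @export
inferPair <- function(pre_path, post_path, checkpoint,
                      aggregate = c("first", "mean"), mel_config = NULL) {
  aggregate <- match.arg(aggregate)
  det <- if (is.character(checkpoint)) loadCheckpoint(checkpoint)
         else checkpoint
  stopifnot(inherits(det, "Detector"))
  if (is.null(mel_config)) mel_config <- attr(det, "mel_config")
  if (is.null(mel_config))
    stop("no mel_config available: pass one or use a checkpoint file")
  segs <- function(path, ph) {
    rec <- readRecording(path, subject_id = "query", phase = ph)
    x <- rec@waveform
    if (ncol(x) == 2L) x <- rowMeans(x)
    wave <- resampleWave(drop(x), rec@sample_rate, mel_config@sample_rate)
    mono <- RawRecording(wave, mel_config@sample_rate, "query", ph)
    if (duration(mono) < 2)
      stop(basename(path), " is shorter than the 2 s minimum (",
           round(duration(mono), 2), " s)")
    ss <- suppressWarnings(segmentFixed(mono, 2))
    lapply(ss, function(s) melStandardize(melSpectrogram(s@waveform,
                                                         mel_config)))
  }
  pre <- segs(pre_path, "pre")
  post <- segs(post_path, "post")
  if (aggregate == "first") { pre <- pre[1]; post <- post[1] }
  combos <- expand.grid(i = seq_along(pre), j = seq_along(post))
  probs <- vapply(seq_len(nrow(combos)), function(r) {
    logit <- forwardDetector(det,
                             stackSpectrograms(pre[combos$i[r]]),
                             stackSpectrograms(post[combos$j[r]]))
    predictProba(logit)
  }, numeric(1))
  p <- mean(probs)
  list(label = classifyProb(p), prob_aspiration = p, prob_normal = 1 - p,
       segment_probs = probs)
}
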