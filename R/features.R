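#' First-order pre-emphasis filter
#'
#' High-pass spectral tilt applied before spectral analysis:
#' `y[1] = x[1]`, `y[t] = x[t] - alpha * x[t-1]` for `t > 1`.
#'
#' @param wave mono numeric vector.
#' @param alpha coefficient in \[0, 1) (default 0.97).
#' @return filtered vector, same length.
#' @export
preemphasize <- function(wave, alpha = 0.97) {
  stopifnot(alpha >= 0, alpha < 1)
  if (alpha == 0 || length(wave) < 2L) return(wave)
  c(wave[1L], wave[-1L] - alpha * wave[-length(wave)])
}

.hz_to_mel <- function(hz, htk = FALSE) {
  if (htk) return(2595 * log10(1 + hz / 700))
  # Slaney: linear below 1 kHz (200/3 Hz per mel), log above
  f_sp <- 200 / 3
  min_log_hz <- 1000
  min_log_mel <- min_log_hz / f_sp
  logstep <- log(6.4) / 27
  ifelse(hz < min_log_hz, hz / f_sp, min_log_mel + log(hz / min_log_hz) / logstep)
}

.mel_to_hz <- function(mel, htk = FALSE) {
  if (htk) return(700 * (10^(mel / 2595) - 1))
  f_sp <- 200 / 3
  min_log_hz <- 1000
  min_log_mel <- min_log_hz / f_sp
  logstep <- log(6.4) / 27
  ifelse(mel < min_log_mel, mel * f_sp, min_log_hz * exp(logstep * (mel - min_log_mel)))
}

#' Mel filterbank matrix
#'
#' Triangular filters on `n_mels` mel-spaced bands between 0 Hz and
#' Nyquist, with Slaney area normalization (each filter scaled by
#' 2 / bandwidth). All weights are non-negative and every FFT bin between
#' the first and last band edge receives nonzero total weight.
#'
#' @param config a [MelConfig-class].
#' @return matrix (n_mels x (n_fft/2 + 1)).
#' @export
melFilterbank <- function(config = MelConfig()) {
  stopifnot(is(config, "MelConfig"))
  key <- paste(config@n_mels, config@sample_rate, config@n_fft, config@htk)
  hit <- .fb_cache[[key]]
  if (!is.null(hit)) return(hit)
  n_bins <- config@n_fft %/% 2L + 1L
  fft_hz <- seq(0, config@sample_rate / 2, length.out = n_bins)
  edges_mel <- seq(.hz_to_mel(0, config@htk),
                   .hz_to_mel(config@sample_rate / 2, config@htk),
                   length.out = config@n_mels + 2L)
  edges_hz <- .mel_to_hz(edges_mel, config@htk)
  fb <- matrix(0, config@n_mels, n_bins)
  for (m in seq_len(config@n_mels)) {
    lo <- edges_hz[m]; ctr <- edges_hz[m + 1L]; hi <- edges_hz[m + 2L]
    up <- (fft_hz - lo) / (ctr - lo)
    down <- (hi - fft_hz) / (hi - ctr)
    fb[m, ] <- pmax(0, pmin(up, down)) * 2 / (hi - lo)
  }
  .fb_cache[[key]] <- fb
  fb
}

.fb_cache <- new.env(parent = emptyenv())

#' Center frequencies of the mel filterbank
#'
#' @param config a [MelConfig-class].
#' @return numeric vector of n_mels center frequencies in Hz.
#' @export
melCenterFrequencies <- function(config = MelConfig()) {
  edges_mel <- seq(.hz_to_mel(0, config@htk),
                   .hz_to_mel(config@sample_rate / 2, config@htk),
                   length.out = config@n_mels + 2L)
  .mel_to_hz(edges_mel, config@htk)[2:(config@n_mels + 1L)]
}

#' Log-power Mel spectrogram
#'
#' The analysis front end: pre-emphasis, centered short-time Fourier
#' transform (periodic Hann window, reflect padding), power magnitude,
#' mel filterbank, and log compression floored at `log_eps`. A waveform of
#' `n` samples yields `1 + floor(n / hop_length)` frames.
#'
#' @param wave mono numeric vector sampled at `config@sample_rate`, or an
#'   [AudioSegment-class].
#' @param config a [MelConfig-class].
#' @param source provenance tag stored on the result.
#' @return a [MelSpectrogram-class] of shape (n_mels, n_frames).
#' @export
melSpectrogram <- function(wave, config = MelConfig(), source = "") {
  if (is(wave, "AudioSegment")) {
    if (wave@sample_rate != config@sample_rate)
      stop("segment rate ", wave@sample_rate, " != config rate ",
           config@sample_rate, "; resample first")
    source <- sprintf("%s/%s#%d", wave@subject_id, wave@phase,
                      wave@segment_index)
    wave <- wave@waveform
  }
  if (!length(wave)) stop("empty waveform")
  if (!all(is.finite(wave))) stop("waveform contains non-finite samples")
  new("MelSpectrogram", values = .mel_matrix(wave, config), config = config,
      source = source)
}

# matrix-only mel path (no S4 construction); the training loop's hot path
.mel_matrix <- function(wave, config) {
  win <- .hann_periodic(config@win_length)
  if (config@win_length < config@n_fft)  # center-pad window to n_fft
    win <- c(rep(0, (config@n_fft - config@win_length) %/% 2L), win,
             rep(0, config@n_fft - config@win_length -
                   (config@n_fft - config@win_length) %/% 2L))
  S <- stft_power(wave, config@n_fft, config@hop_length, win,
                  config@preemphasis)
  log(pmax(melFilterbank(config) %*% S, config@log_eps))
}

.hann_periodic <- function(n) 0.5 * (1 - cos(2 * pi * (0:(n - 1L)) / n))

#' Cosine similarity between two Mel spectrograms
#'
#' The device-bias audit statistic: the cosine of the angle between the two
#' flattened matrices. Spectrograms with different frame counts are cropped
#' to the shorter one.
#'
#' @param a,b [MelSpectrogram-class] objects or plain matrices.
#' @return similarity score in \[-1, 1\].
#' @export
melCosineSimilarity <- function(a, b) {
  va <- if (is(a, "MelSpectrogram")) a@values else a
  vb <- if (is(b, "MelSpectrogram")) b@values else b
  if (nrow(va) != nrow(vb)) stop("mel band counts differ")
  nf <- min(ncol(va), ncol(vb))
  va <- as.vector(va[, seq_len(nf)]); vb <- as.vector(vb[, seq_len(nf)])
  na <- sqrt(sum(va^2)); nb <- sqrt(sum(vb^2))
  if (na == 0 || nb == 0) stop("zero-norm spectrogram")
  sum(va * vb) / (na * nb)
}

#' Standardize a spectrogram for the network
#'
#' Per-spectrogram z-normalization of the log-power values (zero mean, unit
#' variance) so the network input scale is device- and level-independent.
#'
#' @param spec a [MelSpectrogram-class] or matrix.
#' @return plain numeric matrix.
#' @export
melStandardize <- function(spec) {
  v <- if (is(spec, "MelSpectrogram")) spec@values else spec
  s <- sd(v)
  if (s == 0) return(v - mean(v))
  (v - mean(v)) / s
}
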