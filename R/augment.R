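#' Augmentation configuration
#'
#' Parameter ranges for the seven waveform augmentations and their random
#' 2-of-7 composition. Defaults are audible but label-preserving: noise
#' sigma in \[0.0005, 0.005\], SNR targets 20-40 dB, gain -12..+12 dB,
#' tanh drive 1-4, time-mask fraction 0.02-0.2, stretch rate 0.8-1.25.
#' The two additive-noise ranges sit above typical phonation noise
#' floors on purpose: when the class signal lives in breathiness (the
#' harmonics-to-noise ratio), injected noise stronger than that floor
#' would overwrite the label rather than augment the sample.
#'
#' @param noise_sigma length-2 range for Gaussian noise sigma.
#' @param snr_db length-2 range for the noise-at-SNR target, dB.
#' @param gain_db length-2 range for gain, dB.
#' @param tanh_drive length-2 range for the distortion drive.
#' @param time_mask_fraction length-2 range of masked fraction, upper bound
#'   at most 0.5.
#' @param stretch_rate length-2 range of playback-rate factors.
#' @return list of class `AugmentConfig`.
#' @export
augmentConfig <- function(noise_sigma = c(0.0005, 0.005),
                          snr_db = c(20, 40),
                          gain_db = c(-12, 12),
                          tanh_drive = c(1, 4),
                          time_mask_fraction = c(0.02, 0.2),
                          stretch_rate = c(0.8, 1.25)) {
  rng_ok <- function(r) length(r) == 2L && all(is.finite(r)) && r[1] <= r[2]
  stopifnot(rng_ok(noise_sigma), rng_ok(snr_db), rng_ok(gain_db),
            rng_ok(tanh_drive), rng_ok(time_mask_fraction),
            rng_ok(stretch_rate),
            time_mask_fraction[1] > 0, time_mask_fraction[2] <= 0.5)
  structure(list(noise_sigma = noise_sigma, snr_db = snr_db,
                 gain_db = gain_db, tanh_drive = tanh_drive,
                 time_mask_fraction = time_mask_fraction,
                 stretch_rate = stretch_rate),
            class = "AugmentConfig")
}

#' Waveform augmentations
#'
#' The seven training-time audio transforms. All preserve length exactly;
#' none is ever applied to test-split samples.
#'
#' * `addGaussianNoise()` adds i.i.d. `N(0, sigma^2)` noise.
#' * `addNoiseAtSNR()` adds Gaussian noise scaled so the signal-to-noise
#'   ratio equals `snr_db`.
#' * `adjustGain()` scales by `10^(gain_db/20)`.
#' * `invertPolarity()` negates the signal.
#' * `tanhDistort()` applies `tanh(drive*x)/tanh(drive)` soft clipping.
#' * `timeMask()` zeroes one contiguous interval of the given fraction.
#' * `timeStretch()` changes playback rate by linear-interpolation
#'   resampling, then center-crops or zero-pads back to the original
#'   length.
#'
#' @param wave mono numeric vector.
#' @param sigma noise standard deviation.
#' @param snr_db target signal-to-noise ratio, dB.
#' @param gain_db gain in dB.
#' @param drive distortion drive (> 0).
#' @param fraction fraction of samples masked, in (0, 0.5\].
#' @param rate playback-rate factor (> 1 compresses, < 1 stretches).
#' @return transformed waveform, same length as the input.
#' @name augmentations
NULL

#' @rdname augmentations
#' @export
addGaussianNoise <- function(wave, sigma) wave + rnorm(length(wave), 0, sigma)

#' @rdname augmentations
#' @export
addNoiseAtSNR <- function(wave, snr_db) {
  p_sig <- mean(wave^2)
  if (p_sig == 0) return(wave)
  p_noise <- p_sig / 10^(snr_db / 10)
  wave + rnorm(length(wave), 0, sqrt(p_noise))
}

#' @rdname augmentations
#' @export
adjustGain <- function(wave, gain_db) wave * 10^(gain_db / 20)

#' @rdname augmentations
#' @export
invertPolarity <- function(wave) -wave

#' @rdname augmentations
#' @export
tanhDistort <- function(wave, drive) {
  stopifnot(drive > 0)
  tanh(drive * wave) / tanh(drive)
}

#' @rdname augmentations
#' @export
timeMask <- function(wave, fraction) {
  stopifnot(fraction > 0, fraction <= 0.5)
  n <- length(wave)
  mlen <- max(1L, floor(fraction * n))
  start <- sample.int(n - mlen + 1L, 1L)
  wave[start:(start + mlen - 1L)] <- 0
  wave
}

#' @rdname augmentations
#' @export
timeStretch <- function(wave, rate) {
  stopifnot(rate > 0)
  n <- length(wave)
  # linear-interpolation playback-rate change: adequate fidelity for an
  # augmentation transform and orders of magnitude cheaper than a
  # polyphase redesign per random draw
  pos <- seq(1, n, by = rate)
  i0 <- pmin(floor(pos), n - 1L)
  frac <- pos - i0
  y <- wave[i0] * (1 - frac) + wave[i0 + 1L] * frac
  if (length(y) >= n) {
    off <- (length(y) - n) %/% 2L
    y[(off + 1L):(off + n)]
  } else {
    pad <- n - length(y)
    c(rep(0, pad %/% 2L), y, rep(0, pad - pad %/% 2L))
  }
}

#' Random two-of-seven augmentation composition
#'
#' Draws exactly two distinct transforms uniformly without replacement from
#' the seven augmentations, draws each parameter uniformly from its
#' configured range, and applies them in draw order. Uses the current R RNG
#' state, so a seeded caller gets reproducible draws.
#'
#' @param wave mono numeric vector.
#' @param cfg an [augmentConfig()].
#' @return augmented waveform, same length as the input, with the indices
#'   of the two applied transforms (in draw order) attached as attribute
#'   `"picks"`.
#' @export
composeRandomTwo <- function(wave, cfg = augmentConfig()) {
  stopifnot(inherits(cfg, "AugmentConfig"))
  runi <- function(r) runif(1L, r[1], r[2])
  picks <- sample.int(7L, 2L)
  for (k in picks) {
    wave <- switch(k,
      addGaussianNoise(wave, runi(cfg$noise_sigma)),
      addNoiseAtSNR(wave, runi(cfg$snr_db)),
      adjustGain(wave, runi(cfg$gain_db)),
      invertPolarity(wave),
      tanhDistort(wave, runi(cfg$tanh_drive)),
      timeMask(wave, runi(cfg$time_mask_fraction)),
      timeStretch(wave, runi(cfg$stretch_rate)))
  }
  attr(wave, "picks") <- picks
  wave
}
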