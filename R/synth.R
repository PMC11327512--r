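#' Synthetic cohort configuration
#'
#' Parameters of the source-filter vowel generator used to build labeled
#' pre/post cohorts without clinical audio. Defaults describe a healthy
#' sustained /a/: fundamental frequency 100-140 Hz (male) or 180-230 Hz
#' (female), cycle-length jitter 0.5%, amplitude shimmer 3%,
#' harmonics-to-noise ratio 25 dB, and formants near 800/1200/2500 Hz.
#' `post_delta` is the acoustic divergence added to aspiration-group
#' post-swallow recordings only: by default +2 percentage points of
#' jitter, +6 of shimmer, and -10 dB of HNR — a strong, clearly learnable
#' change; set all three to zero for a null (label-uninformative) cohort.
#'
#' @param n_per_cell subjects per (group x sex) cell.
#' @param duration_s recording length in seconds (>= 2 so segmentation
#'   yields at least one segment).
#' @param sample_rate capture sampling rate in Hz.
#' @param f0_male,f0_female fundamental-frequency ranges in Hz.
#' @param jitter_pct cycle-length perturbation, percent of the period.
#' @param shimmer_pct amplitude perturbation, percent.
#' @param hnr_db harmonics-to-noise ratio target, dB.
#' @param formants,formant_bw formant center frequencies and bandwidths,
#'   Hz.
#' @param post_delta list with `jitter`, `shimmer` (added percentage
#'   points, >= 0) and `hnr` (added dB, <= 0).
#' @param seed RNG seed.
#' @return list of class `SynthConfig`.
#' @export
synthConfig <- function(n_per_cell = 8L, duration_s = 5, sample_rate = 44100L,
                        f0_male = c(100, 140), f0_female = c(180, 230),
                        jitter_pct = 0.5, shimmer_pct = 3, hnr_db = 25,
                        formants = c(800, 1200, 2500),
                        formant_bw = c(80, 90, 120),
                        post_delta = list(jitter = 2, shimmer = 6, hnr = -10),
                        seed = 1L) {
  stopifnot(n_per_cell >= 1, duration_s >= 2, jitter_pct >= 0,
            shimmer_pct >= 0, length(formants) == length(formant_bw),
            post_delta$jitter >= 0, post_delta$shimmer >= 0,
            post_delta$hnr <= 0)
  structure(list(n_per_cell = as.integer(n_per_cell),
                 duration_s = duration_s,
                 sample_rate = as.integer(sample_rate), f0_male = f0_male,
                 f0_female = f0_female, jitter_pct = jitter_pct,
                 shimmer_pct = shimmer_pct, hnr_db = hnr_db,
                 formants = formants, formant_bw = formant_bw,
                 post_delta = post_delta, seed = as.integer(seed)),
            class = "SynthConfig")
}

#' Synthesize a sustained vowel
#'
#' Source-filter synthesis: a glottal pulse train whose cycle lengths are
#' perturbed by `N(0, (jitter_pct/100 * T0)^2)` and amplitudes by
#' `N(0, (shimmer_pct/100)^2)`, shaped by second-order resonators at the
#' formant frequencies; breath noise (white noise through the same
#' resonators) is scaled so the harmonic-to-noise power ratio equals
#' `hnr_db`. The result is peak-normalized to 0.9. Draws come from the
#' current RNG state.
#'
#' @param f0 fundamental frequency, Hz (must be below `rate/4`).
#' @param jitter_pct,shimmer_pct,hnr_db perturbation and noise levels (see
#'   [synthConfig()]).
#' @param formants,formant_bw resonator frequencies and bandwidths, Hz.
#' @param duration_s length in seconds.
#' @param rate sampling rate, Hz.
#' @return mono waveform in \[-0.9, 0.9\].
#' @export
synthVowel <- function(f0, jitter_pct = 0.5, shimmer_pct = 3, hnr_db = 25,
                       formants = c(800, 1200, 2500),
                       formant_bw = c(80, 90, 120), duration_s = 5,
                       rate = 44100) {
  if (f0 >= rate / 4)
    stop("f0 must be below rate/4 for a usable harmonic structure")
  n <- round(duration_s * rate)
  T0 <- rate / f0
  n_cycles <- ceiling(n / T0) + 2L
  periods <- T0 * (1 + rnorm(n_cycles, 0, jitter_pct / 100))
  positions <- round(cumsum(c(1, periods)))
  positions <- positions[positions <= n]
  amps <- 1 + rnorm(length(positions), 0, shimmer_pct / 100)
  src <- numeric(n)
  src[positions] <- amps
  tract <- function(x) {
    for (j in seq_along(formants)) {
      r <- exp(-pi * formant_bw[j] / rate)
      th <- 2 * pi * formants[j] / rate
      x <- stats::filter(x, filter = c(2 * r * cos(th), -r * r),
                         method = "recursive")
    }
    as.numeric(x)
  }
  harm <- tract(src)
  noise <- tract(rnorm(n))
  p_h <- mean(harm^2); p_n <- mean(noise^2)
  noise <- noise * sqrt(p_h / (p_n * 10^(hnr_db / 10)))
  x <- harm + noise
  0.9 * x / max(abs(x))
}

#' Generate a labeled synthetic pre/post cohort
#'
#' Writes one pre- and one post-swallow recording per synthetic subject,
#' for both groups and sexes, plus the manifest CSV expected by
#' [standardizeManifest()]. Each subject keeps one fundamental frequency
#' across phases (same speaker); normal-group pre/post and
#' aspiration-group pre recordings are drawn from the baseline
#' parameters, while aspiration-group post recordings receive the
#' `post_delta` perturbations — the class signal lives in the pre-to-post
#' change, not in the baseline voice.
#'
#' @param cfg a [synthConfig()].
#' @param out_dir output directory (created if needed).
#' @return path to the written `manifest.csv`, invisibly; the manifest
#'   data.frame as attribute `"manifest"`.
#' @export
generateCohort <- function(cfg = synthConfig(), out_dir) {
  stopifnot(inherits(cfg, "SynthConfig"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(cfg$seed)
  rows <- list()
  sn <- 0L
  for (grp in .GROUPS) for (sex in .SEXES) {
    f0r <- if (sex == "male") cfg$f0_male else cfg$f0_female
    for (i in seq_len(cfg$n_per_cell)) {
      sn <- sn + 1L
      sid <- sprintf("SYN%03d", sn)
      f0 <- runif(1, f0r[1], f0r[2])
      for (ph in .PHASES) {
        delta <- grp == "aspiration" && ph == "post"
        wave <- synthVowel(
          f0,
          jitter_pct = cfg$jitter_pct + if (delta) cfg$post_delta$jitter else 0,
          shimmer_pct = cfg$shimmer_pct +
            if (delta) cfg$post_delta$shimmer else 0,
          hnr_db = cfg$hnr_db + if (delta) cfg$post_delta$hnr else 0,
          formants = cfg$formants, formant_bw = cfg$formant_bw,
          duration_s = cfg$duration_s, rate = cfg$sample_rate)
        fname <- sprintf("%s_%s.wav", sid, ph)
        writeWavePCM(wave, cfg$sample_rate, file.path(out_dir, fname))
        rows[[length(rows) + 1L]] <- data.frame(
          subject_id = sid, phase = ph, group_label = grp, sex = sex,
          substance = "water", device = "synth", path = fname,
          stringsAsFactors = FALSE)
      }
    }
  }
  manifest <- do.call(rbind, rows)
  mpath <- file.path(out_dir, "manifest.csv")
  write.csv(manifest, mpath, row.names = FALSE)
  out <- invisible(mpath)
  attr(out, "manifest") <- manifest
  out
}
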