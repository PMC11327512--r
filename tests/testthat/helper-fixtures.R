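# Shared fixtures, built in code. Heavier objects are memoized for the
# session so several test files can reuse them.

.fix <- new.env(parent = emptyenv())

sine_wave <- function(freq, dur_s, rate, amp = 0.5) {
  amp * sin(2 * pi * freq * seq(0, dur_s, length.out = round(dur_s * rate) + 1)[-1])
}

make_recording <- function(dur_s = 5, rate = 32000L, subject = "S01",
                           phase = "pre", freq = 200, ...) {
  RawRecording(sine_wave(freq, dur_s, rate), rate, subject, phase, ...)
}

# vowel-like harmonic test signal (not the cohort generator): a few
# harmonics with decaying amplitude
vowel_like <- function(dur_s = 2, rate = 32000L, f0 = 150) {
  t <- seq_len(round(dur_s * rate)) / rate
  x <- Reduce(`+`, lapply(1:8, function(h) sin(2 * pi * f0 * h * t) / h))
  0.7 * x / max(abs(x))
}

make_segment <- function(subject = "S01", phase = "pre", index = 1L,
                         rate = 32000L, freq = 200) {
  new("AudioSegment", subject_id = subject, phase = phase,
      segment_index = as.integer(index),
      waveform = sine_wave(freq, 2, rate), sample_rate = rate,
      duration_s = 2)
}

# a tiny pair table with small distinguishable payloads (not real audio)
toy_pairs <- function(n_subjects = 6, pairs_per_subject = 2,
                      labels = rep(0:1, length.out = n_subjects)) {
  rows <- list()
  for (s in seq_len(n_subjects)) {
    sid <- sprintf("T%02d", s)
    for (p in seq_len(pairs_per_subject)) {
      clip <- function(ph, i) {
        new("EncodedClip",
            payload = as.raw(c(s, p, i, sample.int(200, 5))),
            codec = "pcm16", bitrate_kbps = 64, channels = 1L,
            sample_rate = 32000L, subject_id = sid, phase = ph,
            segment_index = i)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = sid, label = labels[s],
        sex = if (s %% 2) "male" else "female", stringsAsFactors = FALSE)
      attr(rows[[length(rows)]], "pre") <- clip("pre", p)
      attr(rows[[length(rows)]], "post") <- clip("post", p)
    }
  }
  out <- do.call(rbind, rows)
  out$pre <- I(lapply(rows, attr, "pre"))
  out$post <- I(lapply(rows, attr, "post"))
  out
}

# segment table for a minimal synthetic cohort, memoized; used by store
# and training tests. 2 subjects per (group x sex), 5-s recordings at the
# analysis rate -> 2 segments per phase, 4 pairs per subject.
micro_segments <- function() {
  if (!is.null(.fix$micro_segments)) return(.fix$micro_segments)
  dir <- tempfile("micro")
  manifest <- generateCohort(synthConfig(n_per_cell = 2L,
                                         sample_rate = 32000L, seed = 303L),
                             dir)
  segs <- standardizeManifest(manifest)
  .fix$micro_segments <- segs
  segs
}

# a written micro dataset store (4 folds over 8 subjects), memoized
micro_store <- function() {
  if (!is.null(.fix$micro_store) && file.exists(.fix$micro_store))
    return(.fix$micro_store)
  pairs <- enumeratePairs(micro_segments())
  plan <- assignFolds(pairs, k = 4, seed = 17)
  path <- file.path(tempdir(), "micro_store.h5")
  writeDatasetStore(pairs, plan, path, oversample = "auto", seed = 17)
  .fix$micro_store <- path
  path
}

micro_model_cfg <- function() modelConfig(width_multiplier = 0.25)

micro_train_cfg <- function(epochs = 3L, seed = 99L)
  trainConfig(lr0 = 1e-3, batch_size = 16L, epochs = epochs,
              decay_start_epoch = max(1L, epochs - 1L),
              decay_end_epoch = epochs, seed = seed)

# autocorrelation-based fundamental-period estimate (independent oracle
# for the vowel synthesizer)
acf_f0 <- function(wave, rate, f0_range = c(80, 300)) {
  lags <- seq(floor(rate / f0_range[2]), ceiling(rate / f0_range[1]))
  x <- wave - mean(wave)
  denom <- sum(x * x)
  r <- vapply(lags, function(L) {
    sum(x[seq_len(length(x) - L)] * x[-seq_len(L)]) / denom
  }, numeric(1))
  list(f0 = rate / lags[which.max(r)], peak = max(r))
}
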