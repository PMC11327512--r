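test_that("endpoint trimming slices the waveform and preserves metadata", {
  rec <- make_recording(dur_s = 5, group_label = "normal", sex = "male")
  out <- trimEndpoints(rec, 0.3, 0.2)
  expect_equal(duration(out), 4.5, tolerance = 1e-6)
  expect_identical(subjectID(out), subjectID(rec))
  expect_identical(out@group_label, "normal")
  # identity case
  expect_identical(waveform(trimEndpoints(rec, 0, 0)), waveform(rec))
  # empty slice rejected
  short <- make_recording(dur_s = 1)
  expect_error(trimEndpoints(short, 0.6, 0.6), "empty")
})

test_that("energy auto-trimmer cuts silent head and tail only", {
  rate <- 32000L
  body <- sine_wave(200, 2, rate)
  x <- c(rep(0, rate / 2), body, rep(0, rate / 4))
  rec <- RawRecording(x, rate, "S01", "pre")
  out <- autoTrimEndpoints(rec)
  expect_lt(abs(duration(out) - 2), 0.05)
  # nothing to trim: returned unchanged
  rec2 <- make_recording(dur_s = 2)
  expect_equal(length(waveform(autoTrimEndpoints(rec2))),
               length(waveform(rec2)))
})

test_that("stereo split separates channels and rejects mono", {
  rate <- 8000L
  left <- sine_wave(440, 1, rate)
  stereo <- RawRecording(cbind(left, 0), rate, "S02", "post")
  lr <- splitStereo(stereo)
  expect_equal(waveform(lr$left), left)
  expect_equal(waveform(lr$right), rep(0, rate))
  expect_identical(phase(lr$left), "post")
  # identical channels give identical mono takes
  same <- splitStereo(RawRecording(cbind(left, left), rate, "S03", "pre"))
  expect_equal(waveform(same$left), waveform(same$right))
  expect_error(splitStereo(make_recording()), "mono|stereo")
})

test_that("resampling obeys the length law and preserves tones", {
  w <- sine_wave(440, 1, 44100L)
  y <- resampleWave(w, 44100, 32000)
  expect_length(y, 32000)
  # identity is bit-exact
  expect_identical(resampleWave(w, 44100, 44100), w)
  expect_error(resampleWave(w, 0, 32000), "positive")
  # dominant FFT peak stays at 440 Hz within one bin
  spec <- Mod(fft(y))[1:16000]
  peak_hz <- (which.max(spec) - 1) * 32000 / length(y)
  expect_lt(abs(peak_hz - 440), 32000 / length(y) + 1e-9)
  # arbitrary length rounding
  w2 <- rnorm(12345)
  expect_length(resampleWave(w2, 44100, 32000), round(12345 * 32000 / 44100))
})

test_that("fixed segmentation partitions the prefix and drops the tail", {
  rec <- make_recording(dur_s = 5)
  segs <- segmentFixed(rec, 2)
  expect_length(segs, 2)
  expect_true(all(vapply(segs, function(s) length(waveform(s)), numeric(1)) ==
                    64000))
  # concatenation reproduces the first 4 s exactly
  rec4 <- make_recording(dur_s = 4)
  segs4 <- segmentFixed(rec4, 2)
  expect_identical(c(waveform(segs4[[1]]), waveform(segs4[[2]])),
                   waveform(rec4))
  expect_warning(out <- segmentFixed(make_recording(dur_s = 1.5), 2),
                 "shorter")
  expect_length(out, 0)
})

test_that("pcm16 transcode/decode round-trips duration and waveform", {
  seg <- new("AudioSegment", subject_id = "S01", phase = "pre",
             segment_index = 1L, waveform = vowel_like(),
             sample_rate = 32000L, duration_s = 2)
  clip <- transcodeClip(seg, "pcm16")
  expect_s4_class(clip, "EncodedClip")
  y <- decodeClip(clip)
  expect_length(y, 64000)
  expect_gt(cor(y, waveform(seg)), 0.9)
  expect_true(all(abs(y) <= 1))
  # silence in, near-silence out
  silent <- new("AudioSegment", subject_id = "S01", phase = "pre",
                segment_index = 1L, waveform = rep(0, 64000),
                sample_rate = 32000L, duration_s = 2)
  expect_lt(max(abs(decodeClip(transcodeClip(silent)))), 1e-3)
  # corrupt payload: odd byte count cannot be pcm16
  bad <- clip
  bad@payload <- clip@payload[seq_len(length(clip@payload) - 1L)]
  expect_error(decodeClip(bad), "corrupt")
})

test_that("mp3 codec either works through an external encoder or fails informatively", {
  seg <- new("AudioSegment", subject_id = "S01", phase = "pre",
             segment_index = 1L, waveform = vowel_like(),
             sample_rate = 32000L, duration_s = 2)
  if (nzchar(audioConverter())) {
    clip <- transcodeClip(seg, "mp3")
    y <- decodeClip(clip, target_rate = 32000)
    expect_lt(abs(length(y) / 32000 - 2), 0.05)
  } else {
    expect_error(transcodeClip(seg, "mp3"), "encoder")
  }
})

test_that("wav files round-trip through the PCM reader/writer", {
  path <- tempfile(fileext = ".wav")
  w <- vowel_like(dur_s = 0.5)
  writeWavePCM(w, 32000, path)
  r <- readWavePCM(path)
  expect_equal(r$sample_rate, 32000)
  expect_equal(r$channels, 1)
  expect_equal(drop(r$waveform), w, tolerance = 1e-4)
  # stereo
  writeWavePCM(cbind(w, -w), 32000, path)
  r2 <- readWavePCM(path)
  expect_equal(r2$channels, 2)
  expect_equal(r2$waveform[, 2], -w, tolerance = 1e-4)
  unlink(path)
})

test_that("manifest standardization yields encoded 2-s mono segments", {
  segs <- micro_segments()
  expect_true(all(c("subject_id", "phase", "group_label", "sex",
                    "segment_index", "clip") %in% names(segs)))
  # 8 subjects x 2 phases x 2 segments from 5-s recordings
  expect_equal(nrow(segs), 32)
  clip <- segs$clip[[1]]
  expect_s4_class(clip, "EncodedClip")
  expect_equal(sampleRate(clip), 32000L)
  expect_length(decodeClip(clip), 64000)
})
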