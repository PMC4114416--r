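# Front end: WAV I/O, framing, segmentation, mel-cepstral features.

test_that("frame counts follow T = 1 + floor((N - L)/H) and tiling holds", {
  rec <- audioRecording(sin(seq_len(16000) / 50), 16000)
  fs <- frameSignal(rec, 0.025, 0.010)
  expect_equal(nrow(fs$frames), 1 + (16000 - 400) %/% 160)  # 98
  expect_equal(fs$frames[2, 1], samples(rec)[161])          # hop spacing

  short <- audioRecording(numeric(320), 16000)              # 0.02 s
  expect_equal(nrow(frameSignal(short, 0.025, 0.010)$frames), 0)

  two <- audioRecording(stats::runif(32000, -1, 1), 16000)  # 2.0 s
  tiles <- frameSignal(two, 0.5, 0.5)
  expect_equal(nrow(tiles$frames), 4)
  expect_equal(as.vector(t(tiles$frames)), samples(two))
})

test_that("segments tile the recording; only the last may be short", {
  sr <- 16000
  expect_length(segmentStream(audioRecording(numeric(60 * sr), sr)), 10)
  expect_length(segmentStream(audioRecording(numeric(6 * sr), sr)), 1)
  segs <- segmentStream(audioRecording(numeric(13 * sr), sr))
  expect_equal(vapply(segs, `[[`, numeric(1), "durationS"), c(6, 6, 1))
  expect_equal(vapply(segs, `[[`, numeric(1), "startS"), c(0, 6, 12))
  # exact cover, in order
  expect_equal(sum(vapply(segs, function(s) length(s$samples), numeric(1))),
               13 * sr)
})

test_that("WAV round-trips preserve samples; stereo is mean-downmixed", {
  sr <- 8000
  x <- sin(2 * pi * 440 * (0:7999) / sr) * 0.8
  p <- tempfile(fileext = ".wav")
  writeWav(audioRecording(x, sr), p, bits = 16L)
  rt <- readWav(p)
  expect_equal(sampleRate(rt), sr)
  expect_equal(samples(rt), x, tolerance = 1e-3)   # 16-bit quantisation

  writeWav(audioRecording(x, sr), p, bits = 32L)
  expect_equal(samples(readWav(p)), x, tolerance = 1e-7)

  # hand-build a stereo PCM16 file: L = x, R = 0 -> downmix x/2
  p2 <- tempfile(fileext = ".wav")
  con <- file(p2, "wb")
  inter <- as.integer(rbind(round(x * 32767), 0L))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + length(inter) * 2), con, 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, 4, endian = "little")
  writeBin(1L, con, 2, endian = "little"); writeBin(2L, con, 2, endian = "little")
  writeBin(as.integer(sr), con, 4, endian = "little")
  writeBin(as.integer(sr * 4), con, 4, endian = "little")
  writeBin(4L, con, 2, endian = "little"); writeBin(16L, con, 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(length(inter) * 2), con, 4, endian = "little")
  writeBin(inter, con, 2, endian = "little")
  close(con)
  dm <- readWav(p2)
  expect_length(samples(dm), length(x))
  expect_equal(samples(dm), x / 2, tolerance = 1e-3)

  expect_error(readWav(tempfile()), "not found")
})

test_that("resampling to the working rate preserves tone frequency", {
  sr <- 8000
  x <- sin(2 * pi * 440 * (0:(2 * sr - 1)) / sr) * 0.5
  p <- tempfile(fileext = ".wav")
  writeWav(audioRecording(x, sr), p)
  up <- readWav(p, targetRate = 16000)
  expect_equal(sampleRate(up), 16000)
  expect_equal(length(samples(up)), 2 * length(x))
  # dominant frequency via periodogram (independent of the resampler)
  sp <- Mod(stats::fft(samples(up)))^2
  n <- length(samples(up))
  fpeak <- (which.max(sp[2:(n / 2)])) * 16000 / n
  expect_lt(abs(fpeak - 440) / 440, 0.01)
})

test_that("silence at 16 kHz reads back as zeros of the right duration", {
  p <- tempfile(fileext = ".wav")
  writeWav(audioRecording(numeric(16000), 16000), p)
  rec <- readWav(p)
  expect_equal(duration(rec), 1.0)
  expect_true(all(samples(rec) == 0))
})

test_that("feature dimensionality and silence handling", {
  cfg <- featureConfig()
  f <- featuresForSamples(numeric(16000), cfg)
  expect_equal(ncol(featureMatrix(f)), 39)
  expect_true(all(is.finite(featureMatrix(f))))
  cfg0 <- featureConfig(useDeltas = FALSE)
  expect_equal(ncol(featureMatrix(featuresForSamples(numeric(8000), cfg0))),
               13)
})

test_that("static cepstra match an independent naive reference", {
  set.seed(42)
  sr <- 16000
  x <- sin(2 * pi * 1000 * (0:(sr / 2)) / sr) * 0.7 +
    stats::rnorm(sr / 2 + 1, 0, 0.01)
  cfg <- featureConfig(useDeltas = FALSE, cmn = FALSE)
  fs <- frameSignal(audioRecording(x, sr), cfg$frameS, cfg$hopS)
  mine <- featureMatrix(computeFeatureVectors(fs, cfg))
  ref <- naiveMfcc(fs$frames, sr)
  expect_equal(unname(mine), ref, tolerance = 1e-3)
  # pure-tone: interior static features near-constant
  tone <- featuresForSamples(sin(2 * pi * 1000 * (0:sr) / sr), cfg)
  inner <- featureMatrix(tone)[10:(nFrames(tone) - 10), ]
  expect_lt(max(apply(inner, 2, stats::sd)), 1e-2)
})

test_that("features are deterministic and gain-invariant after CMN", {
  set.seed(7)
  x <- stats::rnorm(16000) * 0.1
  cfg <- featureConfig()
  a <- featureMatrix(featuresForSamples(x, cfg))
  b <- featureMatrix(featuresForSamples(x, cfg))
  expect_identical(a, b)
  g <- featureMatrix(featuresForSamples(0.25 * x, cfg))
  expect_equal(a, g, tolerance = 1e-6)
  # without CMN, log-energy shifts by a constant under gain
  cfgN <- featureConfig(cmn = FALSE)
  e1 <- featureMatrix(featuresForSamples(x, cfgN))[, 1]
  e2 <- featureMatrix(featuresForSamples(0.25 * x, cfgN))[, 1]
  expect_equal(stats::sd(e1 - e2), 0, tolerance = 1e-9)
})
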