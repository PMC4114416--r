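# The seeded generators: determinism, acoustic contracts, label fidelity.

test_that("cough synthesis is deterministic with controlled amplitude", {
  cp <- coughParams(amplitude = 0.7)
  a <- synthCough(cp, seed = 3)
  b <- synthCough(cp, seed = 3)
  expect_identical(samples(a), samples(b))
  expect_equal(max(abs(samples(a))), 0.7, tolerance = 1e-12)
  # zero amplitude -> silent burst
  z <- synthCough(coughParams(amplitude = 0), seed = 3)
  expect_true(all(samples(z) == 0))
  expect_error(coughParams(bandLowHz = 3000, bandHighHz = 300), "band")
  expect_error(synthCough(coughParams(bandHighHz = 9000), 16000), "Nyquist")
})

test_that("the burst's spectral centroid lies inside its band", {
  cp <- coughParams(bandLowHz = 400, bandHighHz = 2500,
                    burstDurationS = 0.3, voicedTail = FALSE)
  x <- samples(synthCough(cp, seed = 5))
  sp <- Mod(stats::fft(x))^2
  n <- length(x)
  freqs <- (seq_len(n %/% 2) - 1) * 16000 / n
  p <- sp[seq_len(n %/% 2)]
  centroid <- sum(freqs * p) / sum(p)
  expect_gt(centroid, 400)
  expect_lt(centroid, 2500)
})

test_that("scenes honour event counts, spacing, and the SNR contract", {
  empty <- synthScene(sceneSpec(durationS = 30, nCoughs = 0, seed = 2))
  expect_equal(nrow(empty$truth), 0)
  expect_equal(duration(empty$recording), 30)

  sc <- synthScene(sceneSpec(durationS = 600, nCoughs = 30, snrDb = 10,
                             distractors = c("babble", "hum"), seed = 4))
  tr <- sc$truth
  expect_equal(nrow(tr), 30)
  expect_true(all(tr$end_s > tr$start_s))
  o <- order(tr$start_s)
  expect_true(all(tr$start_s[o][-1] >= tr$end_s[o][-30]))   # non-overlap
  # each cough inside one 6-s segment by default
  expect_true(all(floor(tr$start_s / 6) == floor((tr$end_s - 1e-9) / 6)))

  # measured SNR: in-event power vs out-of-event power, within +/- 1 dB
  x <- samples(sc$recording)
  sr <- 16000
  inEv <- logical(length(x))
  for (k in seq_len(nrow(tr)))
    inEv[(round(tr$start_s[k] * sr) + 1):round(tr$end_s[k] * sr)] <- TRUE
  pIn <- mean(x[inEv]^2)
  pBg <- mean(x[!inEv]^2)
  measured <- 10 * log10((pIn - pBg) / pBg)
  expect_lt(abs(measured - 10), 1)

  expect_error(synthScene(sceneSpec(durationS = 12, nCoughs = 5, seed = 1)),
               "place")
})

test_that("scene generation is a pure function of its seed", {
  s1 <- synthScene(sceneSpec(durationS = 24, nCoughs = 2, seed = 11))
  s2 <- synthScene(sceneSpec(durationS = 24, nCoughs = 2, seed = 11))
  expect_identical(samples(s1$recording), samples(s2$recording))
  expect_identical(s1$truth$start_s, s2$truth$start_s)
})

test_that("HMM sampling reproduces means and self-transition rates", {
  lt <- matrix(-Inf, 4, 4)
  lt[1, 2] <- 0
  lt[2, 2:3] <- log(c(0.85, 0.15))
  lt[3, 3:4] <- log(c(0.90, 0.10))
  lt[4, 4] <- 0
  truth <- new("Hmm", label = "t", nStates = 2L, logTrans = lt,
               emissions = list(
                 list(weights = 1, means = matrix(c(0, 0), 1),
                      variances = matrix(c(1, 1), 1)),
                 list(weights = 1, means = matrix(c(6, 6), 1),
                      variances = matrix(c(1, 1), 1))))
  seqs <- sampleHmmSequences(truth, 400, 200, seed = 8)
  expect_length(seqs, 400)
  s2 <- sampleHmmSequences(truth, 400, 200, seed = 8)
  expect_identical(featureMatrix(seqs[[1]]), featureMatrix(s2[[1]]))

  paths <- attr(seqs, "statePaths")
  X <- do.call(rbind, lapply(seqs, featureMatrix))
  st <- unlist(paths)
  expect_equal(colMeans(X[st == 1, ]), c(0, 0), tolerance = 0.05)
  expect_equal(colMeans(X[st == 2, ]), c(6, 6), tolerance = 0.05)
  # empirical transition frequencies, with exit counted as leaving state 2
  cnt <- vapply(paths, function(p) {
    len <- length(p)
    c(sum(p[-1] == 1 & p[-len] == 1), sum(p == 1),
      sum(p[-1] == 2 & p[-len] == 2), sum(p == 2))
  }, numeric(4))
  tot <- rowSums(cnt)
  expect_lt(abs(tot[1] / tot[2] - 0.85), 0.05)
  expect_lt(abs(tot[3] / tot[4] - 0.90), 0.05)
})

test_that("activity traces stay in range and respect coupling", {
  tr0 <- synthAccel(3600, coupling = 0, seed = 1)
  expect_equal(nrow(tr0), 60)
  expect_true(all(tr0$score >= 0 & tr0$score <= 24))
  ev <- c(90, 95, 100)
  trC <- synthAccel(3600, ev, coupling = 10, seed = 1)
  # same baseline seed: coupled minute 2 is elevated by 3 * 10 (capped)
  expect_equal(trC$score[2], min(tr0$score[2] + 30, 24))
  expect_identical(trC$score[-2], tr0$score[-2])
  expect_error(synthAccel(100, eventTimes = 200), "within")
})

test_that("a high-SNR scene is essentially fully recovered end to end", {
  net <- smallNetwork()
  sc <- synthScene(sceneSpec(durationS = 120, nCoughs = 10, snrDb = 20,
                             seed = 15))
  ev <- collectEvents(detectEvents(sc$recording, net, detectionConfig()))
  m <- matchEvents(ev, sc$truth, 0.5)
  expect_gte(sensitivity(m), 0.9)
})
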