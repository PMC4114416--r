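# Segment-level detection, event post-processing, audit retention, and
# hourly aggregation.

test_that("high-SNR synthetic coughs are recovered at their true times", {
  net <- smallNetwork()
  sc <- synthScene(sceneSpec(durationS = 60, nCoughs = 5, snrDb = 20,
                             seed = 9))
  res <- detectEvents(sc$recording, net, detectionConfig(seed = 2))
  ev <- collectEvents(res)
  m <- matchEvents(ev, sc$truth, tolS = 0.5)
  expect_equal(m$tp, 5)
  # start times within 0.25 s of truth
  for (k in seq_len(nrow(m$matchedPairs))) {
    d <- ev$start_s[m$matchedPairs$detected_index[k]]
    t <- sc$truth$start_s[m$matchedPairs$truth_index[k]]
    expect_lt(abs(d - t), 0.25)
  }
  # positive segments retained as such
  pos <- Filter(function(r) nrow(r$events) > 0, res)
  expect_true(all(vapply(pos, `[[`, logical(1), "retained")))
  expect_true(all(vapply(pos, `[[`, character(1), "retentionReason") ==
                    "positive"))
})

test_that("near-silence yields no events; retention then only by chance", {
  net <- smallNetwork()
  set.seed(5)
  rec <- audioRecording(stats::rnorm(18 * 16000) * 1e-4, 16000)
  res0 <- detectEvents(rec, net, detectionConfig(retentionProbability = 0,
                                                 seed = 3))
  expect_equal(nrow(collectEvents(res0)), 0)
  expect_false(any(vapply(res0, `[[`, logical(1), "retained")))
})

test_that("event counts are conserved into hourly buckets", {
  net <- smallNetwork()
  sc <- synthScene(sceneSpec(durationS = 120, nCoughs = 8, snrDb = 15,
                             seed = 13))
  ev <- collectEvents(detectEvents(sc$recording, net, detectionConfig()))
  hc <- aggregateHourly(ev, NA_real_, 120)
  expect_equal(sum(hc$cough_count), nrow(ev))
})

test_that("segments decode independently of their neighbours", {
  net <- smallNetwork()
  sc <- synthScene(sceneSpec(durationS = 36, nCoughs = 3, snrDb = 15,
                             seed = 21))
  full <- collectEvents(detectEvents(sc$recording, net, detectionConfig()))
  # decode each 6-s segment as its own recording, in shuffled order
  segs <- segmentStream(sc$recording, 6)
  set.seed(1)
  for (i in sample(seq_along(segs))) {
    seg <- segs[[i]]
    solo <- collectEvents(detectEvents(audioRecording(seg$samples, 16000),
                                       net, detectionConfig()))
    mine <- full[full$segment_index == seg$index, , drop = FALSE]
    expect_equal(nrow(solo), nrow(mine))
    if (nrow(solo))
      expect_equal(solo$start_s + seg$startS, mine$start_s,
                   tolerance = 1e-9)
  }
})

test_that("random retention hits its probability within 3 standard errors", {
  empty <- replicate(2000, list(events = data.frame()), simplify = FALSE)
  p <- 0.05
  out <- applyRetention(empty, p, seed = 42)
  rate <- mean(vapply(out, `[[`, logical(1), "retained"))
  se <- sqrt(p * (1 - p) / 2000)
  expect_lt(abs(rate - p), 3 * se)
  expect_true(all(vapply(out, `[[`, character(1), "retentionReason") %in%
                    c("random", "none")))
  # deterministic under the same seed
  out2 <- applyRetention(empty, p, seed = 42)
  expect_identical(vapply(out, `[[`, logical(1), "retained"),
                   vapply(out2, `[[`, logical(1), "retained"))
})

test_that("raising minEventS never increases the event count", {
  net <- smallNetwork()
  sc <- synthScene(sceneSpec(durationS = 60, nCoughs = 5, snrDb = 12,
                             seed = 31))
  counts <- vapply(c(0, 0.06, 0.15, 0.3, 0.6), function(mes) {
    nrow(collectEvents(detectEvents(sc$recording, net,
                                    detectionConfig(minEventS = mes))))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("hourly buckets: counts, partial-hour fractions, wall anchoring", {
  ev <- data.frame(start_s = c(10, 30, 3700))
  hc <- aggregateHourly(ev, NA_real_, 7200)
  expect_equal(hc$cough_count, c(2L, 1L))
  expect_equal(hc$monitored_fraction, c(1, 1))

  none <- aggregateHourly(data.frame(start_s = numeric(0)), NA_real_, 7200)
  expect_equal(none$cough_count, c(0L, 0L))

  halfPast <- as.numeric(as.POSIXct("2024-03-19 13:30:00", tz = "UTC"))
  hc2 <- aggregateHourly(data.frame(start_s = numeric(0)), halfPast, 3600)
  expect_equal(length(hc2$hour_start), 2)
  expect_equal(format(as.POSIXct(hc2$hour_start, origin = "1970-01-01",
                                 tz = "UTC"), "%H:%M"), c("13:00", "14:00"))
  expect_equal(hc2$monitored_fraction, c(0.5, 0.5))

  expect_error(aggregateHourly(data.frame(start_s = 10), NA_real_, 5),
               "outside")
})

test_that("retained-audio export writes clips plus a faithful manifest", {
  net <- smallNetwork()
  sc <- synthScene(sceneSpec(durationS = 60, nCoughs = 2, snrDb = 15,
                             seed = 41))
  cfg <- detectionConfig(retentionProbability = 0.3, seed = 7)
  res <- detectEvents(sc$recording, net, cfg)
  d <- file.path(tempdir(), "retained-a")
  man <- exportRetainedAudio(sc$recording, res, d)
  nKept <- sum(vapply(res, `[[`, logical(1), "retained"))
  expect_equal(nrow(man), nKept)
  expect_true(all(file.exists(file.path(d, man$file))))
  expect_true(all(grepl("positive|random", man$file)))
  # reruns with the same seed/config give a byte-identical manifest
  d2 <- file.path(tempdir(), "retained-b")
  res2 <- detectEvents(sc$recording, net, cfg)
  exportRetainedAudio(sc$recording, res2, d2)
  expect_identical(readLines(file.path(d, "manifest.csv")),
                   readLines(file.path(d2, "manifest.csv")))
  # zero retained -> empty manifest, no clips
  res0 <- applyRetention(lapply(res, function(r) {
    r$events <- r$events[0, , drop = FALSE]; r
  }), 0, seed = 1)
  d3 <- file.path(tempdir(), "retained-c")
  man0 <- exportRetainedAudio(sc$recording, res0, d3)
  expect_equal(nrow(man0), 0)
  expect_equal(length(list.files(d3, pattern = "[.]wav$")), 0)
})
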