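# Segment-by-segment decoding of a recording, event extraction, the
# audit-retention protocol, and hourly aggregation.

#' Detection configuration
#'
#' @param segmentS processing block length, seconds (the device used 6 s).
#' @param minEventS decoded cough spans shorter than this are dropped
#'   (default 60 ms, below the explosive phase of a cough).
#' @param mergeGapS cough spans separated by less than this are merged
#'   (default 200 ms, within-cough phase gaps).
#' @param retentionProbability probability of retaining a cough-free segment
#'   for audit (positive segments are always retained).
#' @param seed RNG seed for random retention draws.
#' @param loopPenalty passed through to decoding; overrides the network's
#'   value when non-NULL.
#' @param beam log-domain beam width for decoding; Inf = exact.
#' @param cfg a [featureConfig()] used per segment.
#' @return list with class "DetectionConfig".
#' @export
detectionConfig <- function(segmentS = 6.0, minEventS = 0.06,
                            mergeGapS = 0.2, retentionProbability = 0.05,
                            seed = 1L, loopPenalty = NULL, beam = Inf,
                            cfg = featureConfig()) {
  stopIfNot(retentionProbability >= 0 && retentionProbability <= 1,
            "retentionProbability must be in [0, 1]")
  stopIfNot(minEventS >= 0, "minEventS must be >= 0")
  structure(list(segmentS = segmentS, minEventS = minEventS,
                 mergeGapS = mergeGapS,
                 retentionProbability = retentionProbability,
                 seed = seed, loopPenalty = loopPenalty, beam = beam,
                 cfg = cfg), class = "DetectionConfig")
}

mergeSpans <- function(ev, gapS) {
  # ev: data.frame(start_s, end_s, log_score) sorted by start
  if (nrow(ev) <= 1L) return(ev)
  keep <- ev[1L, , drop = FALSE]
  for (i in 2L:nrow(ev)) {
    last <- nrow(keep)
    if (ev$start_s[i] - keep$end_s[last] < gapS) {
      keep$end_s[last] <- max(keep$end_s[last], ev$end_s[i])
      keep$log_score[last] <- keep$log_score[last] + ev$log_score[i]
    } else keep <- rbind(keep, ev[i, , drop = FALSE])
  }
  keep
}

#' Apply the audit-retention rule to segment results
#'
#' Segments with detected events are always retained (reason "positive");
#' event-free segments are retained with the configured probability via a
#' seeded draw (reason "random"), else not retained (reason "none").
#'
#' @param results list of SegmentResult lists (fields `events`, ...).
#' @param retentionProbability per-empty-segment retention probability.
#' @param seed RNG seed (one uniform draw per empty segment, in order).
#' @return `results` with `retained` and `retentionReason` filled in.
#' @export
applyRetention <- function(results, retentionProbability, seed = 1L) {
  withLocalSeed(seed, {
    for (i in seq_along(results)) {
      hasEvents <- nrow(results[[i]]$events) > 0L
      if (hasEvents) {
        results[[i]]$retained <- TRUE
        results[[i]]$retentionReason <- "positive"
      } else {
        keep <- stats::runif(1) < retentionProbability
        results[[i]]$retained <- keep
        results[[i]]$retentionReason <- if (keep) "random" else "none"
      }
    }
    results
  })
}

# per-segment feature extraction (shared by detection and penalty
# calibration, which decodes the same features under several penalties)
segmentFeatures <- function(rec, cfg) {
  segs <- segmentStream(rec, cfg$segmentS)
  lapply(segs, function(seg) {
    seg$feats <- featuresForSamples(seg$samples, cfg$cfg)
    seg$samples <- NULL
    seg
  })
}

decodeSegments <- function(segFeats, net, cfg) {
  fcfg <- cfg$cfg
  minStates <- min(vapply(net@models, nStates, integer(1)))
  lapply(segFeats, function(seg) {
    emptyEv <- data.frame(start_s = numeric(0), end_s = numeric(0),
                          segment_index = integer(0), log_score = numeric(0))
    if (nFrames(seg$feats) < minStates)
      return(list(segmentIndex = seg$index, startS = seg$startS,
                  durationS = seg$durationS, events = emptyEv))
    dp <- decodeTokenPassing(net, seg$feats, beam = cfg$beam)
    ck <- dp[dp$label == net@keyword, , drop = FALSE]
    ev <- if (nrow(ck)) {
      data.frame(start_s = seg$startS + (ck$firstFrame - 1) * fcfg$hopS,
                 end_s = seg$startS + (ck$lastFrame - 1) * fcfg$hopS +
                   fcfg$frameS,
                 log_score = ck$logScore)
    } else data.frame(start_s = numeric(0), end_s = numeric(0),
                      log_score = numeric(0))
    ev <- mergeSpans(ev, cfg$mergeGapS)
    ev <- ev[ev$end_s - ev$start_s >= cfg$minEventS, , drop = FALSE]
    ev$end_s <- pmin(ev$end_s, seg$startS + seg$durationS)
    ev <- data.frame(start_s = ev$start_s, end_s = ev$end_s,
                     segment_index = rep(seg$index, nrow(ev)),
                     log_score = ev$log_score)
    rownames(ev) <- NULL
    list(segmentIndex = seg$index, startS = seg$startS,
         durationS = seg$durationS, events = ev)
  })
}

#' Detect cough events in a recording
#'
#' Processes the recording in independent fixed-length segments: features are
#' computed per segment (with per-segment cepstral mean normalisation when
#' configured), each segment is decoded against the recognition network,
#' cough-labeled spans are converted to timestamped events (close spans
#' merged, then short spans dropped), and the audit-retention rule is
#' applied.
#'
#' @param rec an [AudioRecording-class].
#' @param net a trained [RecognitionNetwork-class].
#' @param cfg a [detectionConfig()].
#' @return list of SegmentResult lists, each with `segmentIndex`, `startS`,
#'   `durationS`, `events` (data.frame start_s, end_s, segment_index,
#'   log_score), `retained`, `retentionReason`. Use [collectEvents()] for a
#'   flat event table.
#' @export
detectEvents <- function(rec, net, cfg = detectionConfig()) {
  stopIfNot(length(samples(rec)) > 0L, "recording is empty")
  if (!is(net, "RecognitionNetwork")) stop("net must be a RecognitionNetwork")
  fcfg <- cfg$cfg
  if (abs(sampleRate(rec) - fcfg$sampleRate) > 1e-9)
    stop("recording sample rate ", sampleRate(rec),
         " differs from feature configuration rate ", fcfg$sampleRate,
         "; read with targetRate = ", fcfg$sampleRate)
  dNet <- featureDim(net@models[[1L]])
  dCfg <- fcfg$nCepstra * (if (fcfg$useDeltas) 3L else 1L)
  if (dNet != dCfg)
    stop("network feature dimension ", dNet,
         " does not match configuration dimension ", dCfg)
  if (!is.null(cfg$loopPenalty)) net@loopPenalty <- cfg$loopPenalty
  results <- decodeSegments(segmentFeatures(rec, cfg), net, cfg)
  applyRetention(results, cfg$retentionProbability, cfg$seed)
}

#' Flatten segment results into one event table
#' @param results output of [detectEvents()].
#' @return data.frame with `start_s`, `end_s`, `segment_index`, `log_score`.
#' @export
collectEvents <- function(results) {
  ev <- do.call(rbind, lapply(results, `[[`, "events"))
  if (is.null(ev))
    ev <- data.frame(start_s = numeric(0), end_s = numeric(0),
                     segment_index = integer(0), log_score = numeric(0))
  rownames(ev) <- NULL
  ev
}

#' Aggregate cough events into hourly counts
#'
#' One bucket per clock hour intersecting the recording. When the recording
#' carries a wall-clock start time, buckets are anchored to clock hours;
#' otherwise hours run from the recording start. `monitored_fraction` is the
#' covered fraction of each hour.
#'
#' @param events data.frame with `start_s` (seconds from recording start).
#' @param recStart recording start, seconds since epoch, or NA.
#' @param recDurationS recording duration, seconds.
#' @return data.frame: `hour_start` (seconds since epoch, or seconds from
#'   start), `cough_count`, `monitored_fraction`.
#' @export
aggregateHourly <- function(events, recStart = NA_real_, recDurationS) {
  if (nrow(events) &&
      (any(events$start_s < 0) || any(events$start_s > recDurationS)))
    stop("events outside the recording span")
  anchor <- if (is.na(recStart)) 0 else recStart
  t0 <- anchor
  t1 <- anchor + recDurationS
  firstHour <- floor(t0 / 3600) * 3600
  hours <- seq(firstHour, ifelse(t1 %% 3600 == 0, t1 - 3600, t1), by = 3600)
  hours <- hours[hours < t1]
  cnt <- vapply(hours, function(h) {
    sum(events$start_s + anchor >= h & events$start_s + anchor < h + 3600)
  }, numeric(1))
  frac <- vapply(hours, function(h) {
    (min(h + 3600, t1) - max(h, t0)) / 3600
  }, numeric(1))
  data.frame(hour_start = hours, cough_count = as.integer(cnt),
             monitored_fraction = frac)
}

#' Export retained audit segments as WAV clips with a manifest
#'
#' Writes one clip per retained segment, filenames encoding segment index
#' and retention reason, and a CSV manifest (file, reason, event count).
#'
#' @param rec the decoded [AudioRecording-class].
#' @param results output of [detectEvents()] for `rec`.
#' @param outDir output directory (created if absent).
#' @return data.frame manifest (also written to `manifest.csv` in `outDir`).
#' @export
exportRetainedAudio <- function(rec, results, outDir) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  sr <- sampleRate(rec)
  x <- samples(rec)
  kept <- Filter(function(r) isTRUE(r$retained), results)
  rows <- lapply(kept, function(r) {
    a <- round(r$startS * sr) + 1L
    b <- min(a + round(r$durationS * sr) - 1L, length(x))
    fn <- sprintf("segment_%05d_%s.wav", r$segmentIndex, r$retentionReason)
    writeWav(audioRecording(x[a:b], sr), file.path(outDir, fn))
    data.frame(file = fn, reason = r$retentionReason,
               n_events = nrow(r$events))
  })
  manifest <- if (length(rows)) do.call(rbind, rows) else
    data.frame(file = character(0), reason = character(0),
               n_events = integer(0))
  utils::write.csv(manifest, file.path(outDir, "manifest.csv"),
                   row.names = FALSE)
  manifest
}

#' Write a flat event table as CSV
#' @param events data.frame from [collectEvents()].
#' @param path output path.
#' @export
writeEventsCsv <- function(events, path) {
  utils::write.csv(events, path, row.names = FALSE)
  invisible(path)
}

#' Read an events CSV (start_s, end_s, ...)
#' @param path CSV path.
#' @export
readEventsCsv <- function(path) utils::read.csv(path)
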