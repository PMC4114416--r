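# Seeded generators for every input the pipeline consumes: parametric cough
# bursts, background/distractor audio, labeled acoustic scenes, HMM-sampled
# feature corpora, coupled activity traces, and survey response tables.
# Every generator is a pure function of (spec, seed).

#' Parameters of a synthetic cough burst
#'
#' A cough is modelled as a band-filtered noise burst with a sharp attack and
#' exponential decay, band-limited to the mid-frequency range typical of
#' explosive-phase cough sounds, optionally followed by a short low-frequency
#' voiced tail.
#'
#' @param burstDurationS burst duration, seconds (typical 0.05-0.35).
#' @param attackS attack ramp, seconds.
#' @param decayRate exponential envelope decay, 1/s.
#' @param bandLowHz,bandHighHz band edges, Hz (high edge below Nyquist).
#' @param voicedTail append a short damped-harmonic tail.
#' @param amplitude peak amplitude in \[0, 1\] (0 gives silence).
#' @return list with class "CoughParams".
#' @export
coughParams <- function(burstDurationS = 0.2, attackS = 0.01, decayRate = 15,
                        bandLowHz = 300, bandHighHz = 3000,
                        voicedTail = FALSE, amplitude = 0.9) {
  stopIfNot(bandLowHz < bandHighHz, "need bandLowHz < bandHighHz")
  stopIfNot(burstDurationS > 0 && attackS > 0, "durations must be positive")
  stopIfNot(amplitude >= 0 && amplitude <= 1, "amplitude must be in [0, 1]")
  structure(list(burstDurationS = burstDurationS, attackS = attackS,
                 decayRate = decayRate, bandLowHz = bandLowHz,
                 bandHighHz = bandHighHz, voicedTail = voicedTail,
                 amplitude = amplitude), class = "CoughParams")
}

# zero-phase band-pass via the frequency domain with raised-cosine edges;
# much faster than IIR filtering for the long signals the generators build
fftBandpass <- function(x, sr, lowHz, highHz, transHz = 50) {
  n <- length(x)
  if (n < 16L) return(x)
  f <- abs(seq(0, sr, length.out = n + 1L)[seq_len(n)])
  f <- pmin(f, sr - f)                     # two-sided frequency axis
  ramp <- function(fr, edge, width) {
    w <- pmin(pmax((fr - edge) / width + 0.5, 0), 1)
    0.5 - 0.5 * cos(pi * w)
  }
  gain <- ramp(f, lowHz, transHz) * (1 - ramp(f, highHz, transHz))
  Re(stats::fft(stats::fft(x) * gain, inverse = TRUE)) / n
}

bandNoise <- function(n, sr, lowHz, highHz) {
  if (n < 16L) return(stats::rnorm(n) * 0.1)
  fftBandpass(stats::rnorm(n), sr, lowHz, highHz)
}

#' Synthesise one cough burst
#'
#' @param params a [coughParams()] object.
#' @param sampleRate sample rate, Hz (band high edge must be below Nyquist).
#' @param seed RNG seed; the output is a pure function of (params, seed).
#' @return An [AudioRecording-class] whose peak amplitude equals
#'   `params$amplitude` (all-zero for amplitude effectively 0).
#' @export
synthCough <- function(params = coughParams(), sampleRate = 16000,
                       seed = 1L) {
  stopIfNot(params$bandHighHz < sampleRate / 2,
            "bandHighHz must be below the Nyquist frequency")
  withLocalSeed(seed, {
    n <- max(round(params$burstDurationS * sampleRate), 8L)
    t <- (seq_len(n) - 1L) / sampleRate
    env <- pmin(t / params$attackS, 1) * exp(-params$decayRate * t)
    x <- bandNoise(n, sampleRate, params$bandLowHz, params$bandHighHz) * env
    if (isTRUE(params$voicedTail)) {
      nt <- round(0.08 * sampleRate)
      tt <- (seq_len(nt) - 1L) / sampleRate
      f0 <- stats::runif(1, 140, 220)
      tail <- (sin(2 * pi * f0 * tt) + 0.4 * sin(2 * pi * 2 * f0 * tt)) *
        exp(-25 * tt) * 0.3
      x <- c(x, tail)
    }
    pk <- max(abs(x))
    if (pk > 0) x <- x * (params$amplitude / pk)
    audioRecording(x, sampleRate)
  })
}

# ---- distractor sources ----------------------------------------------------

# steady mains-style hum: 120 Hz fundamental with harmonics + slow wobble
synthHum <- function(n, sr) {
  t <- (seq_len(n) - 1L) / sr
  wob <- 1 + 0.1 * sin(2 * pi * 0.3 * t + stats::runif(1, 0, 2 * pi))
  x <- (sin(2 * pi * 120 * t) + 0.5 * sin(2 * pi * 240 * t) +
        0.25 * sin(2 * pi * 360 * t)) * wob
  x / stats::sd(x)
}

# speech-like babble: few harmonic voices with drifting pitch, formant-band
# filtering and syllabic (~3-4 Hz) amplitude modulation
synthBabble <- function(n, sr, nVoices = 3L) {
  t <- (seq_len(n) - 1L) / sr
  x <- numeric(n)
  for (v in seq_len(nVoices)) {
    f0 <- stats::runif(1, 90, 220)
    drift <- 1 + 0.05 * sin(2 * pi * stats::runif(1, 0.2, 0.6) * t +
                            stats::runif(1, 0, 2 * pi))
    src <- sign(sin(2 * pi * f0 * drift * t)) +
      0.3 * sin(2 * pi * 2 * f0 * drift * t)
    band <- sort(stats::runif(2, 250, 2500))
    if (band[2] - band[1] < 200) band[2] <- band[1] + 200
    voiced <- fftBandpass(src, sr, band[1], band[2], transHz = 150)
    syl <- pmax(sin(2 * pi * stats::runif(1, 2.5, 4.5) * t +
                    stats::runif(1, 0, 2 * pi)), 0)
    x <- x + voiced * syl
  }
  s <- stats::sd(x)
  if (s > 0) x / s else x
}

# impulsive door slam: low-frequency thump (sharp attack, fast decay) with a
# resonant ring around 80-110 Hz
synthDoorSlam <- function(sr) {
  n <- round(0.25 * sr)
  t <- (seq_len(n) - 1L) / sr
  thump <- bandNoise(n, sr, 30, 350) * exp(-28 * t)
  ring <- sin(2 * pi * stats::runif(1, 80, 110) * t) * exp(-12 * t)
  x <- thump / max(abs(thump)) + 0.6 * ring
  x / max(abs(x))
}

# stationary-ish background bed from the requested distractor classes, plus a
# permanent low-level broadband noise floor; unit RMS
synthBed <- function(n, sr, distractors = c("babble", "hum")) {
  ar <- stats::filter(stats::rnorm(n), 0.95, method = "recursive")
  noise <- as.numeric(ar); noise <- noise / stats::sd(noise)
  x <- 0.35 * noise
  if ("hum" %in% distractors) x <- x + 1.0 * synthHum(n, sr)
  if ("babble" %in% distractors) x <- x + 1.0 * synthBabble(n, sr)
  x / stats::sd(x)
}

#' Specification of a labeled acoustic scene
#'
#' @param durationS scene duration, seconds.
#' @param nCoughs number of cough events to embed.
#' @param snrDb event signal-to-noise ratio: mean within-event cough power
#'   over background power, dB.
#' @param distractors character subset of c("babble", "hum", "door_slam").
#' @param seed RNG seed determining the whole scene.
#' @param slamsPerMinute rate of door-slam impulses when "door_slam" is
#'   among the distractors.
#' @param straddleSegments allow cough placement across 6-s segment
#'   boundaries (default keeps each cough inside one segment).
#' @return list with class "SceneSpec".
#' @export
sceneSpec <- function(durationS = 600, nCoughs = 30, snrDb = 10,
                      distractors = c("babble", "hum", "door_slam"),
                      seed = 1L, slamsPerMinute = 2,
                      straddleSegments = FALSE) {
  structure(list(durationS = durationS, nCoughs = nCoughs, snrDb = snrDb,
                 distractors = match.arg(distractors,
                                         c("babble", "hum", "door_slam"),
                                         several.ok = TRUE),
                 seed = seed, slamsPerMinute = slamsPerMinute,
                 straddleSegments = isTRUE(straddleSegments)),
            class = "SceneSpec")
}

sampleCoughParams <- function() {
  coughParams(burstDurationS = stats::runif(1, 0.05, 0.35),
              attackS = stats::runif(1, 0.005, 0.015),
              decayRate = stats::runif(1, 8, 25),
              bandLowHz = stats::runif(1, 250, 400),
              bandHighHz = stats::runif(1, 2200, 3200),
              voicedTail = stats::runif(1) < 0.3,
              amplitude = stats::runif(1, 0.6, 1.0))
}

#' Synthesise a labeled acoustic scene
#'
#' Builds a continuous background (requested distractor bed plus door-slam
#' impulses), embeds `nCoughs` non-overlapping cough bursts, and scales the
#' background so that mean within-event cough power over background power
#' equals `snrDb`. Returned labels are the exact placement intervals.
#'
#' @param spec a [sceneSpec()].
#' @param sampleRate sample rate, Hz.
#' @return list(recording = [AudioRecording-class], truth = data.frame with
#'   `start_s`, `end_s`, class "EventLabelSet" and attribute
#'   "totalDurationS").
#' @export
synthScene <- function(spec, sampleRate = 16000) {
  withLocalSeed(spec$seed, {
    sr <- sampleRate
    n <- round(spec$durationS * sr)

    bedClasses <- setdiff(spec$distractors, "door_slam")
    bg <- synthBed(n, sr, bedClasses)
    if ("door_slam" %in% spec$distractors) {
      nSlams <- stats::rpois(1, spec$slamsPerMinute * spec$durationS / 60)
      if (nSlams > 0) for (k in seq_len(nSlams)) {
        slam <- synthDoorSlam(sr) * stats::runif(1, 4, 7)
        at <- sample.int(max(n - length(slam), 1L), 1L)
        idx <- at:(at + length(slam) - 1L)
        bg[idx] <- bg[idx] + slam
      }
    }

    # non-overlapping cough placement
    coughTrack <- numeric(n)
    events <- data.frame(start_s = numeric(0), end_s = numeric(0))
    if (spec$nCoughs > 0) {
      segLen <- 6 * sr
      nSeg <- n %/% segLen
      if (!spec$straddleSegments && spec$nCoughs > nSeg)
        stop("cannot place ", spec$nCoughs,
             " coughs in distinct 6-s segments of a ", spec$durationS,
             " s scene")
      segPick <- if (!spec$straddleSegments)
        sample.int(nSeg, spec$nCoughs) else NULL
      placed <- matrix(numeric(0), 0, 2)
      for (k in seq_len(spec$nCoughs)) {
        cp <- sampleCoughParams()
        cough <- samples(synthCough(cp, sr, seed = NULL))
        len <- length(cough)
        for (try in 1:200) {
          a <- if (!spec$straddleSegments) {
            s0 <- (segPick[k] - 1L) * segLen
            margin <- segLen - len - round(0.2 * sr)
            if (margin < 1L) break
            s0 + round(0.1 * sr) + sample.int(margin, 1L)
          } else sample.int(n - len, 1L)
          b <- a + len - 1L
          gap <- 0.5 * sr     # keep events separated for unambiguous labels
          if (!any(placed[, 1] <= b + gap & placed[, 2] >= a - gap)) {
            coughTrack[a:b] <- coughTrack[a:b] + cough
            placed <- rbind(placed, c(a, b))
            events <- rbind(events,
                            data.frame(start_s = (a - 1L) / sr,
                                       end_s = b / sr))
            break
          }
          if (try == 200) stop("infeasible cough placement")
        }
      }
      if (nrow(events) < spec$nCoughs) stop("infeasible cough placement")
    }

    # scale background to the requested event SNR
    if (nrow(events) > 0) {
      support <- coughTrack != 0
      pCough <- mean(coughTrack[support]^2)
      pBg <- mean(bg^2)
      gain <- sqrt(pCough / (pBg * 10^(spec$snrDb / 10)))
      bg <- bg * gain
    } else {
      bg <- bg * 0.05 / stats::sd(bg)      # plain listening-level background
    }

    mix <- bg + coughTrack
    pk <- max(abs(mix))
    if (pk > 1) mix <- mix / pk            # common normalisation, SNR intact

    events <- events[order(events$start_s), , drop = FALSE]
    rownames(events) <- NULL
    class(events) <- c("EventLabelSet", "data.frame")
    attr(events, "totalDurationS") <- spec$durationS
    list(recording = audioRecording(mix, sr), truth = events)
  })
}

#' Generate a labeled training corpus of cough and background clips
#'
#' Cough clips are tightly trimmed bursts with 50 ms of background context
#' on each side, mixed with the background bed at the given SNR
#' (multi-condition training). Background clips cycle over the distractor
#' classes: the continuous babble+hum bed, bed + door slam, and low-level
#' quiet noise. Features are extracted per clip with the supplied
#' configuration.
#'
#' @param nCough,nBackground clip counts.
#' @param snrDb cough-clip mixing SNR, dB.
#' @param sampleRate sample rate, Hz.
#' @param seed RNG seed.
#' @param cfg a [featureConfig()].
#' @return list of lists (label, feats) where feats is a
#'   [FeatureVectorSequence-class]; background labels are "background",
#'   "slam" and "quiet".
#' @export
synthTrainingCorpus <- function(nCough = 200L, nBackground = 200L,
                                snrDb = 10, sampleRate = 16000, seed = 1L,
                                cfg = featureConfig()) {
  sr <- sampleRate
  withLocalSeed(seed, {
    pad <- round(0.05 * sr)
    coughs <- lapply(seq_len(nCough), function(i) {
      cp <- sampleCoughParams()
      cough <- samples(synthCough(cp, sr, seed = NULL))
      x <- c(numeric(pad), cough, numeric(pad))
      bed <- synthBed(length(x), sr, c("babble", "hum"))
      gain <- sqrt(mean(cough^2) / (mean(bed^2) * 10^(snrDb / 10)))
      clip <- x + bed * gain
      clip <- clip / max(abs(clip), 1)
      list(label = "cough", feats = featuresForSamples(clip, cfg))
    })
    bgClasses <- rep(c("background", "slam", "quiet"),
                     length.out = nBackground)
    bgs <- lapply(bgClasses, function(cl) {
      nclip <- round(1.0 * sr)
      x <- switch(cl,
        background = synthBed(nclip, sr, c("babble", "hum")),
        slam = {
          bed <- synthBed(nclip, sr, c("babble", "hum"))
          slam <- synthDoorSlam(sr) * stats::runif(1, 4, 7)
          at <- sample.int(nclip - length(slam), 1L)
          bed[at:(at + length(slam) - 1L)] <-
            bed[at:(at + length(slam) - 1L)] + slam
          bed
        },
        quiet = stats::rnorm(nclip) * 0.005)
      x <- x / max(abs(x), 4)
      list(label = cl, feats = featuresForSamples(x, cfg))
    })
    c(coughs, bgs)
  })
}

#' Train the default cough-spotting network on a synthetic corpus
#'
#' Trains one keyword model (5 states) on the cough clips and one 3-state
#' filler per background class, assembles the loop-grammar network, and —
#' unless a fixed `loopPenalty` is supplied — calibrates the model-insertion
#' penalty on seeded cough-free development audio drawn from the same
#' generators (see [calibrateLoopPenalty()]). Calibration fixes the
#' detector's operating point on the sensitivity/false-alarm trade without
#' ever touching evaluation material.
#'
#' @param corpus output of [synthTrainingCorpus()].
#' @param nStatesCough,nStatesFiller states for the keyword and filler
#'   models.
#' @param nMixCough mixtures per keyword-model state.
#' @param nMixFiller mixtures per filler state; fillers absorb heterogeneous
#'   background classes, so they get larger mixtures than the keyword model.
#' @param loopPenalty fixed network insertion penalty; NULL (default)
#'   calibrates it on development audio.
#' @param targetFpPerHour calibration target false-alarm rate.
#' @param seed training seed (also derives the development-audio seed).
#' @return A [RecognitionNetwork-class].
#' @export
trainNetwork <- function(corpus, nStatesCough = 5L, nStatesFiller = 3L,
                         nMixCough = 2L, nMixFiller = 6L,
                         loopPenalty = NULL,
                         targetFpPerHour = 1, seed = 1L) {
  labs <- vapply(corpus, `[[`, character(1), "label")
  models <- lapply(unique(labs), function(lb) {
    seqs <- lapply(corpus[labs == lb], `[[`, "feats")
    trainHmm(lb, seqs,
             nStates = if (lb == "cough") nStatesCough else nStatesFiller,
             nMix = if (lb == "cough") nMixCough else nMixFiller,
             seed = seed)
  })
  net <- recognitionNetwork(models, keyword = "cough", loopPenalty = 0)
  if (is.null(loopPenalty))
    net <- calibrateLoopPenalty(net, seed = seed + 1000L,
                                targetFpPerHour = targetFpPerHour)
  else net@loopPenalty <- loopPenalty
  net
}

#' Calibrate the network's insertion penalty on development audio
#'
#' Generates seeded cough-free development scenes (all distractor classes)
#' with the synthetic module, decodes them under a grid of insertion
#' penalties, and fixes the network's `loopPenalty` to the mildest value
#' whose development false-alarm rate does not exceed `targetFpPerHour`
#' (the most severe grid value if none qualifies). This is a standard
#' operating-point choice on development data; evaluation audio is never
#' consulted.
#'
#' @param net a [RecognitionNetwork-class] with trained models.
#' @param seed base seed for the development scenes (keep distinct from any
#'   evaluation seeds).
#' @param targetFpPerHour development false-alarm budget, events/hour.
#' @param nDevScenes number of development scenes.
#' @param devDurationS length of each development scene, seconds.
#' @param grid candidate penalties, mildest first.
#' @param cfg detection configuration used during calibration.
#' @return the network with `loopPenalty` set; attribute "calibration"
#'   holds the per-penalty development rates.
#' @export
calibrateLoopPenalty <- function(net, seed = 1001L, targetFpPerHour = 1,
                                 nDevScenes = 3L, devDurationS = 600,
                                 grid = c(0, -25, -50, -100, -150, -200,
                                          -250, -300, -350, -400, -450,
                                          -550),
                                 cfg = detectionConfig()) {
  segFeats <- unlist(lapply(seq_len(nDevScenes), function(i) {
    dev <- synthScene(sceneSpec(durationS = devDurationS, nCoughs = 0,
                                seed = seed + i - 1L))
    segmentFeatures(dev$recording, cfg)
  }), recursive = FALSE)
  rates <- vapply(grid, function(p) {
    net@loopPenalty <- p
    res <- decodeSegments(segFeats, net, cfg)
    nrow(collectEvents(res)) / (nDevScenes * devDurationS / 3600)
  }, numeric(1))
  ok <- which(rates <= targetFpPerHour)
  pick <- if (length(ok)) grid[ok[1L]] else grid[length(grid)]
  net@loopPenalty <- pick
  attr(net, "calibration") <- data.frame(penalty = grid, fp_per_hour = rates)
  net
}

#' Sample feature sequences from an HMM
#'
#' Draws sequences from the model's joint distribution by forward
#' simulation: enter at the entry distribution, follow transitions
#' (including the exit transition) until the model exits, emitting one
#' mixture draw per frame. Sequences still running after `maxLength` frames
#' are truncated there, so `maxLength` should comfortably exceed the
#' model's expected duration.
#'
#' @param model an [Hmm-class].
#' @param n number of sequences.
#' @param maxLength truncation length in frames.
#' @param seed RNG seed.
#' @return list of [FeatureVectorSequence-class] objects; attribute
#'   "statePaths" holds the generating state sequences.
#' @export
sampleHmmSequences <- function(model, n, maxLength, seed = 1L) {
  S <- model@nStates
  parts <- hmmLogParts(model)
  A <- exp(parts$logA)
  pExit <- exp(parts$logExit)
  D <- featureDim(model)
  withLocalSeed(seed, {
    paths <- vector("list", n)
    out <- lapply(seq_len(n), function(i) {
      st <- integer(0)
      cur <- sample.int(S, 1L, prob = exp(parts$logPi))
      for (t in seq_len(maxLength)) {
        st <- c(st, cur)
        p <- c(A[cur, ], pExit[cur])
        nxt <- sample.int(S + 1L, 1L, prob = p / sum(p))
        if (nxt == S + 1L) break
        cur <- nxt
      }
      X <- matrix(0, length(st), D)
      for (t in seq_along(st)) {
        e <- model@emissions[[st[t]]]
        m <- sample.int(length(e$weights), 1L, prob = e$weights)
        X[t, ] <- stats::rnorm(D, e$means[m, ], sqrt(e$variances[m, ]))
      }
      paths[[i]] <<- st
      new("FeatureVectorSequence", vectors = X,
          frameTimes = seq_along(st) - 1,
          configId = "sampled")
    })
    attr(out, "statePaths") <- paths
    out
  })
}

#' Synthesise a per-minute activity trace coupled to cough events
#'
#' Baseline low activity (mostly near zero, with random active bouts whose
#' frequency and size emulate ambulatory adolescent wear: overall mean below
#' 1 and SD near 3 on the 0-24 scale) plus `coupling` x (events in minute),
#' capped at 24.
#'
#' @param durationS trace duration, seconds (complete minutes are scored).
#' @param eventTimes cough event times, seconds from trace start.
#' @param coupling added score per cough in the minute (>= 0).
#' @param seed RNG seed.
#' @return data.frame with class "AccelerometerTrace" (scored mode):
#'   `minute_start_s`, `score`.
#' @export
synthAccel <- function(durationS, eventTimes = numeric(0), coupling = 0,
                       seed = 1L) {
  stopIfNot(all(eventTimes >= 0 & eventTimes <= durationS),
            "eventTimes must lie within the trace duration")
  nMin <- floor(durationS / 60)
  withLocalSeed(seed, {
    bout <- stats::runif(nMin) < 0.15
    base <- ifelse(bout, stats::rgamma(nMin, shape = 1.2, scale = 4),
                   abs(stats::rnorm(nMin, 0, 0.2)))
    perMin <- tabulate(pmin(floor(eventTimes / 60) + 1L, nMin), nMin)
    score <- pmin(base + coupling * perMin, 24)
    structure(data.frame(minute_start_s = (seq_len(nMin) - 1) * 60,
                         score = score),
              class = c("AccelerometerTrace", "data.frame"),
              mode = "scored")
  })
}

#' Synthesise acceptance-survey responses with controlled reliability
#'
#' Parallel-items model: each respondent's items share a latent score plus
#' item noise, discretised to the 1-5 response scale. The latent mixing
#' weight is calibrated (by numeric integration over the discretisation) so
#' the post-discretisation inter-item correlation matches `rho`, hence
#' Cronbach's alpha approaches k*rho / (1 + (k-1)*rho).
#'
#' @param n respondents.
#' @param k items (7 for the device's acceptance scale).
#' @param rho target inter-item correlation in \[0, 1).
#' @param seed RNG seed.
#' @return data.frame: `respondent_id`, `item1`..`itemk`, values in 1..5.
#' @export
synthSurvey <- function(n, k = 7L, rho = 0.33, seed = 1L) {
  stopIfNot(rho >= 0 && rho < 1, "rho must be in [0, 1)")
  disc <- function(z) pmin(5, pmax(1, round(3.8 + 1.1 * z)))
  # attenuation of Corr(z, disc(z)) for z ~ N(0,1), by fine-grid integration
  zg <- seq(-6, 6, by = 1e-3)
  w <- stats::dnorm(zg)
  s <- disc(zg)
  mS <- sum(s * w) / sum(w)
  a <- (sum(zg * s * w) / sum(w)) /
    sqrt((sum(s^2 * w) / sum(w) - mS^2) * 1)
  rhoLatent <- min(rho / a^2, 0.999)
  withLocalSeed(seed, {
    latent <- stats::rnorm(n)
    items <- vapply(seq_len(k), function(j) {
      z <- sqrt(rhoLatent) * latent +
        sqrt(1 - rhoLatent) * stats::rnorm(n)
      disc(z)
    }, numeric(n))
    df <- data.frame(respondent_id = seq_len(n), items)
    names(df) <- c("respondent_id", paste0("item", seq_len(k)))
    df
  })
}
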