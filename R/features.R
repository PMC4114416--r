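# Frame/segment arrangement and mel-cepstral feature extraction.
# Standard ASR front end: pre-emphasis, Hamming window, mel filterbank,
# DCT-II cepstra with c0 replaced by log-energy, deltas, optional per-segment
# cepstral mean normalisation.

#' Feature extraction configuration
#'
#' Fixes every knob of the acoustic front end so features are a deterministic
#' function of the audio. Defaults follow common speech-recognition practice:
#' 16 kHz working rate, 25 ms frames at 10 ms hop, 26 mel filters, 13 cepstra
#' (c0 replaced by frame log-energy) plus delta and delta-delta (D = 39),
#' pre-emphasis 0.97 and per-segment cepstral mean normalisation.
#'
#' @param sampleRate working sample rate, Hz.
#' @param frameS frame length, seconds.
#' @param hopS frame hop, seconds.
#' @param nMel number of mel filterbank channels.
#' @param nCepstra number of static coefficients (energy replaces c0).
#' @param useDeltas append delta and delta-delta coefficients.
#' @param preemphasis pre-emphasis coefficient in \[0, 1).
#' @param cmn subtract the per-sequence mean of each static coefficient.
#' @param energyFloor lower clamp applied to powers before taking logs, so
#'   silent frames stay finite.
#' @param deltaWindow half-width of the delta regression window, frames.
#' @return A list with class "FeatureConfig".
#' @export
featureConfig <- function(sampleRate = 16000, frameS = 0.025, hopS = 0.010,
                          nMel = 26L, nCepstra = 13L, useDeltas = TRUE,
                          preemphasis = 0.97, cmn = TRUE,
                          energyFloor = 1e-10, deltaWindow = 2L) {
  stopIfNot(frameS >= hopS && hopS > 0, "need frameS >= hopS > 0")
  cfg <- list(sampleRate = sampleRate, frameS = frameS, hopS = hopS,
              nMel = as.integer(nMel), nCepstra = as.integer(nCepstra),
              useDeltas = isTRUE(useDeltas), preemphasis = preemphasis,
              cmn = isTRUE(cmn), energyFloor = energyFloor,
              deltaWindow = as.integer(deltaWindow))
  cfg$id <- sprintf("mfcc%d_mel%d_%gms_%gms_pe%g_cmn%d_d%d",
                    cfg$nCepstra, cfg$nMel, frameS * 1000, hopS * 1000,
                    preemphasis, as.integer(cfg$cmn),
                    as.integer(cfg$useDeltas))
  class(cfg) <- "FeatureConfig"
  cfg
}

#' Arrange a recording into fixed-length frames
#'
#' Frame count obeys T = 1 + floor((N - L) / H) for N >= L samples (else 0);
#' the trailing partial frame is dropped. Consecutive frame starts differ by
#' exactly the hop.
#'
#' @param rec an [AudioRecording-class].
#' @param frameS frame length in seconds.
#' @param hopS hop in seconds (must satisfy frameS >= hopS > 0).
#' @return A list with class "FrameSequence": elements `frames` (T x L
#'   matrix), `frameLength`, `hop` (both in samples), `sampleRate`.
#' @export
frameSignal <- function(rec, frameS = 0.025, hopS = 0.010) {
  stopIfNot(frameS >= hopS && hopS > 0, "need frameS >= hopS > 0")
  x <- samples(rec)
  sr <- sampleRate(rec)
  L <- round(frameS * sr)
  H <- round(hopS * sr)
  N <- length(x)
  T_ <- if (N >= L) 1L + (N - L) %/% H else 0L
  frames <- if (T_ > 0L) {
    starts <- (seq_len(T_) - 1L) * H
    idx <- outer(starts, seq_len(L), `+`)
    matrix(x[idx], nrow = T_, ncol = L)
  } else matrix(numeric(0), 0L, L)
  structure(list(frames = frames, frameLength = L, hop = H,
                 sampleRate = sr), class = "FrameSequence")
}

#' Split a recording into consecutive fixed-duration segments
#'
#' Segments tile the recording in order without overlap; all but possibly the
#' last have exactly `segmentS` seconds (6 s default, the device's processing
#' block).
#'
#' @param rec an [AudioRecording-class].
#' @param segmentS segment duration, seconds.
#' @return data.frame-free list of segments; each has `index` (0-based),
#'   `startS`, `durationS` and `samples`.
#' @export
segmentStream <- function(rec, segmentS = 6.0) {
  stopIfNot(segmentS > 0, "segmentS must be positive")
  x <- samples(rec)
  sr <- sampleRate(rec)
  L <- round(segmentS * sr)
  n <- length(x)
  if (n == 0L) return(list())
  starts <- seq(1L, n, by = L)
  lapply(seq_along(starts), function(i) {
    a <- starts[i]
    b <- min(a + L - 1L, n)
    list(index = i - 1L, startS = (a - 1L) / sr,
         durationS = (b - a + 1L) / sr, samples = x[a:b])
  })
}

melScale <- function(f) 2595 * log10(1 + f / 700)
melInv <- function(m) 700 * (10^(m / 2595) - 1)

# triangular mel filterbank: nMel x (nfft/2 + 1)
melFilterbank <- function(nMel, nfft, sr, fLow = 0, fHigh = sr / 2) {
  pts <- melInv(seq(melScale(fLow), melScale(fHigh), length.out = nMel + 2L))
  bins <- floor((nfft + 1) * pts / sr)
  fb <- matrix(0, nMel, nfft %/% 2L + 1L)
  for (m in seq_len(nMel)) {
    lo <- bins[m]; ce <- bins[m + 1L]; hi <- bins[m + 2L]
    if (ce > lo) for (k in lo:ce)
      if (k >= 0 && k <= nfft %/% 2L) fb[m, k + 1L] <- (k - lo) / (ce - lo)
    if (hi > ce) for (k in ce:hi)
      if (k >= 0 && k <= nfft %/% 2L) fb[m, k + 1L] <- (hi - k) / (hi - ce)
  }
  fb
}

# orthogonal DCT-II matrix, nCep x nMel
dctMatrix <- function(nCep, nMel) {
  m <- outer(seq_len(nCep) - 1L, seq_len(nMel) - 0.5,
             function(i, j) cos(pi * i * j / nMel))
  m * sqrt(2 / nMel)
}

deltaCoeffs <- function(x, w) {
  # regression deltas with edge padding; x is T x D
  T_ <- nrow(x)
  if (T_ == 0L) return(x)
  denom <- 2 * sum((seq_len(w))^2)
  idx <- function(t) pmin(pmax(t, 1L), T_)
  out <- matrix(0, T_, ncol(x))
  for (n in seq_len(w)) {
    out <- out + n * (x[idx(seq_len(T_) + n), , drop = FALSE] -
                      x[idx(seq_len(T_) - n), , drop = FALSE])
  }
  out / denom
}

#' Compute per-frame mel-cepstral feature vectors
#'
#' Per frame: pre-emphasis, Hamming window, power spectrum, mel filterbank,
#' log (floored), DCT-II; coefficient 0 is replaced by the frame log-energy.
#' With `cmn`, the mean of each static coefficient over the sequence is
#' subtracted (applied per 6-s segment in the detection pipeline). With
#' `useDeltas`, delta and delta-delta coefficients are appended, giving
#' D = 3 * nCepstra.
#'
#' @param frames a "FrameSequence" from [frameSignal()].
#' @param cfg a [featureConfig()].
#' @return A [FeatureVectorSequence-class].
#' @export
computeFeatureVectors <- function(frames, cfg = featureConfig()) {
  fm <- frames$frames
  if (any(!is.finite(fm))) stop("non-finite samples in frames")
  T_ <- nrow(fm)
  L <- frames$frameLength
  D <- cfg$nCepstra * (if (cfg$useDeltas) 3L else 1L)
  if (T_ == 0L)
    return(new("FeatureVectorSequence",
               vectors = matrix(numeric(0), 0L, D),
               frameTimes = numeric(0), configId = cfg$id))

  # per-frame pre-emphasis (first sample scaled by 1 - k)
  if (cfg$preemphasis > 0) {
    pe <- cbind(fm[, 1L, drop = FALSE] * (1 - cfg$preemphasis),
                fm[, -1L, drop = FALSE] -
                  cfg$preemphasis * fm[, -L, drop = FALSE])
  } else pe <- fm

  logE <- log(pmax(rowSums(pe^2), cfg$energyFloor))

  win <- 0.54 - 0.46 * cos(2 * pi * (seq_len(L) - 1L) / (L - 1L))
  wfm <- sweep(pe, 2L, win, `*`)

  nfft <- 2^ceiling(log2(L))
  padded <- cbind(wfm, matrix(0, T_, nfft - L))
  spec <- stats::mvfft(t(padded))[seq_len(nfft %/% 2L + 1L), , drop = FALSE]
  pow <- (Mod(spec)^2) / nfft                      # (nfft/2+1) x T

  fb <- melFilterbank(cfg$nMel, nfft, frames$sampleRate)
  melE <- log(pmax(fb %*% pow, cfg$energyFloor))   # nMel x T
  cep <- t(dctMatrix(cfg$nCepstra, cfg$nMel) %*% melE)  # T x nCep
  cep[, 1L] <- logE

  if (cfg$cmn) cep <- sweep(cep, 2L, colMeans(cep), `-`)

  out <- cep
  if (cfg$useDeltas) {
    d1 <- deltaCoeffs(cep, cfg$deltaWindow)
    d2 <- deltaCoeffs(d1, cfg$deltaWindow)
    out <- cbind(cep, d1, d2)
  }
  colnames(out) <- c(paste0("c", seq_len(cfg$nCepstra) - 1L),
                     if (cfg$useDeltas)
                       c(paste0("d", seq_len(cfg$nCepstra) - 1L),
                         paste0("dd", seq_len(cfg$nCepstra) - 1L)))
  new("FeatureVectorSequence", vectors = out,
      frameTimes = (seq_len(T_) - 1L) * frames$hop / frames$sampleRate,
      configId = cfg$id)
}

#' Extract features for a raw sample vector (convenience)
#' @param x numeric samples.
#' @param cfg a [featureConfig()].
#' @return A [FeatureVectorSequence-class].
#' @export
featuresForSamples <- function(x, cfg = featureConfig()) {
  computeFeatureVectors(
    frameSignal(audioRecording(x, cfg$sampleRate), cfg$frameS, cfg$hopS), cfg)
}

#' Write a feature matrix as CSV (one frame per row, named coefficients)
#' @param feats a [FeatureVectorSequence-class].
#' @param path output CSV path.
#' @export
writeFeaturesCsv <- function(feats, path) {
  df <- data.frame(frame_time_s = frameTimes(feats),
                   featureMatrix(feats), check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
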