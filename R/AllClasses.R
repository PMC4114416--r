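#' @import methods
#' @importFrom Rcpp evalCpp
#' @useDynLib coughSpot, .registration = TRUE
NULL

#' AudioRecording: a sampled single-channel amplitude stream
#'
#' The raw monitoring signal: amplitudes normalised to \[-1, 1\], a sampling
#' rate in Hz, and an optional wall-clock start time (seconds since epoch)
#' used to anchor hourly aggregation to clock hours.
#'
#' @slot samples numeric vector of amplitudes in \[-1, 1\].
#' @slot sampleRate positive integer, samples per second.
#' @slot startTime numeric(1) seconds since epoch, or NA when unanchored.
#' @export
setClass("AudioRecording",
  representation(samples = "numeric", sampleRate = "numeric",
                 startTime = "numeric"),
  prototype(samples = numeric(0), sampleRate = 16000, startTime = NA_real_))

setValidity("AudioRecording", function(object) {
  msg <- NULL
  if (length(object@sampleRate) != 1L || object@sampleRate <= 0)
    msg <- c(msg, "sampleRate must be a single positive number")
  if (length(object@samples) && any(!is.finite(object@samples)))
    msg <- c(msg, "samples must all be finite")
  if (length(object@samples) &&
      max(abs(object@samples)) > 1 + 1e-9)
    msg <- c(msg, "samples must lie within [-1, 1]")
  if (is.null(msg)) TRUE else msg
})

#' Construct an AudioRecording
#'
#' @param samples numeric amplitudes; values outside \[-1, 1\] are an error.
#' @param sampleRate samples per second.
#' @param startTime optional recording start, seconds since epoch.
#' @return An [AudioRecording-class] object.
#' @examples
#' rec <- audioRecording(sin(2 * pi * 440 * (0:15999) / 16000), 16000)
#' duration(rec)
#' @export
audioRecording <- function(samples, sampleRate = 16000, startTime = NA_real_) {
  new("AudioRecording", samples = as.numeric(samples),
      sampleRate = as.numeric(sampleRate),
      startTime = as.numeric(startTime))
}

#' @describeIn audioRecording amplitude vector accessor
#' @param rec an AudioRecording.
#' @export
samples <- function(rec) rec@samples

#' @describeIn audioRecording sampling rate accessor (Hz)
#' @export
sampleRate <- function(rec) rec@sampleRate

#' @describeIn audioRecording start time accessor (seconds since epoch or NA)
#' @export
startTime <- function(rec) rec@startTime

#' @describeIn audioRecording duration in seconds
#' @export
duration <- function(rec) length(rec@samples) / rec@sampleRate

setMethod("show", "AudioRecording", function(object) {
  cat(sprintf("AudioRecording: %.3f s at %g Hz (%d samples)%s\n",
              duration(object), object@sampleRate, length(object@samples),
              if (is.na(object@startTime)) "" else
                sprintf(", starts %s",
                        format(as.POSIXct(object@startTime,
                                          origin = "1970-01-01", tz = "UTC")))))
})

#' FeatureVectorSequence: per-frame cepstral features
#'
#' A T x D matrix of descriptive feature vectors, one row per analysis frame,
#' together with frame-centre times and the identifier of the feature
#' configuration that produced it. All entries are finite; a corpus used to
#' train or decode one recognition network must share one D.
#'
#' @slot vectors numeric T x D matrix.
#' @slot frameTimes numeric length-T frame start times in seconds.
#' @slot configId character identifier of the producing configuration.
#' @export
setClass("FeatureVectorSequence",
  representation(vectors = "matrix", frameTimes = "numeric",
                 configId = "character"),
  prototype(vectors = matrix(numeric(0), 0, 0), frameTimes = numeric(0),
            configId = "unknown"))

setValidity("FeatureVectorSequence", function(object) {
  msg <- NULL
  if (nrow(object@vectors) != length(object@frameTimes))
    msg <- c(msg, "one frame time per feature vector required")
  if (length(object@vectors) && any(!is.finite(object@vectors)))
    msg <- c(msg, "feature vectors must be finite")
  if (is.null(msg)) TRUE else msg
})

#' @rdname FeatureVectorSequence-class
#' @param feats a FeatureVectorSequence.
#' @export
featureMatrix <- function(feats) feats@vectors

#' @rdname FeatureVectorSequence-class
#' @export
frameTimes <- function(feats) feats@frameTimes

#' @rdname FeatureVectorSequence-class
#' @export
nFrames <- function(feats) nrow(feats@vectors)

setMethod("show", "FeatureVectorSequence", function(object) {
  cat(sprintf("FeatureVectorSequence: %d frames x %d dims (config %s)\n",
              nrow(object@vectors), ncol(object@vectors), object@configId))
})

#' Hmm: a left-to-right hidden Markov model with GMM emissions
#'
#' One acoustic class (the cough keyword or a filler). Topology is
#' left-to-right with self-loops; the transition matrix includes entry and
#' exit pseudo-states (row/column 1 = entry, row/column nStates+2 = exit).
#' Each emitting state carries a diagonal-covariance Gaussian mixture.
#'
#' @slot label class name, e.g. "cough" or "background".
#' @slot nStates number of emitting states.
#' @slot logTrans (nStates+2) x (nStates+2) log transition matrix.
#' @slot emissions list of per-state lists with elements weights (length M),
#'   means (M x D) and variances (M x D).
#' @export
setClass("Hmm",
  representation(label = "character", nStates = "integer",
                 logTrans = "matrix", emissions = "list"))

setValidity("Hmm", function(object) {
  S <- object@nStates
  msg <- NULL
  if (nrow(object@logTrans) != S + 2L || ncol(object@logTrans) != S + 2L)
    msg <- c(msg, "logTrans must be (nStates+2) square")
  rs <- rowSums(exp(object@logTrans))
  if (any(abs(rs[seq_len(S + 1L)] - 1) > 1e-6))
    msg <- c(msg, "transition rows must sum to 1 over reachable successors")
  lower <- object@logTrans[lower.tri(object@logTrans)]
  if (any(is.finite(lower)))
    msg <- c(msg, "topology must be left-to-right (no backward transitions)")
  if (length(object@emissions) != S)
    msg <- c(msg, "one emission mixture per emitting state required")
  for (e in object@emissions) {
    if (abs(sum(e$weights) - 1) > 1e-8)
      msg <- c(msg, "mixture weights must sum to 1")
    if (any(e$variances <= 0))
      msg <- c(msg, "mixture variances must be positive")
  }
  if (is.null(msg)) TRUE else msg
})

#' @rdname Hmm-class
#' @param model an Hmm.
#' @export
hmmLabel <- function(model) model@label

#' @rdname Hmm-class
#' @export
nStates <- function(model) model@nStates

#' @rdname Hmm-class
#' @export
transitionMatrix <- function(model) exp(model@logTrans)

#' @rdname Hmm-class
#' @export
emissions <- function(model) model@emissions

#' @rdname Hmm-class
#' @export
featureDim <- function(model) ncol(model@emissions[[1L]]$means)

setMethod("show", "Hmm", function(object) {
  cat(sprintf("Hmm '%s': %d states, %d mixtures/state, dim %d\n",
              object@label, object@nStates,
              length(object@emissions[[1L]]$weights), featureDim(object)))
})

#' RecognitionNetwork: cough + filler models in a loop grammar
#'
#' A closed loop of HMMs for keyword spotting: any model may follow any model,
#' with an optional log-domain insertion penalty charged at each inter-model
#' transition. Exactly one model carries the keyword label; the remainder are
#' fillers absorbing non-target audio.
#'
#' @slot models list of [Hmm-class] objects.
#' @slot keyword label of the target (cough) model.
#' @slot loopPenalty log-domain model-insertion penalty (<= 0 typical).
#' @export
setClass("RecognitionNetwork",
  representation(models = "list", keyword = "character",
                 loopPenalty = "numeric"),
  prototype(loopPenalty = 0))

setValidity("RecognitionNetwork", function(object) {
  msg <- NULL
  labs <- vapply(object@models, hmmLabel, character(1))
  if (length(object@models) < 1L) msg <- c(msg, "at least one model required")
  if (sum(labs == object@keyword) != 1L)
    msg <- c(msg, "exactly one model must carry the keyword label")
  if (anyDuplicated(labs)) msg <- c(msg, "model labels must be unique")
  dims <- vapply(object@models, featureDim, numeric(1))
  if (length(unique(dims)) > 1L)
    msg <- c(msg, "all models must share one feature dimension")
  if (is.null(msg)) TRUE else msg
})

#' Build a recognition network from trained models
#'
#' @param models list of trained [Hmm-class] objects; exactly one must be the
#'   keyword (default label "cough"), the rest fillers.
#' @param keyword label of the target model.
#' @param loopPenalty log-domain penalty added to every inter-model
#'   transition; more negative values suppress model insertions, trading
#'   sensitivity against false positives. Default 0 (no penalty).
#' @return A [RecognitionNetwork-class].
#' @export
recognitionNetwork <- function(models, keyword = "cough", loopPenalty = 0) {
  new("RecognitionNetwork", models = models, keyword = keyword,
      loopPenalty = as.numeric(loopPenalty))
}

#' @rdname RecognitionNetwork-class
#' @param net a RecognitionNetwork.
#' @export
networkModels <- function(net) net@models

#' @rdname RecognitionNetwork-class
#' @export
keywordLabel <- function(net) net@keyword

setMethod("show", "RecognitionNetwork", function(object) {
  labs <- vapply(object@models, hmmLabel, character(1))
  cat(sprintf("RecognitionNetwork: keyword '%s' + fillers [%s], loop penalty %g\n",
              object@keyword,
              paste(setdiff(labs, object@keyword), collapse = ", "),
              object@loopPenalty))
})
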