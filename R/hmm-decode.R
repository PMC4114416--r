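# Viterbi alignment against one model and token-passing decoding over the
# composed loop-grammar network.

#' Align a feature sequence against a single HMM
#'
#' Returns the maximum-probability state path (1-based emitting-state
#' indices) and its joint log score, including entry and exit transition
#' terms. Exact score ties are broken toward the lowest state index.
#'
#' @param model a trained [Hmm-class].
#' @param feats a [FeatureVectorSequence-class] or T x D matrix whose D
#'   matches the model.
#' @return list(path = integer(T), score = numeric(1)).
#' @export
viterbiAlign <- function(model, feats) {
  X <- if (is(feats, "FeatureVectorSequence")) featureMatrix(feats) else feats
  if (ncol(X) != featureDim(model))
    stop("feature dimension ", ncol(X), " does not match model dimension ",
         featureDim(model))
  parts <- hmmLogParts(model)
  logB <- emissionLogLik(model, X)
  v <- viterbi_c(logB, parts$logPi, parts$logA, parts$logExit, Inf)
  list(path = as.integer(v$path), score = v$score)
}

# Compose the loop grammar into one flat state space.
# Returns logPi/logA/logExit over all emitting states of all models, the
# owning model index of each composed state, and a boundary flag matrix
# marking transitions realised as exit -> (loop penalty) -> re-entry.
composeNetwork <- function(net) {
  models <- net@models
  parts <- lapply(models, hmmLogParts)
  sizes <- vapply(models, nStates, integer(1))
  off <- c(0L, cumsum(sizes))
  K <- sum(sizes)
  logPi <- rep(-Inf, K)
  logExit <- rep(-Inf, K)
  logA <- matrix(-Inf, K, K)
  owner <- integer(K)
  for (i in seq_along(models)) {
    idx <- (off[i] + 1L):off[i + 1L]
    owner[idx] <- i
    logPi[idx] <- parts[[i]]$logPi
    logExit[idx] <- parts[[i]]$logExit
    logA[idx, idx] <- parts[[i]]$logA
  }
  cross <- outer(logExit + net@loopPenalty, logPi, `+`)
  boundary <- cross > logA          # ties prefer the within-model transition
  list(logPi = logPi, logA = pmax(logA, cross), logExit = logExit,
       owner = owner, boundary = boundary, offsets = off)
}

#' Decode a feature sequence with the token-passing network decoder
#'
#' Finds the best-scoring segmentation of the frames into model-labeled
#' spans under the loop grammar: tokens propagate through each model's
#' states and, on model exit, re-enter any model's entry state paying the
#' network's `loopPenalty`. With `beam = Inf` decoding is exact (full
#' Viterbi over the composed network); a finite beam prunes states scoring
#' more than `beam` below the per-frame best.
#'
#' @param net a [RecognitionNetwork-class].
#' @param feats a [FeatureVectorSequence-class] or T x D matrix.
#' @param beam log-domain beam width; Inf (default) disables pruning.
#' @return A data.frame with class "DecodedPath": one row per span with
#'   columns `label`, `firstFrame`, `lastFrame` (1-based, inclusive) and
#'   `logScore` (the span's share of emission+transition score); attribute
#'   "totalLogScore" carries the joint path score. Zero frames decode to a
#'   zero-row path.
#' @export
decodeTokenPassing <- function(net, feats, beam = Inf) {
  X <- if (is(feats, "FeatureVectorSequence")) featureMatrix(feats) else feats
  if (length(net@models) == 0L) stop("network has no models")
  dims <- featureDim(net@models[[1L]])
  if (ncol(X) != dims && nrow(X) > 0L)
    stop("feature dimension mismatch with network models")
  labs <- vapply(net@models, hmmLabel, character(1))
  if (nrow(X) == 0L) {
    out <- data.frame(label = character(0), firstFrame = integer(0),
                      lastFrame = integer(0), logScore = numeric(0))
    class(out) <- c("DecodedPath", "data.frame")
    attr(out, "totalLogScore") <- -Inf
    return(out)
  }

  comp <- composeNetwork(net)
  logB <- do.call(cbind, lapply(net@models, function(m) emissionLogLik(m, X)))
  v <- viterbi_c(logB, comp$logPi, comp$logA, comp$logExit, beam)
  path <- as.integer(v$path)
  T_ <- length(path)

  # span boundaries: frame t starts a new span when the realised transition
  # from path[t-1] crossed a model boundary
  newSpan <- c(TRUE, vapply(seq_len(T_ - 1L) + 1L, function(t) {
    comp$boundary[path[t - 1L], path[t]] ||
      comp$owner[path[t - 1L]] != comp$owner[path[t]]
  }, logical(1)))
  spanId <- cumsum(newSpan)
  first <- which(newSpan)
  last <- c(first[-1L] - 1L, T_)

  # per-span share of the total score: emissions within span + transitions
  frameScore <- logB[cbind(seq_len(T_), path)]
  trans <- if (T_ > 1L)
    comp$logA[cbind(path[-T_], path[-1L])] else numeric(0)
  spanScore <- rowsum(frameScore, spanId)[, 1L] +
    rowsum(c(trans, 0)[seq_len(T_)], spanId)[, 1L]

  out <- data.frame(label = labs[comp$owner[path[first]]],
                    firstFrame = first, lastFrame = last,
                    logScore = as.numeric(spanScore))
  class(out) <- c("DecodedPath", "data.frame")
  attr(out, "totalLogScore") <- v$score
  attr(out, "statePath") <- path
  out
}
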