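# Baum-Welch (EM) training of left-to-right HMMs with diagonal-covariance
# Gaussian mixture emissions. All probability arithmetic is in the log
# domain; lattice recursions run in compiled code.

asFeatureList <- function(sequences) {
  lapply(sequences, function(s) {
    if (is(s, "FeatureVectorSequence")) featureMatrix(s)
    else if (is.matrix(s)) s
    else stop("sequences must be FeatureVectorSequence objects or matrices")
  })
}

# log N(x | mu, diag(var)) for all frames x all components.
# X: N x D; means, vars: K x D. Returns N x K.
componentLogDens <- function(X, means, vars) {
  D <- ncol(X)
  iv <- t(1 / vars)                          # D x K
  const <- -0.5 * (D * log(2 * pi) + rowSums(log(vars)))  # K
  q <- X^2 %*% iv - 2 * (X %*% t(means / vars))
  q <- sweep(q, 2L, rowSums(means^2 / vars), `+`)
  sweep(-0.5 * q, 2L, const, `+`)
}

# per-state emission log-likelihoods from stacked component densities.
# logDens: N x (S*M) ordered state-major; logW: length S*M. Returns N x S
# plus the posterior pieces needed for the M step.
stateLogLik <- function(logDens, logW, S, M) {
  lw <- sweep(logDens, 2L, logW, `+`)
  logB <- matrix(0, nrow(logDens), S)
  for (s in seq_len(S)) {
    cols <- ((s - 1L) * M + 1L):(s * M)
    block <- lw[, cols, drop = FALSE]
    if (M == 1L) logB[, s] <- block
    else {
      mx <- do.call(pmax, c(as.data.frame(block), list(-Inf)))
      logB[, s] <- mx + log(rowSums(exp(block - mx)))
    }
  }
  list(logB = logB, logWeighted = lw)
}

hmmLogParts <- function(model) {
  S <- model@nStates
  lt <- model@logTrans
  list(logPi = lt[1L, 2L:(S + 1L)],
       logA = lt[2L:(S + 1L), 2L:(S + 1L), drop = FALSE],
       logExit = lt[2L:(S + 1L), S + 2L])
}

stackEmissions <- function(model) {
  em <- model@emissions
  list(means = do.call(rbind, lapply(em, `[[`, "means")),
       vars = do.call(rbind, lapply(em, `[[`, "variances")),
       logW = log(unlist(lapply(em, `[[`, "weights"))))
}

# emission log-likelihood matrix for one model: T x S
emissionLogLik <- function(model, X) {
  S <- model@nStates
  M <- length(model@emissions[[1L]]$weights)
  st <- stackEmissions(model)
  stateLogLik(componentLogDens(X, st$means, st$vars), st$logW, S, M)$logB
}

initHmm <- function(label, mats, nStates, nMix, varFloor, seed) {
  D <- ncol(mats[[1L]])
  # uniform segmentation of each sequence across states
  assign_state <- function(Ti) pmin(nStates,
                                    ((seq_len(Ti) - 1L) * nStates) %/% Ti + 1L)
  states <- unlist(lapply(mats, function(m) assign_state(nrow(m))))
  X <- do.call(rbind, mats)
  mlVar <- function(m) pmax(colMeans(m^2) - colMeans(m)^2, 0)
  globalVar <- pmax(mlVar(X), varFloor)
  emissions <- lapply(seq_len(nStates), function(s) {
    Xs <- X[states == s, , drop = FALSE]
    if (nMix == 1L || nrow(Xs) < nMix * 2L) {
      mu <- matrix(colMeans(Xs), nMix, D, byrow = TRUE)
      if (nMix > 1L)  # tiny deterministic perturbation to break symmetry
        mu <- mu + outer(seq_len(nMix) - (nMix + 1) / 2,
                         sqrt(globalVar) * 0.1)
      v <- matrix(pmax(mlVar(Xs), varFloor), nMix, D, byrow = TRUE)
      v[!is.finite(v)] <- varFloor
      list(weights = rep(1 / nMix, nMix), means = mu, variances = v)
    } else {
      # deterministic k-means: seed centers at quantile bins along the
      # highest-variance dimension, then Lloyd iterations; ML moments and
      # inverse-ECDF quantiles keep the whole initialisation invariant to
      # duplicating the corpus
      dMax <- which.max(mlVar(Xs))
      br <- stats::quantile(Xs[, dMax], probs = seq(0, 1, 1 / nMix),
                            names = FALSE, type = 1)
      bin <- findInterval(Xs[, dMax], br[-c(1L, nMix + 1L)]) + 1L
      centers0 <- t(vapply(seq_len(nMix), function(k) {
        if (any(bin == k)) colMeans(Xs[bin == k, , drop = FALSE])
        else colMeans(Xs) + (k - (nMix + 1) / 2) * 0.1 * sqrt(globalVar)
      }, numeric(D)))
      if (anyDuplicated(centers0))
        centers0 <- centers0 + outer(seq_len(nMix) - (nMix + 1) / 2,
                                     1e-6 * sqrt(globalVar))
      km <- tryCatch(
        suppressWarnings(stats::kmeans(Xs, centers = centers0,
                                       iter.max = 25L,
                                       algorithm = "Lloyd")),
        error = function(e)        # empty cluster: keep the seed partition
          list(cluster = bin, centers = centers0))
      v <- t(vapply(seq_len(nMix), function(k) {
        xs <- Xs[km$cluster == k, , drop = FALSE]
        vv <- if (nrow(xs) > 1L) mlVar(xs) else globalVar
        pmax(ifelse(is.finite(vv) & vv > 0, vv, globalVar), varFloor)
      }, numeric(D)))
      w <- pmax(tabulate(km$cluster, nMix), 1) |> (\(z) z / sum(z))()
      list(weights = w, means = km$centers, variances = v)
    }
  })
  meanT <- mean(vapply(mats, nrow, numeric(1)))
  dwell <- max(meanT / nStates, 1.25)
  lt <- matrix(-Inf, nStates + 2L, nStates + 2L)
  lt[1L, 2L] <- 0                                      # entry -> state 1
  for (s in seq_len(nStates)) {
    stay <- 1 - 1 / dwell
    lt[s + 1L, s + 1L] <- log(stay)
    lt[s + 1L, s + 2L] <- log(1 - stay)                # next state or exit
  }
  lt[nStates + 2L, nStates + 2L] <- 0                  # absorbing exit
  new("Hmm", label = label, nStates = as.integer(nStates),
      logTrans = lt, emissions = emissions)
}

#' Train an HMM on labeled feature sequences with Baum-Welch
#'
#' Fits a left-to-right HMM (self-loops, entry at state 1, exit from the last
#' state) with diagonal-covariance Gaussian mixture emissions by
#' expectation-maximisation. Initialisation segments each sequence uniformly
#' across states and splits each state's pooled frames into mixtures by
#' deterministic quantile-seeded k-means, so the whole fit is reproducible
#' and invariant to duplicating the corpus. Per-iteration total
#' log-likelihood is non-decreasing; training stops when the relative
#' improvement drops below `tol` or after `maxIter` iterations.
#'
#' @param label class name stored on the model (e.g. "cough").
#' @param sequences list of [FeatureVectorSequence-class] objects or T x D
#'   matrices; every sequence needs at least `nStates` frames.
#' @param nStates number of emitting states.
#' @param nMix Gaussian mixture components per state.
#' @param tol relative log-likelihood improvement at which EM stops.
#' @param maxIter maximum EM iterations.
#' @param varFloor lower bound applied to every fitted variance.
#' @param seed accepted for interface stability; the fit is deterministic.
#' @return A trained [Hmm-class]; attribute "loglik" holds the per-iteration
#'   total log-likelihood trace.
#' @examples
#' set.seed(1)
#' seqs <- replicate(5, matrix(rnorm(60), 20, 3), simplify = FALSE)
#' m <- trainHmm("background", seqs, nStates = 2, nMix = 1)
#' @export
trainHmm <- function(label, sequences, nStates = 5L, nMix = 2L, tol = 1e-5,
                     maxIter = 25L, varFloor = 1e-3, seed = 1L) {
  mats <- asFeatureList(sequences)
  stopIfNot(length(mats) >= 1L, "need at least one training sequence")
  stopIfNot(nMix >= 1L, "nMix must be >= 1")
  lens <- vapply(mats, nrow, numeric(1))
  if (any(lens < nStates))
    stop("every sequence needs at least nStates = ", nStates, " frames; ",
         sum(lens < nStates), " too short")

  S <- as.integer(nStates); M <- as.integer(nMix)
  model <- initHmm(label, mats, S, M, varFloor, seed)
  X <- do.call(rbind, mats)
  D <- ncol(X)
  offsets <- c(0L, cumsum(lens))
  llTrace <- numeric(0)
  llPrev <- -Inf

  for (iter in seq_len(maxIter)) {
    st <- stackEmissions(model)
    parts <- hmmLogParts(model)
    logDens <- componentLogDens(X, st$means, st$vars)
    sl <- stateLogLik(logDens, st$logW, S, M)

    ll <- 0
    xiSum <- matrix(0, S, S)
    exitSum <- numeric(S)
    gammaAll <- matrix(-Inf, nrow(X), S)
    for (i in seq_along(mats)) {
      rows <- (offsets[i] + 1L):offsets[i + 1L]
      fb <- forward_backward_c(sl$logB[rows, , drop = FALSE], parts$logPi,
                               parts$logA, parts$logExit)
      if (!is.finite(fb$loglik))
        stop("EM divergence: non-finite likelihood at iteration ", iter)
      ll <- ll + fb$loglik
      xiSum <- xiSum + fb$xi
      exitSum <- exitSum + fb$exit
      gammaAll[rows, ] <- fb$loggamma
    }
    llTrace <- c(llTrace, ll)
    if (ll < llPrev - 1e-6 * abs(llPrev))
      stop("EM divergence: log-likelihood decreased at iteration ", iter)

    # component responsibilities r[t, k] (state-major component order)
    srep <- rep(seq_len(S), each = M)
    r <- exp(sl$logWeighted + gammaAll[, srep, drop = FALSE] -
             sl$logB[, srep, drop = FALSE])
    r[!is.finite(r)] <- 0
    occK <- colSums(r)                               # K
    occS <- rowsum(occK, srep)[, 1L]                 # S

    muNew <- (t(r) %*% X) / pmax(occK, 1e-300)
    vNew <- (t(r) %*% X^2) / pmax(occK, 1e-300) - muNew^2
    vNew <- pmax(vNew, varFloor)
    wNew <- pmax(occK, 1e-10) / rep(pmax(occS, 1e-300), each = M)
    wNew <- unlist(lapply(seq_len(S), function(s) {
      w <- wNew[((s - 1L) * M + 1L):(s * M)]; w / sum(w)
    }))

    model@emissions <- lapply(seq_len(S), function(s) {
      k <- ((s - 1L) * M + 1L):(s * M)
      list(weights = wNew[k], means = muNew[k, , drop = FALSE],
           variances = vNew[k, , drop = FALSE])
    })

    lt <- matrix(-Inf, S + 2L, S + 2L)
    lt[1L, 2L] <- 0
    for (s in seq_len(S)) {
      denom <- sum(xiSum[s, ]) + exitSum[s]
      if (denom <= 0) {                     # unvisited state: keep alive
        lt[s + 1L, s + 1L] <- log(0.5)
        lt[s + 1L, s + 2L] <- log(0.5)
      } else {
        probs <- c(xiSum[s, ], exitSum[s])[c(s, s + 1L)] / denom
        probs <- pmax(probs, 1e-12); probs <- probs / sum(probs)
        lt[s + 1L, s + 1L] <- log(probs[1L])
        lt[s + 1L, s + 2L] <- log(probs[2L])
      }
    }
    lt[S + 2L, S + 2L] <- 0
    model@logTrans <- lt

    if (is.finite(llPrev) && (ll - llPrev) < tol * abs(llPrev)) {
      llPrev <- ll
      break
    }
    llPrev <- ll
  }
  attr(model, "loglik") <- llTrace
  validObject(model)
  model
}
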