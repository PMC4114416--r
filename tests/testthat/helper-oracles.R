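# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: naive per-frame DFT cepstra, exhaustive path
# enumeration for Viterbi and the loop-grammar decoder, brute-force bipartite
# matching, and the textbook two-pass Pearson formula.

# ---- naive mel-cepstrum reference (per-frame loops, direct DFT) -----------

naiveMfcc <- function(frames, sr, nMel = 26, nCep = 13, preemph = 0.97,
                      energyFloor = 1e-10) {
  L <- ncol(frames)
  nfft <- 2^ceiling(log2(L))
  dft <- exp(-2i * pi * outer(0:(nfft - 1), 0:(nfft - 1)) / nfft)
  mel <- function(f) 2595 * log10(1 + f / 700)
  imel <- function(m) 700 * (10^(m / 2595) - 1)
  pts <- imel(seq(mel(0), mel(sr / 2), length.out = nMel + 2))
  bins <- floor((nfft + 1) * pts / sr)
  ham <- 0.54 - 0.46 * cos(2 * pi * (0:(L - 1)) / (L - 1))
  out <- matrix(0, nrow(frames), nCep)
  for (t in seq_len(nrow(frames))) {
    x <- frames[t, ]
    x <- c(x[1] * (1 - preemph), x[-1] - preemph * x[-L])
    logE <- log(max(sum(x^2), energyFloor))
    xw <- c(x * ham, rep(0, nfft - L))
    X <- as.vector(dft %*% xw)
    p <- (Mod(X)^2 / nfft)[1:(nfft / 2 + 1)]
    fbE <- numeric(nMel)
    for (m in 1:nMel) {
      lo <- bins[m]; ce <- bins[m + 1]; hi <- bins[m + 2]
      acc <- 0
      for (k in lo:hi) {
        if (k < 0 || k > nfft / 2) next
        w <- if (k <= ce) {
          if (ce > lo) (k - lo) / (ce - lo) else 0
        } else {
          if (hi > ce) (hi - k) / (hi - ce) else 0
        }
        acc <- acc + w * p[k + 1]
      }
      fbE[m] <- log(max(acc, energyFloor))
    }
    cep <- numeric(nCep)
    for (i in 0:(nCep - 1))
      cep[i + 1] <- sqrt(2 / nMel) *
        sum(fbE * cos(pi * i * ((1:nMel) - 0.5) / nMel))
    cep[1] <- logE
    out[t, ] <- cep
  }
  out
}

# ---- random left-to-right test models -------------------------------------

randomHmm <- function(label, S, D, M = 1L, seed = 1) {
  set.seed(seed)
  lt <- matrix(-Inf, S + 2, S + 2)
  lt[1, 2] <- 0
  for (s in seq_len(S)) {
    stay <- stats::runif(1, 0.3, 0.9)
    lt[s + 1, s + 1] <- log(stay)
    lt[s + 1, s + 2] <- log(1 - stay)
  }
  lt[S + 2, S + 2] <- 0
  em <- lapply(seq_len(S), function(s) {
    w <- stats::runif(M); w <- w / sum(w)
    list(weights = w,
         means = matrix(stats::rnorm(M * D, sd = 2), M, D),
         variances = matrix(stats::runif(M * D, 0.5, 1.5), M, D))
  })
  new("Hmm", label = label, nStates = as.integer(S), logTrans = lt,
      emissions = em)
}

# ---- exhaustive Viterbi over a single left-to-right model -----------------

hmmGaussLogLik <- function(model, x, s) {
  e <- coughSpot::emissions(model)[[s]]
  M <- length(e$weights)
  comp <- vapply(seq_len(M), function(m)
    log(e$weights[m]) + sum(stats::dnorm(x, e$means[m, ],
                                         sqrt(e$variances[m, ]),
                                         log = TRUE)), numeric(1))
  mx <- max(comp)
  mx + log(sum(exp(comp - mx)))
}

enumerateAlign <- function(model, X) {
  S <- coughSpot::nStates(model)
  lt <- log(coughSpot::transitionMatrix(model))
  T_ <- nrow(X)
  best <- -Inf; bestPath <- NULL
  paths <- expand.grid(rep(list(seq_len(S)), T_))
  for (r in seq_len(nrow(paths))) {
    st <- as.integer(paths[r, ])
    sc <- lt[1, st[1] + 1] + hmmGaussLogLik(model, X[1, ], st[1])
    if (T_ > 1) for (t in 2:T_) {
      sc <- sc + lt[st[t - 1] + 1, st[t] + 1] +
        hmmGaussLogLik(model, X[t, ], st[t])
      if (sc == -Inf) break
    }
    sc <- sc + lt[st[T_] + 1, S + 2]
    if (sc > best) { best <- sc; bestPath <- st }
  }
  list(path = bestPath, score = best)
}

# ---- exhaustive decoding over the composed loop grammar -------------------
# enumerate every frame-level assignment of (model, state) and keep legal
# ones: within-model left-to-right steps, or exit -> penalty -> entry.

enumerateDecode <- function(net, X) {
  models <- coughSpot::networkModels(net)
  nm <- length(models)
  penalty <- net@loopPenalty
  combos <- do.call(rbind, lapply(seq_len(nm), function(i)
    cbind(i, seq_len(coughSpot::nStates(models[[i]])))))
  K <- nrow(combos)
  lts <- lapply(models, function(m) log(coughSpot::transitionMatrix(m)))
  T_ <- nrow(X)
  emis <- matrix(0, T_, K)
  for (k in seq_len(K))
    for (t in seq_len(T_))
      emis[t, k] <- hmmGaussLogLik(models[[combos[k, 1]]], X[t, ],
                                   combos[k, 2])
  step <- matrix(-Inf, K, K)
  for (a in seq_len(K)) for (b in seq_len(K)) {
    ia <- combos[a, 1]; sa <- combos[a, 2]
    ib <- combos[b, 1]; sb <- combos[b, 2]
    within <- if (ia == ib) lts[[ia]][sa + 1, sb + 1] else -Inf
    Sa <- coughSpot::nStates(models[[ia]])
    cross <- lts[[ia]][sa + 1, Sa + 2] + penalty + lts[[ib]][1, sb + 1]
    step[a, b] <- max(within, cross)
  }
  entry <- vapply(seq_len(K), function(k)
    lts[[combos[k, 1]]][1, combos[k, 2] + 1], numeric(1))
  exitv <- vapply(seq_len(K), function(k) {
    Sk <- coughSpot::nStates(models[[combos[k, 1]]])
    lts[[combos[k, 1]]][combos[k, 2] + 1, Sk + 2]
  }, numeric(1))
  paths <- expand.grid(rep(list(seq_len(K)), T_))
  best <- -Inf; bestStates <- NULL
  for (r in seq_len(nrow(paths))) {
    st <- as.integer(paths[r, ])
    sc <- entry[st[1]] + emis[1, st[1]]
    if (T_ > 1) for (t in 2:T_) {
      sc <- sc + step[st[t - 1], st[t]] + emis[t, st[t]]
      if (sc == -Inf) break
    }
    sc <- sc + exitv[st[T_]]
    if (sc > best) { best <- sc; bestStates <- st }
  }
  list(score = best, modelSeq = combos[bestStates, 1])
}

# ---- maximum bipartite matching by brute force ----------------------------

maxMatchingSize <- function(dm, tm, tol) {
  n <- length(dm)
  if (n == 0 || length(tm) == 0) return(0L)
  adj <- lapply(seq_len(n), function(i) which(abs(tm - dm[i]) <= tol))
  best <- 0L
  rec <- function(i, used, cnt) {
    if (cnt + (n - i + 1) <= best) return()
    if (i > n) { best <<- max(best, cnt); return() }
    rec(i + 1L, used, cnt)
    for (j in adj[[i]]) if (!used[j]) {
      used[j] <- TRUE
      rec(i + 1L, used, cnt + 1L)
      used[j] <- FALSE
    }
  }
  rec(1L, logical(length(tm)), 0L)
  best
}

# ---- textbook two-pass Pearson r ------------------------------------------

twoPassPearson <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# ---- small shared trained network (memoised across test files) ------------

.netCache <- new.env(parent = emptyenv())

smallNetwork <- function() {
  if (is.null(.netCache$net)) {
    corpus <- synthTrainingCorpus(nCough = 60, nBackground = 60, seed = 77)
    net <- trainNetwork(corpus, seed = 1, loopPenalty = 0)
    .netCache$net <- calibrateLoopPenalty(net, seed = 1001L,
                                          nDevScenes = 1L,
                                          devDurationS = 360)
  }
  .netCache$net
}

benchmarkNetwork <- function() {
  if (is.null(.netCache$bench)) {
    corpus <- synthTrainingCorpus(nCough = 200, nBackground = 200,
                                  seed = 101)
    .netCache$bench <- trainNetwork(corpus, seed = 1)
  }
  .netCache$bench
}
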