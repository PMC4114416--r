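# Training (Baum-Welch) and decoding (single-model Viterbi, token-passing
# network decoding), checked against closed forms and exhaustive enumeration.

test_that("one state, one mixture: M-step gives pooled mean and variance", {
  set.seed(3)
  seqs <- replicate(4, matrix(stats::rnorm(30, 2, 1.5), 10, 3),
                    simplify = FALSE)
  m <- trainHmm("x", seqs, nStates = 1, nMix = 1, maxIter = 3)
  X <- do.call(rbind, seqs)
  e <- emissions(m)[[1]]
  expect_equal(as.numeric(e$means), colMeans(X), tolerance = 1e-8)
  # ML (biased) variance, floored
  vML <- colMeans(sweep(X, 2, colMeans(X))^2)
  expect_equal(as.numeric(e$variances), pmax(vML, 1e-3), tolerance = 1e-8)
})

test_that("training is deterministic for a fixed seed", {
  set.seed(11)
  seqs <- replicate(6, matrix(stats::rnorm(80), 20, 4), simplify = FALSE)
  m1 <- trainHmm("x", seqs, nStates = 3, nMix = 2, seed = 5)
  m2 <- trainHmm("x", seqs, nStates = 3, nMix = 2, seed = 5)
  expect_identical(m1@logTrans, m2@logTrans)
  expect_identical(emissions(m1), emissions(m2))
})

test_that("sequences shorter than nStates are rejected", {
  expect_error(trainHmm("x", list(matrix(0, 2, 3)), nStates = 3),
               "at least nStates")
})

test_that("EM log-likelihood is monotone and variances respect the floor", {
  set.seed(21)
  for (rep in 1:3) {
    seqs <- replicate(8, matrix(stats::rnorm(60, sd = runif(1, 0.5, 2)),
                                15, 4), simplify = FALSE)
    m <- trainHmm("x", seqs, nStates = 3, nMix = 2, maxIter = 15,
                  varFloor = 1e-3, seed = rep)
    ll <- attr(m, "loglik")
    expect_true(all(diff(ll) >= -1e-6 * abs(ll[-length(ll)])))
    for (e in emissions(m)) expect_true(all(e$variances >= 1e-3))
  }
})

test_that("1-state alignment is the sum of frame log-likelihoods", {
  m <- randomHmm("x", 1, 3, seed = 2)
  X <- matrix(stats::rnorm(15), 5, 3)
  v <- viterbiAlign(m, X)
  expect_equal(v$path, rep(1L, 5))
  lt <- log(transitionMatrix(m))
  manual <- lt[1, 2] + sum(vapply(1:5, function(t)
    hmmGaussLogLik(m, X[t, ], 1L), numeric(1))) +
    4 * lt[2, 2] + lt[2, 3]
  expect_equal(v$score, manual, tolerance = 1e-9)
})

test_that("Viterbi matches exhaustive path enumeration on small instances", {
  set.seed(31)
  for (rep in 1:8) {
    S <- sample(2:3, 1)
    T_ <- sample(S:6, 1)
    m <- randomHmm("x", S, 2, M = sample(1:2, 1), seed = 100 + rep)
    X <- matrix(stats::rnorm(T_ * 2, sd = 2), T_, 2)
    v <- viterbiAlign(m, X)
    o <- enumerateAlign(m, X)
    expect_equal(v$score, o$score, tolerance = 1e-9)
    expect_equal(v$path, o$path)
  }
})

test_that("adding a constant per-frame log-likelihood shifts the score by T*c", {
  set.seed(13)
  T_ <- 7; S <- 3
  logB <- matrix(stats::rnorm(T_ * S), T_, S)
  logPi <- log(c(1, 0, 0))
  logA <- log(matrix(c(0.6, 0.4, 0,
                       0, 0.7, 0.3,
                       0, 0, 0.8), S, S, byrow = TRUE))
  logExit <- log(c(0, 0, 0.2))
  v1 <- coughSpot:::viterbi_c(logB, logPi, logA, logExit, Inf)
  cshift <- 2.5
  v2 <- coughSpot:::viterbi_c(logB + cshift, logPi, logA, logExit, Inf)
  expect_identical(v1$path, v2$path)
  expect_equal(v2$score, v1$score + T_ * cshift, tolerance = 1e-10)
})

test_that("single-model network decodes as one full-length span", {
  m <- randomHmm("only", 1, 2, seed = 4)
  net <- recognitionNetwork(list(m), keyword = "only")
  X <- matrix(stats::rnorm(10), 5, 2)
  dp <- decodeTokenPassing(net, X)
  expect_true(nrow(dp) >= 1)
  expect_equal(dp$firstFrame[1], 1)
  expect_equal(dp$lastFrame[nrow(dp)], 5)
  expect_true(all(dp$label == "only"))
})

test_that("token passing matches exhaustive search over the composed network", {
  set.seed(41)
  for (rep in 1:6) {
    nm <- sample(1:2, 1)
    models <- lapply(seq_len(nm), function(i)
      randomHmm(paste0("m", i), sample(2:3, 1), 2, M = 1L,
                seed = 200 + 10 * rep + i))
    net <- recognitionNetwork(models, keyword = "m1",
                              loopPenalty = sample(c(0, -1), 1))
    T_ <- sample(3:5, 1)
    X <- matrix(stats::rnorm(T_ * 2, sd = 2), T_, 2)
    dp <- decodeTokenPassing(net, X)
    o <- enumerateDecode(net, X)
    expect_equal(attr(dp, "totalLogScore"), o$score, tolerance = 1e-9)
    # identical frame-level label sequence
    labs <- vapply(networkModels(net), hmmLabel, character(1))
    mine <- rep(dp$label, dp$lastFrame - dp$firstFrame + 1)
    expect_equal(mine, labs[o$modelSeq])
  }
})

test_that("an infinite insertion penalty forces a single-model span", {
  models <- list(randomHmm("a", 2, 2, seed = 51), randomHmm("b", 2, 2, seed = 52))
  net <- recognitionNetwork(models, keyword = "a", loopPenalty = -Inf)
  X <- matrix(stats::rnorm(16, sd = 2), 8, 2)
  dp <- decodeTokenPassing(net, X)
  expect_equal(nrow(dp), 1)
  sa <- viterbiAlign(models[[1]], X)$score
  sb <- viterbiAlign(models[[2]], X)$score
  expect_equal(dp$label, if (sa >= sb) "a" else "b")
  expect_equal(attr(dp, "totalLogScore"), max(sa, sb), tolerance = 1e-9)
})

test_that("transition probabilities are recovered from sampled corpora", {
  truth <- randomHmm("truth", 2, 2, M = 1L, seed = 61)
  # well-separated state means (>= 5 SD apart)
  truth@emissions[[1]]$means[] <- c(0, 0)
  truth@emissions[[2]]$means[] <- c(6, 6)
  truth@emissions[[1]]$variances[] <- 1
  truth@emissions[[2]]$variances[] <- 1
  truth@logTrans[2, 2:4] <- log(c(0.85, 0.15, 0))
  truth@logTrans[2, 4] <- -Inf
  truth@logTrans[3, 3:4] <- log(c(0.90, 0.10))

  errFor <- function(n) {
    seqs <- sampleHmmSequences(truth, n, 50, seed = 62)
    fit <- trainHmm("fit", seqs, nStates = 2, nMix = 1, maxIter = 30,
                    seed = 1)
    A <- transitionMatrix(fit)
    max(abs(A[2, 2] - 0.85), abs(A[3, 3] - 0.90))
  }
  eBig <- errFor(200)
  expect_lt(eBig, 0.05)
  eSmall <- errFor(25)
  expect_lt(eBig, eSmall + 0.02)   # error shrinks (allowing MC slack)
})

test_that("duplicating the corpus leaves the fit unchanged (same seed)", {
  set.seed(71)
  seqs <- replicate(5, matrix(stats::rnorm(60), 15, 4), simplify = FALSE)
  m1 <- trainHmm("x", seqs, nStates = 2, nMix = 1, maxIter = 10, seed = 3)
  m2 <- trainHmm("x", c(seqs, seqs), nStates = 2, nMix = 1, maxIter = 10,
                 seed = 3)
  expect_equal(m1@logTrans, m2@logTrans, tolerance = 1e-6)
  expect_equal(emissions(m1)[[1]]$means, emissions(m2)[[1]]$means,
               tolerance = 1e-6)
})

test_that("network JSON serialisation round-trips losslessly", {
  net <- smallNetwork()
  p <- tempfile(fileext = ".json")
  saveNetwork(net, p)
  rt <- loadNetwork(p)
  expect_equal(keywordLabel(rt), keywordLabel(net))
  for (i in seq_along(networkModels(net))) {
    a <- networkModels(net)[[i]]; b <- networkModels(rt)[[i]]
    expect_identical(hmmLabel(a), hmmLabel(b))
    expect_equal(a@logTrans, b@logTrans, tolerance = 1e-12)
    for (s in seq_len(nStates(a))) {
      expect_equal(emissions(a)[[s]]$means, emissions(b)[[s]]$means,
                   tolerance = 1e-12, ignore_attr = TRUE)
      expect_equal(emissions(a)[[s]]$variances,
                   emissions(b)[[s]]$variances, tolerance = 1e-12,
                   ignore_attr = TRUE)
      expect_equal(emissions(a)[[s]]$weights, emissions(b)[[s]]$weights,
                   tolerance = 1e-12, ignore_attr = TRUE)
    }
  }
  # a reloaded network decodes identically
  X <- featureMatrix(featuresForSamples(stats::rnorm(16000) * 0.05))
  d1 <- decodeTokenPassing(net, X)
  d2 <- decodeTokenPassing(rt, X)
  expect_equal(attr(d1, "totalLogScore"), attr(d2, "totalLogScore"),
               tolerance = 1e-9)
})

test_that("dimension mismatches are rejected", {
  m <- randomHmm("x", 2, 3, seed = 81)
  expect_error(viterbiAlign(m, matrix(0, 4, 2)), "dimension")
})
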