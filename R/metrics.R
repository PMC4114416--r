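# Detector validation metrics: event matching, sensitivity, false positives
# per hour, and rater percent agreement.

#' Match detected events against ground truth
#'
#' Greedy one-to-one matching in time order: each detected event (by
#' midpoint) is matched to the earliest unmatched truth event whose midpoint
#' lies within `tolS`; remaining detected events are false positives,
#' remaining truth events false negatives. Deterministic; on the midpoint
#' tolerance graph this greedy matching attains the maximum one-to-one
#' matching size.
#'
#' @param detected data.frame with `start_s`, `end_s` (detected events).
#' @param truth data.frame with `start_s`, `end_s` (ground-truth events).
#' @param tolS midpoint tolerance, seconds (>= 0).
#' @return list with class "MatchResult": `tp`, `fn`, `fp` counts and
#'   `matchedPairs` (data.frame detected_index, truth_index).
#' @export
matchEvents <- function(detected, truth, tolS = 0.5) {
  stopIfNot(tolS >= 0, "tolS must be >= 0")
  dm <- if (nrow(detected)) (detected$start_s + detected$end_s) / 2
        else numeric(0)
  tm <- if (nrow(truth)) (truth$start_s + truth$end_s) / 2 else numeric(0)
  dOrd <- order(dm)
  tOrd <- order(tm)
  usedT <- logical(length(tm))
  pairs <- matrix(integer(0), 0, 2)
  for (i in dOrd) {
    cand <- tOrd[!usedT[tOrd] & abs(tm[tOrd] - dm[i]) <= tolS]
    if (length(cand)) {
      j <- cand[1L]                      # earliest unmatched truth in reach
      usedT[j] <- TRUE
      pairs <- rbind(pairs, c(i, j))
    }
  }
  res <- list(tp = nrow(pairs), fn = length(tm) - nrow(pairs),
              fp = length(dm) - nrow(pairs),
              matchedPairs = data.frame(detected_index = pairs[, 1],
                                        truth_index = pairs[, 2]))
  class(res) <- "MatchResult"
  res
}

#' Detector sensitivity (true-positive fraction)
#'
#' tp / (tp + fn): detected true events over all true events.
#'
#' @param m a "MatchResult" from [matchEvents()].
#' @return fraction in \[0, 1\].
#' @export
sensitivity <- function(m) {
  if (m$tp + m$fn == 0)
    stop("sensitivity undefined: no ground-truth events")
  m$tp / (m$tp + m$fn)
}

#' False positives per monitored hour
#'
#' @param m a "MatchResult".
#' @param monitoredS monitored duration, seconds (> 0).
#' @return rate >= 0, detections without a matching true event per hour.
#' @export
fpPerHour <- function(m, monitoredS) {
  if (monitoredS <= 0) stop("monitoredS must be positive")
  m$fp / (monitoredS / 3600)
}

#' Percent agreement between independent raters
#'
#' @param nAgree number of cases with identical classification.
#' @param nTotal total cases (> 0).
#' @return percentage, 100 * nAgree / nTotal, at full precision.
#' @export
percentAgreement <- function(nAgree, nTotal) {
  if (nTotal <= 0) stop("nTotal must be positive")
  stopIfNot(nAgree >= 0 && nAgree <= nTotal,
            "need 0 <= nAgree <= nTotal")
  100 * nAgree / nTotal
}
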