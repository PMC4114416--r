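# Acceptance-survey statistics: scale scoring with cutoff, per-item
# agreement, Cronbach's alpha, and item-companion correlations.

#' Score acceptance-survey responses against the satisfaction cutoff
#'
#' Totals the 7 items (5-point scale, 5 = strongly agree; range 7-35) per
#' respondent and flags totals at or above the cutoff as satisfactory
#' acceptance. The default cutoff 28 corresponds to answering at least
#' "agree" on all 7 items. Respondents with any missing item get NA totals
#' and are excluded from the summary.
#'
#' @param responses data.frame with `respondent_id` and `item1`..`item7`
#'   columns (integers 1..5; NA = missing).
#' @param cutoff satisfaction threshold on the total score.
#' @return list: `perRespondent` data.frame (respondent_id, total,
#'   satisfied), `summary` list (n, mean, sd, satisfiedProportion).
#' @export
scoreSurvey <- function(responses, cutoff = 28L) {
  itemCols <- grep("^item[0-9]+$", names(responses), value = TRUE)
  stopIfNot(length(itemCols) >= 1L, "no item columns found")
  items <- as.matrix(responses[, itemCols])
  bad <- which(apply(items, 1L, function(r)
    any(!is.na(r) & (r < 1 | r > 5 | r != round(r)))))
  if (length(bad))
    stop("malformed response for respondent ",
         responses$respondent_id[bad[1L]])
  total <- rowSums(items)                      # NA when any item missing
  per <- data.frame(respondent_id = responses$respondent_id,
                    total = total, satisfied = total >= cutoff)
  ok <- !is.na(total)
  list(perRespondent = per,
       summary = list(n = sum(ok), mean = mean(total[ok]),
                      sd = stats::sd(total[ok]),
                      satisfiedProportion = mean(total[ok] >= cutoff)))
}

#' Per-item agreement proportions
#'
#' Proportion of non-missing responses of 4 or 5 ("agree" pooled with
#' "strongly agree") per item, with the per-item denominator after pairwise
#' exclusion of missing values.
#'
#' @param responses data.frame with `item1`..`itemk` columns.
#' @return data.frame: `item`, `n_agree`, `n`, `proportion` (NA and flagged
#'   when an item is all-missing).
#' @export
itemAgreement <- function(responses) {
  itemCols <- grep("^item[0-9]+$", names(responses), value = TRUE)
  rows <- lapply(itemCols, function(cl) {
    v <- responses[[cl]]
    n <- sum(!is.na(v))
    if (n == 0L)
      return(data.frame(item = cl, n_agree = 0L, n = 0L,
                        proportion = NA_real_))
    data.frame(item = cl, n_agree = sum(v >= 4, na.rm = TRUE), n = n,
               proportion = sum(v >= 4, na.rm = TRUE) / n)
  })
  do.call(rbind, rows)
}

#' Cronbach's alpha internal-consistency reliability
#'
#' alpha = k/(k-1) * (1 - sum(item variances) / variance of totals), with
#' unbiased variances over listwise-complete responses.
#'
#' @param items n x k numeric matrix or data.frame of item responses.
#' @return alpha in (-Inf, 1\].
#' @export
cronbachAlpha <- function(items) {
  m <- as.matrix(items)
  m <- m[stats::complete.cases(m), , drop = FALSE]
  k <- ncol(m)
  stopIfNot(k >= 2L, "need at least 2 items")
  stopIfNot(nrow(m) >= 2L, "need at least 2 complete responses")
  totVar <- stats::var(rowSums(m))
  if (totVar == 0) stop("alpha undefined: zero total-score variance")
  k / (k - 1) * (1 - sum(apply(m, 2L, stats::var)) / totVar)
}

#' Correlation between an item and a companion measure
#'
#' Pearson r with two-sided p over pairwise-complete cases (shares its
#' implementation with [correlateCoughActivity()]).
#'
#' @param itemScores per-respondent item values.
#' @param companionScores per-respondent companion values (e.g. an asthma
#'   control item).
#' @return list(r, p, n).
#' @export
itemCorrelation <- function(itemScores, companionScores) {
  ok <- stats::complete.cases(itemScores, companionScores)
  correlateCoughActivity(itemScores[ok], companionScores[ok])
}

#' Read a survey CSV (respondent_id, item1..item7, companion columns)
#' @param path CSV path.
#' @export
readSurveyCsv <- function(path) utils::read.csv(path)
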