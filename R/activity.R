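# Accelerometer-derived activity on the device's 0-24 per-minute scale,
# hourly summaries, and cough-activity correlation.

#' Read an accelerometer CSV (raw or scored dialect)
#'
#' Raw dialect has columns `t`, `ax`, `ay`, `az` (seconds, g units); scored
#' dialect has `minute_start_s` and `score` (0-24).
#'
#' @param path CSV path.
#' @return data.frame with class "AccelerometerTrace" and attribute "mode"
#'   ("raw" or "scored").
#' @export
readAccelCsv <- function(path) {
  df <- utils::read.csv(path)
  if (all(c("t", "ax", "ay", "az") %in% names(df))) {
    mode <- "raw"
    if (is.unsorted(df$t, strictly = TRUE))
      stop("raw accelerometer timestamps must be strictly increasing")
  } else if (all(c("minute_start_s", "score") %in% names(df))) {
    mode <- "scored"
    if (any(df$score < 0 | df$score > 24))
      stop("scored-mode values must lie in [0, 24]")
  } else stop("unrecognised accelerometer CSV dialect: ", path)
  structure(df, class = c("AccelerometerTrace", "data.frame"), mode = mode)
}

#' Score raw accelerometer minutes on the 0-24 activity scale
#'
#' For each complete minute, the score is the mean absolute deviation of the
#' acceleration magnitude from its minute mean, scaled by a calibration
#' constant and capped at 24. The default constant (12 * pi) maps a 1 g
#' sinusoidal magnitude oscillation (vigorous motion) to the cap, since a
#' sine of amplitude A has mean absolute deviation 2A/pi. Incomplete
#' trailing minutes are dropped.
#'
#' @param trace a raw-mode "AccelerometerTrace" (columns t, ax, ay, az).
#' @param rateHz nominal sampling rate (used only to require >= 1 minute).
#' @param scale calibration constant (score per g of mean absolute
#'   deviation).
#' @return list with class "ActivitySummary": `minuteScores` data.frame
#'   (minute_start_s, score) and `hourlyMeans` data.frame (hour_index,
#'   mean_score).
#' @export
scoreMinutes <- function(trace, rateHz = 10, scale = 12 * pi) {
  stopIfNot(all(c("t", "ax", "ay", "az") %in% names(trace)),
            "raw-mode trace with columns t, ax, ay, az required")
  if (is.unsorted(trace$t, strictly = TRUE))
    stop("timestamps must be strictly increasing")
  stopIfNot(max(trace$t) - min(trace$t) >= 60,
            "need at least one complete minute of data")
  mag <- sqrt(trace$ax^2 + trace$ay^2 + trace$az^2)
  minute <- floor((trace$t - trace$t[1L]) / 60)
  nMin <- floor((max(trace$t) - trace$t[1L]) / 60)
  scores <- vapply(seq_len(nMin) - 1L, function(m) {
    v <- mag[minute == m]
    min(scale * mean(abs(v - mean(v))), 24)
  }, numeric(1))
  minuteScores <- data.frame(minute_start_s = (seq_len(nMin) - 1L) * 60,
                             score = scores)
  structure(list(minuteScores = minuteScores,
                 hourlyMeans = hourlyActivity(minuteScores)),
            class = "ActivitySummary")
}

#' Hourly means of per-minute activity scores
#' @param minuteScores data.frame with `minute_start_s` and `score`.
#' @return data.frame: `hour_index` (0-based from trace start),
#'   `mean_score`.
#' @export
hourlyActivity <- function(minuteScores) {
  hour <- floor(minuteScores$minute_start_s / 3600)
  agg <- stats::aggregate(minuteScores$score, list(hour_index = hour), mean)
  names(agg)[2L] <- "mean_score"
  agg
}

#' Pearson correlation between cough counts and activity
#'
#' Standard product-moment correlation with a two-sided p-value from the t
#' transform, computed on equal-length paired interval series (per-minute by
#' default in the pipeline; hourly when the caller aggregates first).
#'
#' @param coughCounts per-interval event counts.
#' @param activity per-interval activity scores.
#' @return list(r, p, n).
#' @export
correlateCoughActivity <- function(coughCounts, activity) {
  stopIfNot(length(coughCounts) == length(activity),
            "paired series must have equal length")
  stopIfNot(length(coughCounts) >= 3L, "need n >= 3 pairs")
  if (stats::sd(coughCounts) == 0 || stats::sd(activity) == 0)
    stop("undefined correlation: a series has zero variance")
  ct <- stats::cor.test(coughCounts, activity, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value,
       n = length(coughCounts))
}

#' Per-minute cough counts for pairing with activity scores
#' @param events event data.frame with `start_s`.
#' @param nMinutes number of minutes covered.
#' @return integer vector of length `nMinutes`.
#' @export
coughsPerMinute <- function(events, nMinutes) {
  tabulate(floor(events$start_s / 60) + 1L, nMinutes)
}

#' Write an activity summary CSV
#' @param summary an "ActivitySummary" or minute-score data.frame.
#' @param path output path.
#' @export
writeActivityCsv <- function(summary, path) {
  df <- if (inherits(summary, "ActivitySummary")) summary$minuteScores
        else summary
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
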