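# Medication/diary logging and assembly of the daily report combining
# hourly cough bars, the activity line, and medication marks.

#' Open (or create) a line-delimited JSON diary store
#'
#' @param path path to a .jsonl file; created on first append.
#' @return list with class "DiaryStore": `path` and `records` data.frame
#'   (timestamp, kind, note).
#' @export
diaryStore <- function(path) {
  records <- if (file.exists(path) && file.size(path) > 0) {
    lines <- readLines(path)
    do.call(rbind, lapply(lines, function(l) {
      x <- jsonlite::fromJSON(l)
      data.frame(timestamp = as.numeric(x$timestamp), kind = x$kind,
                 note = if (is.null(x$note) || !length(x$note))
                   NA_character_ else as.character(x$note))
    }))
  } else data.frame(timestamp = numeric(0), kind = character(0),
                    note = character(0))
  structure(list(path = path, records = records), class = "DiaryStore")
}

#' Log a medication record (append-only)
#'
#' @param store a [diaryStore()].
#' @param timestamp seconds since epoch.
#' @param kind "controller" or "rescue".
#' @param note optional free text.
#' @return the updated store. Records are never deduplicated.
#' @export
logMedication <- function(store, timestamp, kind, note = NA_character_) {
  if (!kind %in% c("controller", "rescue"))
    stop("unknown medication kind: ", kind)
  rec <- data.frame(timestamp = as.numeric(timestamp), kind = kind,
                    note = note)
  doc <- list(timestamp = as.numeric(timestamp), kind = kind)
  if (!is.na(note)) doc$note <- note
  line <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA)
  cat(line, "\n", sep = "", file = store$path, append = TRUE)
  store$records <- rbind(store$records, rec)
  store
}

#' Per-day medication summary
#' @param store a [diaryStore()].
#' @param date "YYYY-MM-DD" string, or NULL for all days.
#' @param tz time zone for day boundaries.
#' @return data.frame: `date`, `controller`, `rescue`.
#' @export
medicationSummary <- function(store, date = NULL, tz = "UTC") {
  r <- store$records
  if (nrow(r) == 0L)
    return(data.frame(date = character(0), controller = integer(0),
                      rescue = integer(0)))
  day <- format(as.POSIXct(r$timestamp, origin = "1970-01-01", tz = tz),
                "%Y-%m-%d")
  if (!is.null(date)) {
    keep <- day == date
    r <- r[keep, , drop = FALSE]
    day <- day[keep]
    if (nrow(r) == 0L)
      return(data.frame(date = date, controller = 0L, rescue = 0L))
  }
  agg <- lapply(split(r$kind, day), function(k)
    c(controller = sum(k == "controller"), rescue = sum(k == "rescue")))
  data.frame(date = names(agg),
             controller = vapply(agg, `[[`, integer(1), "controller"),
             rescue = vapply(agg, `[[`, integer(1), "rescue"),
             row.names = NULL)
}

#' Assemble the user-facing daily report
#'
#' Aligns hourly cough counts (bar heights), hourly mean activity (line) and
#' medication events on a single 24-slot day grid. Day boundaries follow the
#' recording clock when event times are wall-anchored (`recStart` given).
#'
#' @param events event data.frame (`start_s` seconds from recording start).
#' @param activity minute-score data.frame (`minute_start_s`, `score`) or an
#'   "ActivitySummary".
#' @param meds a [diaryStore()] or medication data.frame (timestamp, kind).
#' @param date "YYYY-MM-DD" of the reported day.
#' @param recStart recording start, seconds since epoch; NA treats
#'   `date` 00:00 UTC as recording start.
#' @param recDurationS recording duration, seconds.
#' @param tz time zone for the day grid.
#' @return list with class "DailyReport": `date`, `hourLabels` (0..23),
#'   `hourlyCoughCounts`, `hourlyActivityMeans`, `medicationEvents`,
#'   `diaryEntries`, `empty` flag.
#' @export
buildReport <- function(events, activity, meds, date,
                        recStart = NA_real_, recDurationS = 86400,
                        tz = "UTC") {
  day0 <- as.numeric(as.POSIXct(paste0(date, " 00:00:00"), tz = tz))
  anchor <- if (is.na(recStart)) day0 else recStart
  hc <- aggregateHourly(events, anchor, recDurationS)
  inDay <- hc$hour_start >= day0 & hc$hour_start < day0 + 86400
  counts <- rep(0L, 24L)
  monitored <- rep(0, 24L)
  slot <- as.integer((hc$hour_start[inDay] - day0) / 3600) + 1L
  counts[slot] <- hc$cough_count[inDay]
  monitored[slot] <- hc$monitored_fraction[inDay]

  act <- if (inherits(activity, "ActivitySummary")) activity$minuteScores
         else activity
  actMeans <- rep(NA_real_, 24L)
  if (!is.null(act) && nrow(act)) {
    wall <- anchor + act$minute_start_s
    inD <- wall >= day0 & wall < day0 + 86400
    if (any(inD)) {
      hr <- as.integer((wall[inD] - day0) / 3600) + 1L
      agg <- tapply(act$score[inD], hr, mean)
      actMeans[as.integer(names(agg))] <- as.numeric(agg)
    }
  }

  medRec <- if (inherits(meds, "DiaryStore")) meds$records else meds
  medDay <- if (!is.null(medRec) && nrow(medRec)) {
    d <- format(as.POSIXct(medRec$timestamp, origin = "1970-01-01",
                           tz = tz), "%Y-%m-%d")
    medRec[d == date, , drop = FALSE]
  } else data.frame(timestamp = numeric(0), kind = character(0),
                    note = character(0))

  structure(list(date = date, hourLabels = 0:23,
                 hourlyCoughCounts = counts,
                 hourlyActivityMeans = actMeans,
                 monitoredFraction = monitored,
                 medicationEvents = medDay,
                 diaryEntries = medDay$note[!is.na(medDay$note)],
                 empty = all(monitored == 0)),
            class = "DailyReport")
}

reportToList <- function(report) {
  x <- list(
    date = report$date,
    diary_entries = as.character(report$diaryEntries),
    empty = report$empty,
    hour_labels = report$hourLabels,
    hourly_activity_means = report$hourlyActivityMeans,
    hourly_cough_counts = report$hourlyCoughCounts,
    medication_events = lapply(seq_len(nrow(report$medicationEvents)),
      function(i) list(kind = report$medicationEvents$kind[i],
                       timestamp = report$medicationEvents$timestamp[i])),
    monitored_fraction = report$monitoredFraction)
  x[order(names(x))]          # stable, sorted keys
}

#' Serialise a daily report to JSON (stable, sorted keys)
#' @param report a "DailyReport".
#' @param path output path.
#' @export
saveReport <- function(report, path) {
  jsonlite::write_json(reportToList(report), path, auto_unbox = TRUE,
                       digits = NA, na = "null", pretty = TRUE)
  invisible(path)
}

#' Load a daily report saved by [saveReport()]
#' @param path JSON path.
#' @return a "DailyReport".
#' @export
loadReport <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  med <- if (length(x$medication_events))
    data.frame(timestamp = vapply(x$medication_events, `[[`, numeric(1),
                                  "timestamp"),
               kind = vapply(x$medication_events, `[[`, character(1),
                             "kind"),
               note = NA_character_)
  else data.frame(timestamp = numeric(0), kind = character(0),
                  note = character(0))
  num <- function(v) vapply(v, function(e)
    if (is.null(e)) NA_real_ else as.numeric(e), numeric(1))
  structure(list(date = x$date, hourLabels = unlist(x$hour_labels),
                 hourlyCoughCounts = as.integer(num(x$hourly_cough_counts)),
                 hourlyActivityMeans = num(x$hourly_activity_means),
                 monitoredFraction = num(x$monitored_fraction),
                 medicationEvents = med,
                 diaryEntries = as.character(unlist(x$diary_entries)),
                 empty = isTRUE(x$empty)),
            class = "DailyReport")
}

#' Render the daily chart (hourly cough bars + activity line + med marks)
#'
#' @param report a "DailyReport".
#' @param path output image path; format by extension (.svg or .png).
#' @return `path`, invisibly.
#' @export
plotDailyReport <- function(report, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") grDevices::png(path, width = 900, height = 450)
  else grDevices::svg(path, width = 9, height = 4.5)
  on.exit(grDevices::dev.off())
  op <- graphics::par(mar = c(4, 4, 2, 4))
  on.exit(graphics::par(op), add = TRUE)
  bars <- report$hourlyCoughCounts
  graphics::barplot(bars, names.arg = report$hourLabels,
                    col = "steelblue", border = NA,
                    xlab = "hour of day", ylab = "coughs",
                    main = paste("Daily report", report$date),
                    ylim = c(0, max(bars, 1) * 1.2))
  act <- report$hourlyActivityMeans
  if (any(!is.na(act))) {
    sc <- max(bars, 1) / 24
    xs <- seq(0.7, by = 1.2, length.out = 24)
    graphics::lines(xs, act * sc, col = "darkorange", lwd = 2)
    graphics::axis(4, at = seq(0, max(bars, 1), length.out = 5),
                   labels = round(seq(0, 24, length.out = 5), 1))
    graphics::mtext("activity (0-24)", side = 4, line = 2.5)
  }
  if (nrow(report$medicationEvents)) {
    day0 <- as.numeric(as.POSIXct(paste0(report$date, " 00:00:00"),
                                  tz = "UTC"))
    hr <- (report$medicationEvents$timestamp - day0) / 3600
    xs <- 0.7 + 1.2 * hr
    graphics::points(xs, rep(0, length(xs)), pch = 17, col = "firebrick",
                     cex = 1.2)
  }
  invisible(path)
}
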