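# Required columns of an event table, with their checkers. Coordinates live on
# the standard 120 x 80 event-data grid, oriented in the direction of the
# possessing team's attack; times are seconds from the start of the event's
# period.
.event_cols <- c("match_id", "team", "period", "time_s", "duration_s",
                 "x", "y", "event_type")

.field_length <- 120
.field_width <- 80

#' Assemble a labelled match-event dataset
#'
#' Bundles an event table and a match-result table into a validated
#' `edran_dataset`. Every event carries a possessing team (`"A"` or `"B"`),
#' the period it occurred in (1 or 2), its start time within that period, its
#' duration, and its pitch location on the 120 x 80 grid (already oriented
#' toward the possessing team's attack). Results are binary: 1 means Team A
#' won the match, 0 means Team B won; drawn matches are not representable and
#' must be excluded upstream.
#'
#' @param events data.frame with columns `match_id`, `team` ("A"/"B"),
#'   `period` (1 or 2), `time_s`, `duration_s`, `x` (0-120), `y` (0-80),
#'   `event_type`.
#' @param results data.frame with columns `match_id` and `result` (0 or 1).
#' @param period_end optional data.frame with columns `match_id`, `period`,
#'   `end_s` giving each half's true duration including injury time. When
#'   missing, each half's end is inferred as the latest `time_s + duration_s`
#'   observed in that half.
#' @return An object of class `edran_dataset`: a list with elements `events`,
#'   `results` and `period_end`.
#' @examples
#' ev <- data.frame(match_id = "m1", team = c("A", "B"), period = 1,
#'                  time_s = c(10, 40), duration_s = c(2, 3),
#'                  x = c(60, 30), y = c(40, 20), event_type = "pass")
#' res <- data.frame(match_id = "m1", result = 1)
#' d <- edran_dataset(ev, res)
#' class_balance(d)
#' @export
edran_dataset <- function(events, results, period_end = NULL) {
  events <- validate_events(events)
  results <- validate_results(results)

  missing_lab <- setdiff(unique(events$match_id), results$match_id)
  if (length(missing_lab))
    stop("matches without a result label: ", paste(missing_lab, collapse = ", "))

  if (is.null(period_end)) {
    period_end <- infer_period_end(events)
  } else {
    stopifnot(all(c("match_id", "period", "end_s") %in% names(period_end)))
    period_end <- period_end[, c("match_id", "period", "end_s")]
    period_end$match_id <- as.character(period_end$match_id)
    key <- paste(events$match_id, events$period)
    pkey <- paste(period_end$match_id, period_end$period)
    end <- period_end$end_s[match(key, pkey)]
    bad <- which(is.na(end) | events$time_s > end)
    if (length(bad))
      stop("event row ", bad[1], ": time_s ", events$time_s[bad[1]],
           " exceeds (or lacks) the declared end of period ",
           events$period[bad[1]])
  }

  structure(list(events = events, results = results, period_end = period_end),
            class = "edran_dataset")
}

validate_events <- function(events) {
  if (!is.data.frame(events)) stop("events must be a data.frame")
  miss <- setdiff(.event_cols, names(events))
  if (length(miss)) stop("events is missing columns: ", paste(miss, collapse = ", "))
  events <- as.data.frame(events)[, .event_cols]
  events$match_id <- as.character(events$match_id)
  events$team <- as.character(events$team)
  events$event_type <- as.character(events$event_type)

  fail <- function(rows, field, why) {
    if (length(rows))
      stop("event row ", rows[1], ", field '", field, "': ", why)
  }
  fail(which(!events$team %in% c("A", "B")), "team", "must be \"A\" or \"B\"")
  fail(which(!events$period %in% c(1L, 2L)), "period", "must be 1 or 2")
  num <- function(v) is.numeric(v) & is.finite(v)
  fail(which(!num(events$time_s) | events$time_s < 0), "time_s",
       "must be a finite number >= 0")
  fail(which(!num(events$duration_s) | events$duration_s < 0), "duration_s",
       "must be a finite number >= 0")
  fail(which(!num(events$x) | events$x < 0 | events$x > .field_length), "x",
       paste0("must lie in [0, ", .field_length, "]"))
  fail(which(!num(events$y) | events$y < 0 | events$y > .field_width), "y",
       paste0("must lie in [0, ", .field_width, "]"))
  events$period <- as.integer(events$period)
  rownames(events) <- NULL
  events
}

validate_results <- function(results) {
  if (!is.data.frame(results)) stop("results must be a data.frame")
  if (!all(c("match_id", "result") %in% names(results)))
    stop("results needs columns match_id and result")
  results <- as.data.frame(results)[, c("match_id", "result")]
  results$match_id <- as.character(results$match_id)
  bad <- which(!results$result %in% c(0, 1))
  if (length(bad))
    stop("results row ", bad[1], ": result must be 0 (Team B win) or 1 ",
         "(Team A win); draws are not representable and must be excluded")
  if (anyDuplicated(results$match_id))
    stop("duplicated match_id in results")
  results$result <- as.integer(results$result)
  rownames(results) <- NULL
  results
}

infer_period_end <- function(events) {
  end <- aggregate(list(end_s = events$time_s + events$duration_s),
                   by = list(match_id = events$match_id, period = events$period),
                   FUN = max)
  end[order(end$match_id, end$period), c("match_id", "period", "end_s")]
}

#' @export
print.edran_dataset <- function(x, ...) {
  cat("edran_dataset:", nrow(x$results), "matches,",
      nrow(x$events), "events\n")
  cat("  Team A win rate:", format(class_balance(x), digits = 4), "\n")
  invisible(x)
}

#' @export
summary.edran_dataset <- function(object, ...) {
  ev <- object$events
  cat("Matches:            ", nrow(object$results), "\n")
  cat("Events:             ", nrow(ev), "\n")
  cat("Event types:        ", paste(sort(unique(ev$event_type)), collapse = ", "), "\n")
  cat("Team A win rate:    ", format(class_balance(object), digits = 4), "\n")
  cat("Total event time (h):", format(sum(ev$duration_s) / 3600, digits = 4), "\n")
  invisible(object)
}

#' Read a match event log and its result labels
#'
#' Reads a flat event log (JSON lines, one event object per line, or CSV) and
#' a CSV of match results into an [edran_dataset]. The JSON-lines dialect is
#' canonical; CSV is a convenience mirror with identical columns.
#'
#' @param events_path path to the event log.
#' @param results_path path to a CSV with columns `match_id,result`.
#' @param format `"jsonl"` or `"csv"`.
#' @param period_end optional half-duration table passed on to
#'   [edran_dataset()]; when absent, half ends are inferred from the events.
#' @return an [edran_dataset].
#' @seealso [write_event_log()]
#' @export
read_event_log <- function(events_path, results_path,
                           format = c("jsonl", "csv"), period_end = NULL) {
  format <- match.arg(format)
  if (!file.exists(events_path)) stop("no such file: ", events_path)
  if (!file.exists(results_path)) stop("no such file: ", results_path)
  events <- switch(format,
    jsonl = {
      lines <- readLines(events_path)
      lines <- lines[nzchar(trimws(lines))]
      rows <- lapply(seq_along(lines), function(i) {
        rec <- tryCatch(jsonlite::fromJSON(lines[i]),
                        error = function(e) stop("event row ", i,
                                                 ": malformed JSON line"))
        miss <- setdiff(.event_cols, names(rec))
        if (length(miss))
          stop("event row ", i, ": missing field(s) ",
               paste(miss, collapse = ", "))
        as.data.frame(rec[.event_cols])
      })
      do.call(rbind, rows)
    },
    csv = utils::read.csv(events_path, stringsAsFactors = FALSE)
  )
  results <- utils::read.csv(results_path, stringsAsFactors = FALSE)
  edran_dataset(events, results, period_end = period_end)
}

#' Write a match event log and its result labels
#'
#' Inverse of [read_event_log()]: writes the event table as JSON lines or CSV
#' and the result labels as CSV. Round-tripping reproduces integer fields
#' exactly and coordinates/durations to at least six decimals.
#'
#' @param dataset an [edran_dataset].
#' @param events_path,results_path output paths.
#' @param format `"jsonl"` or `"csv"`.
#' @export
write_event_log <- function(dataset, events_path, results_path,
                            format = c("jsonl", "csv")) {
  stopifnot(inherits(dataset, "edran_dataset"))
  format <- match.arg(format)
  ev <- dataset$events
  if (format == "jsonl") {
    lines <- vapply(seq_len(nrow(ev)), function(i)
      jsonlite::toJSON(as.list(ev[i, ]), auto_unbox = TRUE, digits = NA),
      character(1))
    writeLines(lines, events_path)
  } else {
    utils::write.csv(ev, events_path, row.names = FALSE)
  }
  utils::write.csv(dataset$results, results_path, row.names = FALSE)
  invisible(dataset)
}

#' Configure the on-ball event filter
#'
#' The entropy analysis weights events by duration over the pitch, so it only
#' wants on-ball (ball-movement) events. The source data does not come with a
#' canonical on-ball tag set, so the included types are configuration with a
#' sensible default. Zero-duration events add no possession weight and are
#' dropped by default.
#'
#' @param included_event_types character vector of event-type tags to keep.
#' @param drop_zero_duration drop events with `duration_s == 0`?
#' @return a list of class `event_filter_config`.
#' @export
event_filter_config <- function(
    included_event_types = c("pass", "carry", "dribble", "shot",
                             "clearance", "goalkeeper-distribution"),
    drop_zero_duration = TRUE) {
  if (!length(included_event_types))
    stop("included_event_types must be non-empty")
  structure(list(included_event_types = as.character(included_event_types),
                 drop_zero_duration = isTRUE(drop_zero_duration)),
            class = "event_filter_config")
}

#' Keep only ball-movement events
#'
#' Drops every event whose type is not in the configured on-ball set and,
#' optionally, events of zero duration. Idempotent. If a team ends up with no
#' events at all in some match a warning (not an error) is raised, since the
#' downstream entropy treats empty intervals explicitly.
#'
#' @param dataset an [edran_dataset].
#' @param config an [event_filter_config()].
#' @param quiet suppress the dropped-event message.
#' @return the filtered [edran_dataset].
#' @export
filter_ball_movement_events <- function(dataset,
                                        config = event_filter_config(),
                                        quiet = FALSE) {
  stopifnot(inherits(dataset, "edran_dataset"),
            inherits(config, "event_filter_config"))
  ev <- dataset$events
  keep <- ev$event_type %in% config$included_event_types
  if (config$drop_zero_duration) keep <- keep & ev$duration_s > 0
  dropped <- sum(!keep)
  if (!quiet && dropped > 0)
    message("filter_ball_movement_events: dropped ", dropped, " of ",
            nrow(ev), " events")
  out <- ev[keep, , drop = FALSE]
  rownames(out) <- NULL
  for (m in dataset$results$match_id) {
    teams <- unique(out$team[out$match_id == m])
    gone <- setdiff(c("A", "B"), teams)
    if (length(gone))
      warning("match ", m, ": team ", paste(gone, collapse = ", "),
              " has no events left after filtering", call. = FALSE)
  }
  # keep the original period ends: filtering must not shrink the halves
  structure(list(events = out, results = dataset$results,
                 period_end = dataset$period_end),
            class = "edran_dataset")
}

#' Proportion of matches won by Team A
#'
#' @param dataset an [edran_dataset], or a results data.frame with a `result`
#'   column of 0/1 labels.
#' @return the fraction of matches with `result == 1`.
#' @examples
#' class_balance(data.frame(match_id = 1:4, result = c(1, 1, 1, 0)))
#' @export
class_balance <- function(dataset) {
  res <- if (inherits(dataset, "edran_dataset")) dataset$results else
    validate_results(dataset)
  if (!nrow(res)) stop("empty dataset: class balance undefined")
  mean(res$result == 1)
}
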