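#' Adapt a raw StatsBomb-format event file to the flat schema
#'
#' Optional convenience for users holding public event-log JSON in the
#' StatsBomb open-data layout (one JSON array of nested event objects per
#' match). Maps the nested fields onto the package's flat schema: possessing
#' team from `possession_team$name`, period, time within the period from the
#' `timestamp` (which resets at the start of each half), `duration`,
#' `location` x/y (already oriented toward the possessing team's attack in
#' the source data; no flipping is applied) and the lower-cased `type$name`
#' as the event tag. Events without a location or outside regular time
#' (periods other than 1 and 2) are dropped; missing durations become 0 and
#' are left to the zero-duration filter.
#'
#' This adapter is I/O plumbing only; none of the analysis depends on it.
#' The bundled `synthetic_statsbomb_events.json` fixture is a hand-written
#' synthetic miniature of the layout, not real data.
#'
#' @param path path to a StatsBomb-layout events JSON file (one match).
#' @param match_id identifier to assign to the match.
#' @param team_a name of the team to map to side "A" (by convention the
#'   file's home team); every other possessing team maps to "B".
#' @param result 1 if `team_a` won, 0 otherwise (draws must be excluded).
#' @return an [edran_dataset] containing the single match.
#' @export
read_statsbomb_events <- function(path, match_id, team_a, result) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE, flatten = TRUE)
  if (!is.data.frame(raw) || !nrow(raw)) stop("no events found in ", path)
  need <- c("period", "timestamp", "possession_team.name", "type.name")
  miss <- setdiff(need, names(raw))
  if (length(miss))
    stop("not a StatsBomb-layout event file; missing ",
         paste(miss, collapse = ", "))
  has_loc <- !vapply(raw$location, function(l) is.null(l) || all(is.na(l)),
                     logical(1))
  keep <- has_loc & raw$period %in% 1:2
  raw <- raw[keep, , drop = FALSE]
  if (!nrow(raw)) stop("no located regular-time events in ", path)
  loc <- do.call(rbind, lapply(raw$location, function(l) as.numeric(l[1:2])))
  hms <- do.call(rbind, strsplit(raw$timestamp, ":", fixed = TRUE))
  time_s <- as.numeric(hms[, 1]) * 3600 + as.numeric(hms[, 2]) * 60 +
    as.numeric(hms[, 3])
  dur <- if ("duration" %in% names(raw)) raw$duration else rep(0, nrow(raw))
  dur[is.na(dur)] <- 0
  ev <- data.frame(
    match_id = match_id,
    team = ifelse(raw$possession_team.name == team_a, "A", "B"),
    period = as.integer(raw$period),
    time_s = time_s,
    duration_s = dur,
    x = pmin(pmax(loc[, 1], 0), 120),
    y = pmin(pmax(loc[, 2], 0), 80),
    event_type = tolower(raw$type.name))
  edran_dataset(ev, data.frame(match_id = match_id, result = result))
}
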