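#' Narrative segments
#'
#' A collection of transcript fragments ("segments") from one or more
#' recording sessions. `sequence_index` records the order in which a segment
#' was narrated within its session; tie-breaking during timeline insertion
#' uses this narrative proximity.
#'
#' @param segment_id Character vector of unique ids.
#' @param session_id Character vector (recycled if scalar).
#' @param sequence_index Non-negative integers, unique within a session.
#' @param text Non-empty (after trimming) character vector.
#' @return A `data.frame` of class `narrative_segments`.
#' @export
narrative_segments <- function(segment_id, session_id = "s1",
                               sequence_index = seq_along(segment_id) - 1L,
                               text) {
  df <- data.frame(
    segment_id = as.character(segment_id),
    session_id = rep_len(as.character(session_id), length(segment_id)),
    sequence_index = as.integer(sequence_index),
    text = as.character(text),
    stringsAsFactors = FALSE
  )
  validate_segments(df)
}

validate_segments <- function(df) {
  if (anyDuplicated(df$segment_id))
    stop("duplicate segment_id: ", df$segment_id[duplicated(df$segment_id)][1])
  if (any(df$sequence_index < 0)) stop("sequence_index must be non-negative")
  for (s in unique(df$session_id)) {
    idx <- df$sequence_index[df$session_id == s]
    if (anyDuplicated(idx))
      stop("sequence_index values must be unique within session '", s, "'")
  }
  if (any(!nzchar(trimws(df$text))))
    stop("segment text must be non-empty after whitespace stripping")
  class(df) <- c("narrative_segments", "data.frame")
  df
}

#' Read narrative segments from disk
#'
#' @param path Path to a UTF-8 file.
#' @param format `"jsonl"` (one JSON object per line with fields
#'   `segment_id`, `session_id`, `sequence_index`, `text`; missing
#'   `sequence_index` is assigned in file order) or `"plain_text"` (one
#'   segment per non-empty line, ids generated as `seg-%06d`).
#' @return A `narrative_segments` data frame in file order.
#' @export
read_segments <- function(path, format = c("jsonl", "plain_text")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  if (format == "plain_text") {
    lines <- lines[nzchar(trimws(lines))]
    return(narrative_segments(
      segment_id = sprintf("seg-%06d", seq_along(lines)),
      text = lines
    ))
  }
  keep <- which(nzchar(trimws(lines)) & !startsWith(trimws(lines), "#"))
  recs <- vector("list", length(keep))
  for (i in seq_along(keep)) {
    rec <- tryCatch(jsonlite::fromJSON(lines[keep[i]]),
                    error = function(e) stop("malformed JSONL record at line ",
                                             keep[i], ": ", conditionMessage(e)))
    if (is.null(rec$segment_id) || is.null(rec$text))
      stop("malformed JSONL record at line ", keep[i],
           ": missing segment_id or text")
    recs[[i]] <- rec
  }
  get <- function(f, default) vapply(seq_along(recs), function(i) {
    v <- recs[[i]][[f]]
    if (is.null(v)) default(i) else v
  }, FUN.VALUE = if (f == "sequence_index") integer(1) else character(1))
  narrative_segments(
    segment_id = get("segment_id", function(i) stop("unreachable")),
    session_id = get("session_id", function(i) "s1"),
    sequence_index = get("sequence_index", function(i) i - 1L),
    text = get("text", function(i) stop("unreachable"))
  )
}

#' Normalized timestamp
#'
#' @param kind One of `"absolute"`, `"relative_resolved"`,
#'   `"historical_mapped"`, `"unknown"`.
#' @param value Calendar year (integer) or `NA` when kind is `"unknown"`.
#' @param confidence Real in \[0, 1\]; defaults to 1 for absolute values.
#' @param flagged_for_review Logical; `TRUE` only for historical matches in
#'   the human-review confidence band \[0.70, 0.85\].
#' @return An object of class `event_timestamp`.
#' @export
event_timestamp <- function(kind = "unknown", value = NA_integer_,
                            confidence = 1, flagged_for_review = FALSE) {
  kind <- match.arg(kind, c("absolute", "relative_resolved",
                            "historical_mapped", "unknown"))
  if (kind == "unknown" && !is.na(value))
    stop("kind 'unknown' must not carry a value")
  if (kind != "unknown" && is.na(value))
    stop("kind '", kind, "' requires a value")
  if (confidence < 0 || confidence > 1) stop("confidence must be in [0, 1]")
  if (flagged_for_review && (confidence < 0.70 || confidence > 0.85))
    stop("flagged timestamps must have confidence in [0.70, 0.85]")
  structure(list(kind = kind, value = if (is.na(value)) NA_integer_ else
                   as.integer(value),
                 confidence = confidence,
                 flagged_for_review = isTRUE(flagged_for_review)),
            class = "event_timestamp")
}

#' @export
print.event_timestamp <- function(x, ...) {
  cat(sprintf("<timestamp %s%s conf=%.2f%s>\n", x$kind,
              if (is.na(x$value)) "" else paste0(" ", x$value),
              x$confidence, if (x$flagged_for_review) " FLAGGED" else ""))
  invisible(x)
}

is_dated <- function(ts) ts$kind != "unknown"

#' Structured life event
#'
#' The six-element event representation: type, trigger word, time, location,
#' participants, and a short extractive summary.
#'
#' @param event_id Unique id string.
#' @param event_type Type label from the matching template.
#' @param trigger Non-empty trigger word or phrase.
#' @param time An [event_timestamp()].
#' @param location Optional string (`NA` when absent).
#' @param participants Character vector (possibly empty).
#' @param summary Character vector of at most 3 sentences.
#' @param source_segment_ids Ids of the segments the event was extracted from.
#' @param source_sequence_index Narrative order of the earliest source
#'   segment; used for tie-breaking.
#' @param time_raw Raw time token as found in the text (`NA` if none).
#' @return An object of class `structured_event`.
#' @export
structured_event <- function(event_id, event_type, trigger,
                             time = event_timestamp(),
                             location = NA_character_,
                             participants = character(),
                             summary = character(),
                             source_segment_ids = character(),
                             source_sequence_index = NA_integer_,
                             time_raw = NA_character_) {
  if (!nzchar(trimws(trigger))) stop("trigger must be non-empty")
  if (length(summary) > 3) stop("summary has at most 3 sentences")
  stopifnot(inherits(time, "event_timestamp"))
  structure(list(event_id = as.character(event_id),
                 event_type = as.character(event_type),
                 trigger = trigger, time = time,
                 location = location,
                 participants = as.character(participants),
                 summary = as.character(summary),
                 source_segment_ids = as.character(source_segment_ids),
                 source_sequence_index = as.integer(source_sequence_index),
                 time_raw = time_raw),
            class = "structured_event")
}

#' @export
print.structured_event <- function(x, ...) {
  cat(sprintf("<event %s [%s] trigger='%s' %s%s>\n", x$event_id, x$event_type,
              x$trigger, x$time$kind,
              if (is.na(x$time$value)) "" else paste0(" ", x$time$value)))
  invisible(x)
}

event_ids <- function(events) vapply(events, `[[`, character(1), "event_id")

#' Event feature matrix
#'
#' The n x m matrix of event feature vectors (one row per event) feeding the
#' relevance model.
#'
#' @param matrix Numeric n x m matrix, no all-zero rows.
#' @param event_ids Character vector of n ids matching row order.
#' @return Numeric matrix of class `event_feature_matrix` with rownames set
#'   to the event ids.
#' @export
event_feature_matrix <- function(matrix, event_ids) {
  m <- as.matrix(matrix)
  if (nrow(m) < 1) stop("feature matrix needs at least one row")
  if (length(event_ids) != nrow(m)) stop("event_ids length must match rows")
  if (any(rowSums(abs(m)) == 0)) stop("feature matrix has an all-zero row")
  rownames(m) <- as.character(event_ids)
  class(m) <- c("event_feature_matrix", class(m))
  m
}

#' Event correlation matrix
#'
#' Symmetric n x n matrix of pairwise relevance values in \[0, 1\] with unit
#' diagonal; pairs never co-clustered by either view carry 0.
#'
#' @param values Numeric n x n matrix.
#' @param event_ids Character vector of n ids.
#' @return Matrix of class `correlation_matrix`.
#' @export
correlation_matrix <- function(values, event_ids) {
  v <- as.matrix(values)
  if (nrow(v) != ncol(v)) stop("correlation matrix must be square")
  if (length(event_ids) != nrow(v)) stop("event_ids length must match")
  if (any(v < -1e-9) || any(v > 1 + 1e-9))
    stop("correlation values must lie in [0, 1]")
  if (max(abs(v - t(v))) > 1e-9) stop("correlation matrix must be symmetric")
  if (max(abs(diag(v) - 1)) > 1e-9) stop("correlation diagonal must be 1")
  v <- (v + t(v)) / 2
  v[v < 0] <- 0; v[v > 1] <- 1
  dimnames(v) <- list(event_ids, event_ids)
  class(v) <- c("correlation_matrix", class(v))
  v
}

#' Event timeline
#'
#' Ordered event sequence with anchor provenance. Positions are 0-based;
#' virtual start/end nodes used by the insertion algorithm are positional
#' conventions and are never stored.
#'
#' @param event_id Character vector in timeline order.
#' @param kind,value,confidence,flagged Timestamp columns (parallel vectors).
#' @param anchored Logical; `TRUE` for backbone (dated) entries.
#' @param position_score Insertion score for greedily inserted entries
#'   (`NA` for backbone entries).
#' @return A `data.frame` of class `event_timeline`.
#' @export
event_timeline <- function(event_id = character(), kind = character(),
                           value = integer(), confidence = numeric(),
                           flagged = logical(), anchored = logical(),
                           position_score = rep(NA_real_, length(event_id))) {
  df <- data.frame(event_id = as.character(event_id),
                   kind = as.character(kind),
                   value = as.integer(value),
                   confidence = as.numeric(confidence),
                   flagged = as.logical(flagged),
                   anchored = as.logical(anchored),
                   position_score = as.numeric(position_score),
                   stringsAsFactors = FALSE)
  validate_timeline(df)
}

validate_timeline <- function(df) {
  if (anyDuplicated(df$event_id))
    stop("an event appears more than once in the timeline: ",
         df$event_id[duplicated(df$event_id)][1])
  av <- df$value[df$anchored]
  if (length(av) > 1 && any(diff(av) < 0))
    stop("anchored timestamps must be non-decreasing along the timeline")
  class(df) <- c("event_timeline", "data.frame")
  df
}

#' @export
print.event_timeline <- function(x, ...) {
  cat(sprintf("<event_timeline: %d events, %d anchored>\n",
              nrow(x), sum(x$anchored)))
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 10))
  invisible(x)
}

#' Write a timeline as JSONL
#'
#' One record per timeline position with fields `position`, `event_id`,
#' `kind`, `value`, `anchored`, `flagged`, `summary`.
#'
#' @param timeline An [event_timeline()].
#' @param events List of [structured_event()]s resolving every timeline id.
#' @param path Output path.
#' @export
write_timeline <- function(timeline, events, path) {
  ids <- event_ids(events)
  missing <- setdiff(timeline$event_id, ids)
  if (length(missing))
    stop("timeline references unknown event ids: ",
         paste(missing, collapse = ", "))
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines("# event timeline (JSONL); position is 0-based", con)
  if (nrow(timeline) == 0) return(invisible(NULL))
  for (i in seq_len(nrow(timeline))) {
    ev <- events[[match(timeline$event_id[i], ids)]]
    rec <- list(position = i - 1L,
                event_id = timeline$event_id[i],
                kind = timeline$kind[i],
                value = timeline$value[i],
                confidence = timeline$confidence[i],
                flagged = timeline$flagged[i],
                anchored = timeline$anchored[i],
                position_score = timeline$position_score[i],
                summary = paste(ev$summary, collapse = " "))
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, na = "null",
                                digits = NA), con)
  }
  invisible(NULL)
}

#' Read a timeline written by [write_timeline()]
#'
#' @param path Path to the JSONL file.
#' @return An [event_timeline()] (summaries are not restored into events).
#' @export
read_timeline <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  if (!length(lines)) return(event_timeline())
  recs <- lapply(seq_along(lines), function(i)
    tryCatch(jsonlite::fromJSON(lines[[i]]),
             error = function(e) stop("malformed timeline record at line ",
                                      i, ": ", conditionMessage(e))))
  recs <- recs[order(vapply(recs, function(r) r$position, numeric(1)))]
  g <- function(f, cast, default) vapply(recs, function(r) {
    v <- r[[f]]
    if (is.null(v) || length(v) == 0) default else cast(v)
  }, FUN.VALUE = cast(default))
  event_timeline(event_id = g("event_id", as.character, NA_character_),
                 kind = g("kind", as.character, "unknown"),
                 value = g("value", as.integer, NA_integer_),
                 confidence = g("confidence", as.numeric, NA_real_),
                 flagged = g("flagged", as.logical, FALSE),
                 anchored = g("anchored", as.logical, FALSE),
                 position_score = g("position_score", as.numeric, NA_real_))
}

#' Read a historical event table
#'
#' Tab-separated, three columns: `name`, `year`, `description`. The shipped
#' synthetic fixture (see `system.file("extdata",
#' "historical_db_synthetic.tsv", package = "eventline")`) mimics the shape of
#' a 20th-century anchor database.
#'
#' @param path Path to the TSV file (a header line is allowed).
#' @return A `data.frame` with columns `name` (unique), `year` (integer in
#'   \[1900, 2100\]), `description`.
#' @export
read_historical_db <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                          colClasses = "character", fileEncoding = "UTF-8")
  if (ncol(df) != 3) stop("historical DB must have exactly 3 columns")
  names(df) <- c("name", "year", "description")
  yr <- suppressWarnings(as.integer(df$year))
  if (anyNA(yr)) stop("non-integer year in historical DB: ",
                      df$year[which(is.na(yr))[1]])
  df$year <- yr
  validate_historical_db(df)
}

validate_historical_db <- function(df) {
  if (anyDuplicated(df$name))
    stop("duplicate historical event name: ",
         df$name[duplicated(df$name)][1])
  if (any(df$year < 1900 | df$year > 2100))
    stop("historical event years must lie in [1900, 2100]")
  df
}

write_historical_db <- function(db, path) {
  utils::write.table(db, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(NULL)
}
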