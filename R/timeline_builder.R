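# Timeline building: temporal normalization, historical anchoring, dated
# backbone construction, and relevance-based greedy insertion of undated
# events.

.number_words <- c(one = 1, two = 2, three = 3, four = 4, five = 5, six = 6,
                   seven = 7, eight = 8, nine = 9, ten = 10, eleven = 11,
                   twelve = 12, fifteen = 15, twenty = 20, thirty = 30,
                   forty = 40, fifty = 50)
.cjk_digits <- c("零" = 0, "一" = 1, "二" = 2, "三" = 3, "四" = 4, "五" = 5,
                 "六" = 6, "七" = 7, "八" = 8, "九" = 9)

# Parse a small Chinese numeral (up to 99, e.g. 三, 十, 二十五).
.parse_cjk_number <- function(s) {
  chars <- strsplit(s, "")[[1]]
  if (identical(chars, "十")) return(10)
  ten_pos <- which(chars == "十")
  if (!length(ten_pos)) {
    if (length(chars) == 1 && chars %in% names(.cjk_digits))
      return(unname(.cjk_digits[chars]))
    return(NA_real_)
  }
  tens <- if (ten_pos[1] == 1) 1 else .cjk_digits[chars[1]]
  units <- if (ten_pos[1] < length(chars)) .cjk_digits[chars[length(chars)]]
           else 0
  if (anyNA(c(tens, units))) return(NA_real_)
  unname(tens * 10 + units)
}

#' Normalize a temporal expression
#'
#' Recognizes explicit 4-digit years ("1962"), relative expressions of the
#' form "N years ago" (digits, English number words, or Chinese "N年前"),
#' resolved against the narration reference year. Everything else —
#' including vague adverbs such as "back then" — yields kind `"unknown"`
#' and is left for relevance-based sequencing.
#'
#' @param raw_expression Non-empty string.
#' @param narration_reference_year Year the narration took place.
#' @return An [event_timestamp()].
#' @export
normalize_time <- function(raw_expression, narration_reference_year) {
  stopifnot(nzchar(raw_expression))
  s <- trimws(raw_expression)
  m <- regmatches(s, regexpr("\\b(1[89][0-9]{2}|20[0-9]{2}|2100)\\b", s))
  if (length(m))
    return(event_timestamp("absolute", as.integer(m[1]), confidence = 1))
  rel <- regexec("([0-9]+|[a-z]+) years? ago", tolower(s), perl = TRUE)[[1]]
  if (rel[1] != -1) {
    tok <- substr(tolower(s), rel[2], rel[2] + attr(rel, "match.length")[2] - 1)
    nyr <- suppressWarnings(as.numeric(tok))
    if (is.na(nyr) && tok %in% names(.number_words))
      nyr <- .number_words[[tok]]
    if (!is.na(nyr))
      return(event_timestamp("relative_resolved",
                             narration_reference_year - nyr, confidence = 1))
  }
  cjk <- regexec("([零一二三四五六七八九十0-9]+)年前", s, perl = TRUE)[[1]]
  if (cjk[1] != -1) {
    tok <- substr(s, cjk[2], cjk[2] + attr(cjk, "match.length")[2] - 1)
    nyr <- suppressWarnings(as.numeric(tok))
    if (is.na(nyr)) nyr <- .parse_cjk_number(tok)
    if (!is.na(nyr))
      return(event_timestamp("relative_resolved",
                             narration_reference_year - nyr, confidence = 1))
  }
  event_timestamp("unknown")
}

#' Match an event against the historical anchor database
#'
#' Embeds the event text and every database description and takes the
#' best-similarity entry. Similarity above `accept` assigns a
#' `historical_mapped` timestamp outright; similarity in
#' \[`flag_low`, `accept`\] assigns the timestamp flagged for
#' human-in-the-loop review with confidence equal to the similarity; below
#' `flag_low` no timestamp is assigned.
#'
#' @param event A [structured_event()].
#' @param db Historical event table (see [read_historical_db()]).
#' @param embedder An embedder.
#' @param accept Acceptance threshold (default 0.85).
#' @param flag_low Lower edge of the review band (default 0.70).
#' @return `NULL` when no match clears `flag_low`; otherwise a list with
#'   `name`, `year`, `similarity`, and `timestamp`.
#' @export
match_anchor <- function(event, db, embedder, accept = 0.85,
                         flag_low = 0.70) {
  stopifnot(flag_low < accept)
  if (is.null(db) || nrow(db) == 0) return(NULL)
  ev_vec <- embedder$embed(event_text(event))[1, ]
  db_mat <- embedder$embed(paste(db$name, db$description))
  sims <- vapply(seq_len(nrow(db)), function(i)
    .cosine(ev_vec, db_mat[i, ]), numeric(1))
  best <- which.max(sims)
  s <- sims[best]
  if (s < flag_low) return(NULL)
  flagged <- s <= accept
  ts <- event_timestamp("historical_mapped", db$year[best],
                        confidence = if (flagged) s else 1,
                        flagged_for_review = flagged)
  list(name = db$name[best], year = db$year[best], similarity = s,
       timestamp = ts)
}

#' Resolve event timestamps
#'
#' Applies [normalize_time()] to each event's raw time token and, for events
#' still undated, [match_anchor()] against the historical database.
#'
#' @param events List of [structured_event()]s.
#' @param reference_year Narration reference year.
#' @param db Optional historical database.
#' @param embedder Embedder used for anchoring.
#' @param accept,flag_low Anchor thresholds.
#' @return The events with `time` filled in where resolvable.
#' @export
resolve_times <- function(events, reference_year, db = NULL,
                          embedder = hash_embedder(), accept = 0.85,
                          flag_low = 0.70) {
  lapply(events, function(ev) {
    if (!is.na(ev$time_raw)) {
      ts <- normalize_time(ev$time_raw, reference_year)
      if (is_dated(ts)) { ev$time <- ts; return(ev) }
    }
    if (!is.null(db)) {
      hit <- match_anchor(ev, db, embedder, accept, flag_low)
      if (!is.null(hit)) ev$time <- hit$timestamp
    }
    ev
  })
}

#' Build the dated timeline backbone
#'
#' Sorts events carrying a resolvable timestamp by year (stable: equal
#' years keep the narrative order of their earliest source segment).
#' Undated events are left for [insert_undated()].
#'
#' @param events List of [structured_event()]s.
#' @param exclude_flagged Drop review-flagged historical anchors from the
#'   backbone (they then join the undated pool).
#' @return An [event_timeline()] of the dated events only.
#' @export
build_backbone <- function(events, exclude_flagged = FALSE) {
  dated <- Filter(function(e) {
    is_dated(e$time) && !(exclude_flagged && e$time$flagged_for_review)
  }, events)
  if (!length(dated)) return(event_timeline())
  yrs <- vapply(dated, function(e) e$time$value, integer(1))
  seqi <- vapply(dated, function(e) {
    v <- e$source_sequence_index
    if (is.na(v)) .Machine$integer.max else v
  }, integer(1))
  ord <- order(yrs, seqi)
  dated <- dated[ord]
  tl <- event_timeline(
    event_id = event_ids(dated),
    kind = vapply(dated, function(e) e$time$kind, character(1)),
    value = yrs[ord],
    confidence = vapply(dated, function(e) e$time$confidence, numeric(1)),
    flagged = vapply(dated, function(e) e$time$flagged_for_review,
                     logical(1)),
    anchored = rep(TRUE, length(dated)))
  # narrative order of each backbone entry, used for insertion tie-breaking
  attr(tl, "sequence_index") <- ifelse(seqi[ord] == .Machine$integer.max,
                                       NA_integer_, seqi[ord])
  tl
}

# Score all n+1 insertion gaps of one undated event against the current
# timeline. Gap i (0-based, 0..n) sits between entries i and i+1; virtual
# start/end nodes contribute relevance 0.
.gap_scores <- function(rel_row, backbone_ids, rel, alpha) {
  n <- length(backbone_ids)
  vapply(0:n, function(i) {
    left <- if (i >= 1) rel[backbone_ids[i], rel_row] else 0
    right <- if (i < n) rel[rel_row, backbone_ids[i + 1]] else 0
    alpha * left + (1 - alpha) * right
  }, numeric(1))
}

#' Greedily insert undated events by relevance
#'
#' Undated events are processed in transcript order. Each is placed at the
#' gap `i` (0 .. n, with virtual start and end nodes) maximizing
#' `alpha * Rel(e_i, e_u) + (1 - alpha) * Rel(e_u, e_{i+1})`; relevance to a
#' virtual node is 0. Exact ties go to the gap whose flanking real event is
#' nearest in transcript `sequence_index` to the undated event (then the
#' earlier gap). Each insertion immediately extends the timeline seen by
#' subsequent events; the dated backbone's internal order is never changed.
#'
#' @param backbone An [event_timeline()] from [build_backbone()].
#' @param undated List of [structured_event()]s (none may already be in the
#'   backbone).
#' @param rel A [correlation_matrix()] covering all involved events.
#' @param alpha Left/right relevance weight in \[0, 1\] (default 0.5).
#' @return The completed [event_timeline()].
#' @export
insert_undated <- function(backbone, undated, rel, alpha = 0.5) {
  stopifnot(alpha >= 0, alpha <= 1)
  if (!length(undated)) return(backbone)
  und_ids <- event_ids(undated)
  clash <- intersect(und_ids, backbone$event_id)
  if (length(clash))
    stop("event present in both backbone and undated pool: ", clash[1])
  all_ids <- c(backbone$event_id, und_ids)
  missing <- setdiff(all_ids, rownames(rel))
  if (length(missing))
    stop("correlation matrix does not cover: ",
         paste(missing, collapse = ", "))
  tl <- as.data.frame(backbone)
  # per-timeline-entry narrative order for tie-breaking
  tl_seq <- attr(backbone, "sequence_index")
  if (is.null(tl_seq)) tl_seq <- rep(NA_integer_, nrow(tl))
  ord <- order(vapply(undated, function(e) {
    v <- e$source_sequence_index
    if (is.na(v)) .Machine$integer.max else v
  }, integer(1)))
  for (u in ord) {
    ev <- undated[[u]]
    scores <- .gap_scores(ev$event_id, tl$event_id, rel, alpha)
    best <- max(scores)
    cand <- which(abs(scores - best) < 1e-12) - 1L  # 0-based gaps
    if (length(cand) > 1 && nrow(tl) > 0 &&
        !is.na(ev$source_sequence_index)) {
      prox <- vapply(cand, function(i) {
        flanks <- c(if (i >= 1) tl_seq[i],
                    if (i < nrow(tl)) tl_seq[i + 1])
        flanks <- flanks[!is.na(flanks)]
        if (!length(flanks)) return(Inf)
        min(abs(flanks - ev$source_sequence_index))
      }, numeric(1))
      cand <- cand[order(prox, cand)]
    }
    pos <- cand[1]
    new_row <- data.frame(event_id = ev$event_id, kind = ev$time$kind,
                          value = ev$time$value,
                          confidence = ev$time$confidence,
                          flagged = ev$time$flagged_for_review,
                          anchored = FALSE, position_score = best,
                          stringsAsFactors = FALSE)
    if (pos == 0) {
      tl <- rbind(new_row, tl)
      tl_seq <- c(ev$source_sequence_index, tl_seq)
    } else if (pos == nrow(tl)) {
      tl <- rbind(tl, new_row)
      tl_seq <- c(tl_seq, ev$source_sequence_index)
    } else {
      tl <- rbind(tl[1:pos, ], new_row, tl[(pos + 1):nrow(tl), ])
      tl_seq <- c(tl_seq[1:pos], ev$source_sequence_index,
                  tl_seq[(pos + 1):length(tl_seq)])
    }
  }
  rownames(tl) <- NULL
  validate_timeline(tl)
}

#' Build the full timeline
#'
#' Backbone sort of the dated events followed by greedy insertion of the
#' undated pool.
#'
#' @inheritParams insert_undated
#' @param events All events, dated or not (after [resolve_times()]).
#' @param exclude_flagged See [build_backbone()].
#' @return An [event_timeline()] over all events.
#' @export
build_timeline <- function(events, rel, alpha = 0.5,
                           exclude_flagged = FALSE) {
  backbone <- build_backbone(events, exclude_flagged)
  undated <- Filter(function(e) !(e$event_id %in% backbone$event_id), events)
  insert_undated(backbone, undated, rel, alpha)
}
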