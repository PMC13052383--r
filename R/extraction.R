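#' Event template
#'
#' Templates drive extraction: a trigger lexicon names the words that signal
#' an event of this type, and optional element patterns (regular expressions
#' with one capture group) pull out time, location and participant strings.
#'
#' @param event_type Type label.
#' @param triggers Non-empty character vector of trigger words.
#' @param patterns Named list of regexes for roles `time`, `location`,
#'   `participant` (any subset).
#' @return An object of class `event_template`.
#' @export
event_template <- function(event_type, triggers, patterns = list()) {
  if (length(triggers) == 0) stop("trigger_lexicon must be non-empty")
  bad <- setdiff(names(patterns), c("time", "location", "participant"))
  if (length(bad)) stop("unknown element roles: ", paste(bad, collapse = ", "))
  structure(list(event_type = as.character(event_type),
                 triggers = tolower(as.character(triggers)),
                 patterns = patterns),
            class = "event_template")
}

#' Read event templates from a JSON config
#'
#' The file holds an array of objects `{event_type, triggers, patterns}`.
#'
#' @param path Path to the JSON file.
#' @return List of [event_template()]s.
#' @export
read_templates <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  lapply(raw, function(r)
    event_template(r$event_type, unlist(r$triggers),
                   lapply(r$patterns, unlist)))
}

#' Built-in life-event templates
#'
#' A small template set covering the life-course event types emitted by
#' [generate_story()]: birth, schooling, marriage, relocation, work,
#' retirement, loss, and celebration.
#'
#' @return List of [event_template()]s.
#' @export
default_event_templates <- function() {
  pat <- list(
    time = "\\b(1[89][0-9]{2}|20[0-9]{2}|[a-z]+ years ago|\\d+ years ago)\\b",
    location = "\\b(?:in|at|to) ([A-Z][a-z]+(?: [A-Z][a-z]+)?)(?=[ ,.]|$)",
    participant = "\\b(?:with|married|met) ([A-Z][a-z]+(?: [A-Z][a-z]+)?)(?=[ ,.]|$)"
  )
  list(
    event_template("birth", c("born"), pat),
    event_template("education", c("school", "studied", "graduated"), pat),
    event_template("marriage", c("married", "wedding"), pat),
    event_template("relocation", c("moved", "settled"), pat),
    event_template("career", c("worked", "job", "factory"), pat),
    event_template("retirement", c("retired"), pat),
    event_template("loss", c("flood", "lost", "died"), pat),
    event_template("celebration", c("celebrated", "reunion"), pat)
  )
}

# ---- coreference -----------------------------------------------------------

# Candidate mentions: maximal runs of capitalized words (proper-name
# heuristic). Returns a data.frame with segment_id, start, end (half-open,
# 0-based), text, and the token offset of the mention in the session stream.
.find_mentions <- function(segments) {
  out <- list()
  tok_base <- 0L
  ord <- order(segments$session_id, segments$sequence_index)
  for (r in ord) {
    text <- segments$text[r]
    m <- gregexpr("\\b[A-Z][a-z]+(?: [A-Z][a-z]+)*\\b", text, perl = TRUE)[[1]]
    # token offsets: count tokens before each character position
    toks <- tokenize_text(text)
    if (m[1] != -1) {
      for (k in seq_along(m)) {
        start <- m[k]; len <- attr(m, "match.length")[k]
        mention_text <- substr(text, start, start + len - 1)
        ntok_before <- length(tokenize_text(substr(text, 1, start - 1)))
        out[[length(out) + 1L]] <- data.frame(
          segment_id = segments$segment_id[r],
          start = start - 1L, end = start - 1L + len,
          text = mention_text,
          token_offset = tok_base + ntok_before,
          stringsAsFactors = FALSE)
      }
    }
    tok_base <- tok_base + length(toks)
  }
  if (!length(out)) return(data.frame(segment_id = character(),
                                      start = integer(), end = integer(),
                                      text = character(),
                                      token_offset = integer()))
  do.call(rbind, out)
}

#' Resolve coreference between candidate mentions
#'
#' Compares candidate mentions pairwise within a sliding token window:
#' mentions whose embedded texts have cosine similarity at or above
#' `threshold` are linked. Chains are the transitive closure of accepted
#' links.
#'
#' @param segments A [narrative_segments()] data frame.
#' @param embedder An embedder (see [hash_embedder()]).
#' @param window_tokens Mentions farther apart than this many tokens in the
#'   session stream are never compared.
#' @param threshold Cosine acceptance threshold in (0, 1\].
#' @return A `data.frame` of class `mention_links` with columns
#'   `segment_a`, `start_a`, `end_a`, `segment_b`, `start_b`, `end_b`,
#'   `similarity`; attribute `mentions` holds the mention table and
#'   `chains` the chain id per mention.
#' @export
resolve_coreference <- function(segments, embedder, window_tokens = 512L,
                                threshold = 0.8) {
  stopifnot(threshold > 0, threshold <= 1, window_tokens >= 1)
  empty <- data.frame(segment_a = character(), start_a = integer(),
                      end_a = integer(), segment_b = character(),
                      start_b = integer(), end_b = integer(),
                      similarity = numeric(), stringsAsFactors = FALSE)
  mentions <- .find_mentions(segments)
  n <- nrow(mentions)
  if (n < 2) {
    res <- empty
    attr(res, "mentions") <- mentions
    attr(res, "chains") <- seq_len(n)
    class(res) <- c("mention_links", "data.frame")
    return(res)
  }
  emb <- embedder$embed(mentions$text)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  links <- list()
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (abs(mentions$token_offset[j] - mentions$token_offset[i]) >
          window_tokens) next
      s <- .cosine(emb[i, ], emb[j, ])
      if (s >= threshold) {
        links[[length(links) + 1L]] <- data.frame(
          segment_a = mentions$segment_id[i], start_a = mentions$start[i],
          end_a = mentions$end[i],
          segment_b = mentions$segment_id[j], start_b = mentions$start[j],
          end_b = mentions$end[j], similarity = s,
          stringsAsFactors = FALSE)
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[rj] <- ri
      }
    }
  }
  res <- if (length(links)) do.call(rbind, links) else empty
  attr(res, "mentions") <- mentions
  attr(res, "chains") <- vapply(seq_len(n), find, integer(1))
  class(res) <- c("mention_links", "data.frame")
  res
}

# Map a mention text to its chain representative (earliest mention of the
# chain in narration order). Identity when no chain contains it.
.chain_representative <- function(links, text) {
  mentions <- attr(links, "mentions")
  chains <- attr(links, "chains")
  if (is.null(mentions) || nrow(mentions) == 0) return(text)
  hit <- which(mentions$text == text)
  if (!length(hit)) return(text)
  ch <- chains[hit[1]]
  members <- which(chains == ch)
  mentions$text[members[1]]  # mentions are stored in narration order
}

# ---- event extraction ------------------------------------------------------

.split_sentences <- function(text) {
  s <- strsplit(text, "(?<=[.!?。！？])\\s+", perl = TRUE)[[1]]
  s[nzchar(trimws(s))]
}

#' Extract structured events from segments
#'
#' One event is produced per trigger occurrence per matching template.
#' Element patterns fill time (raw token only; normalization happens later),
#' location and participants; participant strings are canonicalized to their
#' coreference-chain representative. When several templates claim the same
#' trigger occurrence all matches are reported and the ambiguity recorded in
#' the `ambiguities` attribute.
#'
#' @param segments A [narrative_segments()] data frame.
#' @param templates Non-empty list of [event_template()]s.
#' @param links Optional [resolve_coreference()] result.
#' @return List of [structured_event()]s (ids `ev-%06d`).
#' @export
extract_events <- function(segments, templates, links = NULL) {
  if (length(templates) == 0) stop("templates must be non-empty")
  events <- list()
  ambiguities <- list()
  counter <- 0L
  for (r in seq_len(nrow(segments))) {
    text <- segments$text[r]
    words <- tolower(tokenize_text(text))
    sentences <- .split_sentences(text)
    hits_by_word <- list()
    for (ti in seq_along(templates)) {
      tpl <- templates[[ti]]
      for (w in unique(intersect(words, tpl$triggers))) {
        hits_by_word[[w]] <- c(hits_by_word[[w]], ti)
      }
    }
    for (w in names(hits_by_word)) {
      tis <- hits_by_word[[w]]
      if (length(tis) > 1)
        ambiguities[[length(ambiguities) + 1L]] <- list(
          segment_id = segments$segment_id[r], trigger = w,
          event_types = vapply(tis, function(ti)
            templates[[ti]]$event_type, character(1)))
      for (ti in tis) {
        tpl <- templates[[ti]]
        counter <- counter + 1L
        time_raw <- .first_capture(tpl$patterns$time, text, whole = TRUE)
        loc <- .first_capture(tpl$patterns$location, text)
        part <- .first_capture(tpl$patterns$participant, text)
        if (!is.na(part) && !is.null(links))
          part <- .chain_representative(links, part)
        trig_sent <- sentences[grepl(w, tolower(sentences), fixed = TRUE)]
        if (!length(trig_sent)) trig_sent <- sentences[1]
        events[[length(events) + 1L]] <- structured_event(
          event_id = sprintf("ev-%06d", counter),
          event_type = tpl$event_type,
          trigger = w,
          time = event_timestamp(),
          location = loc,
          participants = if (is.na(part)) character() else part,
          summary = utils::head(trig_sent, 3),
          source_segment_ids = segments$segment_id[r],
          source_sequence_index = segments$sequence_index[r],
          time_raw = time_raw)
      }
    }
  }
  attr(events, "ambiguities") <- ambiguities
  events
}

# First regex capture group (or whole match when whole=TRUE and the pattern
# has no group); NA when the pattern is NULL or does not match.
.first_capture <- function(pattern, text, whole = FALSE) {
  if (is.null(pattern)) return(NA_character_)
  m <- regexec(pattern, text, perl = TRUE)[[1]]
  if (m[1] == -1) return(NA_character_)
  pick <- if (length(m) > 1) 2L else 1L
  if (whole && length(m) > 1 && m[2] == -1) pick <- 1L
  substr(text, m[pick], m[pick] + attr(m, "match.length")[pick] - 1)
}

# ---- summary selection -----------------------------------------------------

# Bag-of-words cosine between two sentences; used by MMR redundancy term.
.bow_cosine <- function(a, b) {
  ta <- table(tolower(tokenize_text(a)))
  tb <- table(tolower(tokenize_text(b)))
  common <- intersect(names(ta), names(tb))
  if (!length(common)) return(0)
  num <- sum(as.numeric(ta[common]) * as.numeric(tb[common]))
  num / (sqrt(sum(as.numeric(ta)^2)) * sqrt(sum(as.numeric(tb)^2)))
}

#' TF-IDF centroid salience scores
#'
#' Shipped salience scorer for [select_summary()]: each sentence is scored by
#' the cosine of its TF-IDF vector with the centroid of all candidate
#' sentences.
#'
#' @param sentences Character vector.
#' @return Numeric vector of scores in \[0, 1\].
#' @export
tfidf_salience <- function(sentences) {
  toks <- lapply(sentences, function(s) tolower(tokenize_text(s)))
  vocab <- unique(unlist(toks))
  if (!length(vocab)) return(rep(0, length(sentences)))
  df <- vapply(vocab, function(v)
    sum(vapply(toks, function(tk) v %in% tk, logical(1))), numeric(1))
  idf <- log(1 + length(sentences) / df)
  tf <- t(vapply(toks, function(tk)
    as.numeric(table(factor(tk, levels = vocab))), numeric(length(vocab))))
  if (length(vocab) == 1) tf <- matrix(tf, ncol = 1)
  w <- tf * rep(idf, each = nrow(tf))
  centroid <- colMeans(w)
  vapply(seq_len(nrow(w)), function(i) .cosine(w[i, ], centroid), numeric(1))
}

#' Select an event summary by maximal marginal relevance
#'
#' Greedy MMR: the first pick is the most salient sentence; each subsequent
#' pick maximizes `diversity_weight * salience - (1 - diversity_weight) *
#' max cosine similarity to the sentences already picked`. With
#' `diversity_weight = 1` this reduces to top-k by salience.
#'
#' @param event A [structured_event()] (used only for its identity; the
#'   trade-off is agnostic of the event).
#' @param candidate_sentences Character vector.
#' @param salience Numeric vector, same length.
#' @param k Maximum number of sentences (default 3).
#' @param diversity_weight Trade-off in \[0, 1\] (default 0.7).
#' @return Up to `k` sentences in pick order.
#' @export
select_summary <- function(event, candidate_sentences, salience, k = 3L,
                           diversity_weight = 0.7) {
  stopifnot(length(candidate_sentences) == length(salience), k >= 1)
  n <- length(candidate_sentences)
  if (n == 0) return(character())
  picked <- integer()
  avail <- seq_len(n)
  while (length(picked) < min(k, n)) {
    if (!length(picked)) {
      best <- avail[which.max(salience[avail])]
    } else {
      scores <- vapply(avail, function(i) {
        red <- max(vapply(picked, function(p)
          .bow_cosine(candidate_sentences[i], candidate_sentences[p]),
          numeric(1)))
        diversity_weight * salience[i] - (1 - diversity_weight) * red
      }, numeric(1))
      best <- avail[which.max(scores)]
    }
    picked <- c(picked, best)
    avail <- setdiff(avail, best)
  }
  candidate_sentences[picked]
}

# ---- event embedding -------------------------------------------------------

event_text <- function(ev) {
  paste(c(ev$trigger, ev$summary,
          if (!is.na(ev$location)) ev$location,
          ev$participants), collapse = ". ")
}

#' Embed structured events into a feature matrix
#'
#' Row i is the embedding of the concatenation "trigger. summary. location.
#' participants" of event i.
#'
#' @param events Non-empty list of [structured_event()]s.
#' @param embedder An embedder.
#' @return An [event_feature_matrix()] of shape n x `embedder$dimension`.
#' @export
embed_events <- function(events, embedder) {
  if (!length(events)) stop("events must be non-empty")
  texts <- vapply(events, event_text, character(1))
  m <- embedder$embed(texts)
  if (ncol(m) != embedder$dimension)
    stop("embedder contract violation: dimension mismatch")
  event_feature_matrix(m, event_ids(events))
}
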