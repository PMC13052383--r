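# Synthetic life-story generator: fragmented single-narrator segments with
# redundant near-duplicate mentions, a mix of absolute dates, relative
# expressions, historical references and fully undated events, plus the
# matching ground truth. Everything is driven by one seed.

#' Simulation configuration
#'
#' Fractions use quota (not Bernoulli) sampling so tests can assert exact
#' counts; the three time-mode fractions (undated, relative, historical)
#' must sum to at most 1, the remainder being events with an explicit year.
#'
#' @param n_events Number of ground-truth life events.
#' @param undated_fraction Fraction narrated with no time cue.
#' @param redundancy_rate Fraction narrated twice (near-duplicate paraphrase
#'   without the date — the classic deduplication failure case).
#' @param relative_time_fraction Fraction phrased as "N years ago".
#' @param historical_fraction Fraction referencing a historical anchor event
#'   instead of a date.
#' @param n_clusters Number of life phases (thematic clusters).
#' @param cluster_separation Centroid spacing for
#'   [generate_clustered_features()] companions.
#' @param shuffle Narrate segments in random order (`TRUE`) or
#'   chronologically.
#' @param reference_year Year of the narration (resolves "N years ago").
#' @param birth_year Narrator's birth year; events span the following 80
#'   years.
#' @param seed RNG seed; the corpus is fully determined by it.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(n_events = 20L, undated_fraction = 0.3,
                       redundancy_rate = 0.1,
                       relative_time_fraction = 0.15,
                       historical_fraction = 0.1, n_clusters = 4L,
                       cluster_separation = 5, shuffle = TRUE,
                       reference_year = 2023L, birth_year = 1940L,
                       seed = 1L) {
  fr <- c(undated_fraction, relative_time_fraction, historical_fraction,
          redundancy_rate)
  if (any(fr < 0 | fr > 1)) stop("fractions must lie in [0, 1]")
  if (undated_fraction + relative_time_fraction + historical_fraction > 1)
    stop("time-mode fractions must sum to at most 1")
  if (n_events < n_clusters) stop("n_events must be >= n_clusters")
  structure(list(n_events = as.integer(n_events),
                 undated_fraction = undated_fraction,
                 redundancy_rate = redundancy_rate,
                 relative_time_fraction = relative_time_fraction,
                 historical_fraction = historical_fraction,
                 n_clusters = as.integer(n_clusters),
                 cluster_separation = cluster_separation,
                 shuffle = isTRUE(shuffle),
                 reference_year = as.integer(reference_year),
                 birth_year = as.integer(birth_year),
                 seed = as.integer(seed)),
            class = "sim_config")
}

# Thematic life phases; vocabulary is disjoint from the historical-database
# vocabulary and each phase shares participants/locations/motifs so that
# same-phase events are textually similar.
.life_phases <- list(
  list(name = "childhood", triggers = c("born", "school", "studied"),
       participants = c("Mother", "Teacher Wang"),
       location = "Chuzhou",
       motifs = c("village courtyard", "childhood mornings")),
  list(name = "family", triggers = c("married", "wedding", "celebrated"),
       participants = c("Wei Lan", "Little Hua"),
       location = "Nanjing",
       motifs = c("family banquet", "red lanterns")),
  list(name = "career", triggers = c("worked", "job", "moved"),
       participants = c("Old Chen", "Foreman Liu"),
       location = "Shanghai",
       motifs = c("textile workshop", "morning shifts")),
  list(name = "late_life", triggers = c("retired", "reunion", "celebrated"),
       participants = c("Grandson Ming", "Neighbor Zhao"),
       location = "Hefei",
       motifs = c("quiet garden", "evening walks"))
)

#' Synthetic historical anchor table
#'
#' Small invented table shaped like a 20th-century historical-event anchor
#' database (name, year, description). Vocabulary avoids the built-in
#' template trigger words so anchoring is exercised without trigger
#' collisions. The same table ships as a TSV fixture under
#' `inst/extdata/historical_db_synthetic.tsv`.
#'
#' @return A `data.frame` with columns `name`, `year`, `description`.
#' @export
builtin_historical_db <- function() {
  data.frame(
    name = c("Great River Inundation", "Northern Railway Opening",
             "Coastal Reconstruction Drive", "National Grain Campaign",
             "Southern Bridge Completion", "City Electrification Push",
             "Provincial Harvest Festival", "Eastern Harbor Expansion",
             "Mountain Road Project", "New Calendar Reform"),
    year = c(1954L, 1935L, 1962L, 1958L, 1968L, 1972L, 1984L, 1990L,
             1978L, 1949L),
    description = c(
      "the great river rose over its banks and water covered whole towns",
      "the first northern railway line opened and trains reached the county",
      "coastal districts were rebuilt street by street after the storms",
      "the national grain campaign sent brigades to every commune",
      "the southern bridge was completed and the ferry crossings ended",
      "electric light arrived in the city lanes during the big push",
      "the provincial harvest festival filled the squares with drums",
      "the eastern harbor was expanded and foreign ships began to call",
      "the mountain road project connected the high villages at last",
      "the new calendar reform changed how every household counted days"),
    stringsAsFactors = FALSE)
}

.render_sentence <- function(mode, trigger, participant, location, motif,
                             year, n_ago, hist_row) {
  switch(mode,
    absolute = sprintf("In %d I %s with %s in %s and the %s stayed with me.",
                       year, trigger, participant, location, motif),
    relative = sprintf("I %s with %s in %s, that was %d years ago.",
                       trigger, participant, location, n_ago),
    historical = sprintf("I %s with %s during the %s, when %s.",
                         trigger, participant, hist_row$name,
                         hist_row$description),
    undated = sprintf("I %s with %s in %s near the %s.",
                      trigger, participant, location, motif))
}

.paraphrase_sentence <- function(mode, trigger, participant, location,
                                 motif) {
  # near-duplicate retelling: same trigger and cast, no date token
  sprintf("Like I told you before, I %s with %s back in %s by the %s.",
          trigger, participant, location, motif)
}

#' Generate a synthetic life-story corpus with ground truth
#'
#' Draws `n_events` life events with strictly increasing years along a life
#' course, assigns each to a thematic life phase, renders one sentence per
#' event (time cue per the quota-sampled mode), optionally retells some
#' events as undated near-duplicates, and optionally shuffles the narration
#' order. Fully determined by `config$seed`.
#'
#' @param config A [sim_config()].
#' @return List with `segments` ([narrative_segments()]),
#'   `truth_timeline` (data frame: `event_id`, `year`, `segment_id`,
#'   `position` in chronological order), `truth_clusters` (data frame:
#'   `event_id`, `cluster`), `segment_event` (segment-to-event map incl.
#'   redundant retellings), `historical_db`, and the `config`.
#' @export
generate_story <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_events
  db <- builtin_historical_db()
  years <- sort(sample(seq(config$birth_year + 5,
                           min(config$reference_year - 3,
                               config$birth_year + 80)), n))
  phases <- rep(seq_len(config$n_clusters),
                each = ceiling(n / config$n_clusters))[seq_len(n)]
  n_und <- round(config$undated_fraction * n)
  n_rel <- round(config$relative_time_fraction * n)
  n_hist <- round(config$historical_fraction * n)
  modes <- rep("absolute", n)
  pool <- sample(n)  # quota assignment in one shuffled pass
  if (n_und > 0) modes[pool[seq_len(n_und)]] <- "undated"
  if (n_rel > 0) modes[pool[n_und + seq_len(n_rel)]] <- "relative"
  if (n_hist > 0) modes[pool[n_und + n_rel + seq_len(n_hist)]] <- "historical"

  hist_used <- integer()
  texts <- character(n)
  triggers <- character(n)
  for (i in seq_len(n)) {
    ph <- .life_phases[[(phases[i] - 1) %% length(.life_phases) + 1]]
    triggers[i] <- sample(ph$triggers, 1)
    participant <- sample(ph$participants, 1)
    motif <- sample(ph$motifs, 1)
    hist_row <- NULL
    if (modes[i] == "historical") {
      avail <- setdiff(seq_len(nrow(db)), hist_used)
      # keep event years unique so the true order stays unambiguous
      avail <- avail[!(db$year[avail] %in% years[-i])]
      if (!length(avail)) { modes[i] <- "absolute" } else {
        pick <- avail[which.min(abs(db$year[avail] - years[i]))]
        hist_used <- c(hist_used, pick)
        hist_row <- db[pick, ]
        years[i] <- db$year[pick]  # the anchor defines the true year
      }
    }
    texts[i] <- .render_sentence(modes[i], triggers[i], participant,
                                 ph$location, motif,
                                 year = years[i],
                                 n_ago = config$reference_year - years[i],
                                 hist_row = hist_row)
  }

  event_id <- sprintf("sim-%03d", seq_len(n))
  chrono <- order(years, seq_len(n))
  narration <- if (config$shuffle) sample(n) else chrono
  seg_ids <- sprintf("seg-%03d", seq_len(n))
  segment_of_event <- character(n)
  segment_of_event[narration] <- seg_ids

  # redundant retellings: extra undated segments appended after the story
  n_red <- round(config$redundancy_rate * n)
  red_idx <- if (n_red > 0) sort(sample(n, n_red)) else integer()
  red_texts <- vapply(red_idx, function(i) {
    ph <- .life_phases[[(phases[i] - 1) %% length(.life_phases) + 1]]
    .paraphrase_sentence(modes[i], triggers[i],
                         sample(ph$participants, 1), ph$location,
                         sample(ph$motifs, 1))
  }, character(1))

  segments <- narrative_segments(
    segment_id = c(seg_ids, sprintf("seg-r%02d", seq_along(red_idx))),
    session_id = "s1",
    sequence_index = seq_len(n + length(red_idx)) - 1L,
    text = c(texts[narration], red_texts))

  truth <- data.frame(event_id = event_id[chrono],
                      year = years[chrono],
                      segment_id = segment_of_event[chrono],
                      position = seq_len(n) - 1L,
                      stringsAsFactors = FALSE)
  seg_map <- data.frame(
    segment_id = c(seg_ids, sprintf("seg-r%02d", seq_along(red_idx))),
    event_id = c(event_id[narration], event_id[red_idx]),
    is_redundant = c(rep(FALSE, n), rep(TRUE, length(red_idx))),
    mode = c(modes[narration], rep("redundant", length(red_idx))),
    stringsAsFactors = FALSE)

  list(segments = segments, truth_timeline = truth,
       truth_clusters = data.frame(event_id = event_id,
                                   cluster = phases,
                                   stringsAsFactors = FALSE),
       segment_event = seg_map, historical_db = db, config = config)
}

#' Generate planted-cluster Gaussian features
#'
#' k isotropic unit-variance Gaussian blobs whose centroids sit
#' `separation` apart along orthogonal axes; the standard training fixture
#' for the relevance model.
#'
#' @param n Number of points.
#' @param k Number of blobs.
#' @param separation Centroid spacing.
#' @param dim Feature dimension (>= k).
#' @param seed RNG seed.
#' @return List with `features` (an [event_feature_matrix()]) and integer
#'   `labels`.
#' @export
generate_clustered_features <- function(n, k, separation, dim = 8L,
                                        seed = 1L) {
  stopifnot(n >= k, dim >= k)
  set.seed(seed)
  labels <- rep(seq_len(k), length.out = n)
  centers <- matrix(0, k, dim)
  for (j in seq_len(k)) centers[j, j] <- separation
  x <- centers[labels, , drop = FALSE] +
    matrix(stats::rnorm(n * dim), n, dim)
  # guard the no-all-zero-row invariant (astronomically unlikely, but cheap)
  zr <- rowSums(abs(x)) == 0
  x[zr, 1] <- 1e-8
  list(features = event_feature_matrix(x, sprintf("ev-%06d", seq_len(n))),
       labels = labels)
}

#' Write a generated story to a directory
#'
#' Writes `segments.jsonl`, `truth_timeline.jsonl`, `truth_clusters.tsv`,
#' and `historical_db.tsv`.
#'
#' @param story A [generate_story()] result.
#' @param dir Output directory (created if needed).
#' @export
write_story <- function(story, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  seg_path <- file.path(dir, "segments.jsonl")
  con <- file(seg_path, open = "w", encoding = "UTF-8")
  for (i in seq_len(nrow(story$segments))) {
    writeLines(jsonlite::toJSON(as.list(story$segments[i, ]),
                                auto_unbox = TRUE), con)
  }
  close(con)
  con <- file(file.path(dir, "truth_timeline.jsonl"), open = "w",
              encoding = "UTF-8")
  for (i in seq_len(nrow(story$truth_timeline))) {
    writeLines(jsonlite::toJSON(as.list(story$truth_timeline[i, ]),
                                auto_unbox = TRUE), con)
  }
  close(con)
  utils::write.table(story$truth_clusters,
                     file.path(dir, "truth_clusters.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_historical_db(story$historical_db,
                      file.path(dir, "historical_db.tsv"))
  invisible(NULL)
}
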