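# Storyline and timeline quality metrics: SLEU in both its h-gram-matching
# and positional-decay readings, timeline-identity absolute/relative scores,
# plus the workload-table arithmetic helper and a small ROUGE implementation
# for summary assessment.

#' Count comparable h-grams
#'
#' An h-gram is a length-h subsequence (not necessarily consecutive) of an
#' n-sentence storyline, so there are `choose(n, h)` of them — e.g. a
#' 4-sentence storyline has 6 2-grams.
#'
#' @param n Storyline length.
#' @param h Subsequence length, `1 <= h <= n`.
#' @return Integer count.
#' @export
count_hgrams <- function(n, h) {
  stopifnot(n >= 1, h >= 1)
  if (h > n) stop("h must not exceed n")
  as.integer(round(choose(n, h)))
}

# All h-element index subsequences of 1..n as a matrix (rows), in
# lexicographic order.
.hgram_indices <- function(n, h) {
  if (choose(n, h) > 1e5) stop("too many h-grams to enumerate (n too large)")
  m <- utils::combn(n, h)
  t(m)
}

# Default sentence similarity: bag-of-words cosine.
.default_sentence_similarity <- function(a, b) .bow_cosine(a, b)

#' Storyline quality by h-gram matching (SLEU)
#'
#' For each h in `names(weights)`, enumerates all `choose(n, h)` h-grams of
#' the predicted and reference storylines. A predicted h-gram matches a
#' reference h-gram when every position-aligned sentence pair has
#' similarity strictly above `match_threshold`; matching is greedy in
#' lexicographic order without reuse, from each side. Then
#' `p_h = min(matched_pred, matched_ref) / choose(n, h)` and
#' `SLEU = exp(sum_h w_h log p_h)`; any `p_h = 0` gives SLEU 0.
#'
#' @param predicted,reference Equal-length character vectors (or anything a
#'   custom `similarity` understands) in storyline order.
#' @param similarity Function of two elements returning a similarity, or an
#'   n x n matrix `S[i, j] = sim(predicted[i], reference[j])`. Defaults to
#'   bag-of-words cosine.
#' @param match_threshold Pairwise similarity threshold (default 0.2).
#' @param weights Named numeric vector mapping h to w_h; must sum to 1.
#'   Default `c("1" = 0.5, "2" = 0.5)`.
#' @return SLEU in \[0, 1\].
#' @export
sleu_hgram <- function(predicted, reference, similarity = NULL,
                       match_threshold = 0.2,
                       weights = c("1" = 0.5, "2" = 0.5)) {
  n <- length(predicted)
  if (n == 0 || length(reference) == 0) stop("empty storyline")
  if (length(reference) != n)
    stop("predicted and reference storylines must have equal length")
  if (abs(sum(weights) - 1) > 1e-9) stop("weights must sum to 1")
  S <- if (is.matrix(similarity)) {
    similarity
  } else {
    fn <- if (is.null(similarity)) .default_sentence_similarity else similarity
    outer(seq_len(n), seq_len(n),
          Vectorize(function(i, j) fn(predicted[[i]], reference[[j]])))
  }
  hs <- as.integer(names(weights))
  if (any(hs < 1 | hs > n)) stop("weights name an h outside [1, n]")
  log_sleu <- 0
  for (t in seq_along(hs)) {
    h <- hs[t]
    idx <- .hgram_indices(n, h)
    total <- nrow(idx)
    pair_ok <- S > match_threshold
    match_one_side <- function(from, to) {
      used <- rep(FALSE, total)
      matched <- 0L
      for (a in seq_len(total)) {
        for (b in seq_len(total)) {
          if (used[b]) next
          if (all(pair_ok[cbind(from(idx[a, ]), to(idx[b, ]))])) {
            used[b] <- TRUE
            matched <- matched + 1L
            break
          }
        }
      }
      matched
    }
    m_pred <- match_one_side(identity, identity)
    m_ref <- {
      # reference side: match reference h-grams against predicted ones
      used <- rep(FALSE, total)
      matched <- 0L
      for (a in seq_len(total)) {
        for (b in seq_len(total)) {
          if (used[b]) next
          if (all(pair_ok[cbind(idx[b, ], idx[a, ])])) {
            used[b] <- TRUE
            matched <- matched + 1L
            break
          }
        }
      }
      matched
    }
    p_h <- min(m_pred, m_ref) / total
    if (p_h == 0) return(0)
    log_sleu <- log_sleu + weights[t] * log(p_h)
  }
  unname(exp(log_sleu))
}

#' Storyline quality by positional decay (SLEU, standardized form)
#'
#' Computes the mean absolute rank deviation between predicted and
#' reference positions and scores
#' `sum_{h=1..H} (1/h) exp(-decay * mean_dev)`, normalized by
#' `sum_{h=1..H} 1/h` so a perfect timeline scores 1.
#'
#' @param pred_positions,ref_positions Named numeric vectors of ranks over
#'   the same events (names = event ids), or unnamed equal-length vectors
#'   aligned by position.
#' @param H Maximum hop distance (default 3).
#' @param decay Distance penalty constant (default 0.5).
#' @return Score in (0, 1\].
#' @export
sleu_positional <- function(pred_positions, ref_positions, H = 3,
                            decay = 0.5) {
  if (!is.null(names(pred_positions)) && !is.null(names(ref_positions))) {
    if (!setequal(names(pred_positions), names(ref_positions)))
      stop("position lists cover different event sets")
    ref_positions <- ref_positions[names(pred_positions)]
  } else if (length(pred_positions) != length(ref_positions)) {
    stop("position lists cover different event sets")
  }
  dev <- mean(abs(pred_positions - ref_positions))
  w <- 1 / seq_len(H)
  sum(w * exp(-decay * dev)) / sum(w)
}

.timeline_ranks <- function(x) {
  ids <- if (inherits(x, "event_timeline") || is.data.frame(x)) x$event_id
         else as.character(x)
  stats::setNames(seq_along(ids), ids)
}

#' Timeline identity: absolute position deviation
#'
#' Mean absolute difference between each event's rank in the predicted and
#' reference timelines; raw ranks (1..N) by default, normalized ranks
#' (i / N) when `normalized = TRUE`. Smaller is better; identical timelines
#' score 0.
#'
#' @param pred,ref Timelines ([event_timeline()] or character vectors of
#'   event ids) over the same event set.
#' @param normalized Use normalized ranks i / N.
#' @return Non-negative scalar.
#' @export
timid_absolute <- function(pred, ref, normalized = FALSE) {
  rp <- .timeline_ranks(pred); rr <- .timeline_ranks(ref)
  if (!setequal(names(rp), names(rr))) stop("timelines cover different events")
  rr <- rr[names(rp)]
  if (normalized) { rp <- rp / length(rp); rr <- rr / length(rr) }
  mean(abs(rp - rr))
}

#' Timeline identity: relative order (Kendall tau)
#'
#' Kendall tau-a between the two orders, computed by concordant/discordant
#' pair counting (no ties by construction: ranks are permutations).
#'
#' @inheritParams timid_absolute
#' @return Correlation in \[-1, 1\].
#' @export
timid_relative <- function(pred, ref) {
  rp <- .timeline_ranks(pred); rr <- .timeline_ranks(ref)
  if (!setequal(names(rp), names(rr))) stop("timelines cover different events")
  rr <- rr[names(rp)]
  n <- length(rp)
  if (n < 2) stop("need at least 2 events")
  conc <- 0L
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      s <- sign(rp[i] - rp[j]) * sign(rr[i] - rr[j])
      conc <- conc + s
    }
  }
  unname(conc / choose(n, 2))
}

#' Relative reduction between two workload means
#'
#' `100 * (baseline - treated) / baseline`, rounded to one decimal, as
#' printed in workload-comparison tables.
#'
#' @param baseline_mean Positive baseline mean.
#' @param treated_mean Treated-condition mean.
#' @return Percentage (one decimal).
#' @export
relative_reduction <- function(baseline_mean, treated_mean) {
  if (baseline_mean <= 0) stop("baseline mean must be positive")
  round(100 * (baseline_mean - treated_mean) / baseline_mean, 1)
}

# ---- ROUGE (summary overlap) ----------------------------------------------

.ngrams <- function(tokens, n) {
  if (length(tokens) < n) return(character())
  vapply(seq_len(length(tokens) - n + 1), function(i)
    paste(tokens[i:(i + n - 1)], collapse = " "), character(1))
}

.lcs_length <- function(a, b) {
  na <- length(a); nb <- length(b)
  if (na == 0 || nb == 0) return(0L)
  prev <- integer(nb + 1)
  for (i in seq_len(na)) {
    cur <- integer(nb + 1)
    for (j in seq_len(nb)) {
      cur[j + 1] <- if (a[i] == b[j]) prev[j] + 1L
                    else max(cur[j], prev[j + 1])
    }
    prev <- cur
  }
  prev[nb + 1]
}

#' ROUGE-N / ROUGE-L F1 scores
#'
#' Token-overlap summary metrics: clipped n-gram overlap (`rouge_n`) and
#' longest-common-subsequence overlap (`rouge_l`), both reported as F1.
#'
#' @param candidate,reference Text strings.
#' @param n N-gram order for `rouge_n`.
#' @return F1 in \[0, 1\].
#' @export
rouge_n <- function(candidate, reference, n = 1L) {
  ct <- .ngrams(tolower(tokenize_text(candidate)), n)
  rt <- .ngrams(tolower(tokenize_text(reference)), n)
  if (!length(ct) || !length(rt)) return(0)
  tc <- table(ct); tr <- table(rt)
  common <- intersect(names(tc), names(tr))
  overlap <- sum(pmin(as.numeric(tc[common]), as.numeric(tr[common])))
  p <- overlap / length(ct); r <- overlap / length(rt)
  if (p + r == 0) 0 else 2 * p * r / (p + r)
}

#' @rdname rouge_n
#' @export
rouge_l <- function(candidate, reference) {
  ct <- tolower(tokenize_text(candidate))
  rt <- tolower(tokenize_text(reference))
  if (!length(ct) || !length(rt)) return(0)
  l <- .lcs_length(ct, rt)
  p <- l / length(ct); r <- l / length(rt)
  if (p + r == 0) 0 else 2 * p * r / (p + r)
}

#' Evaluate a predicted timeline against a reference
#'
#' @param pred,ref Timelines over the same events.
#' @param pred_sentences,ref_sentences Optional sentence vectors (timeline
#'   order) for the h-gram SLEU; when absent, event ids are compared by
#'   exact match.
#' @param metrics Which metrics to compute.
#' @return Named list of metric values.
#' @export
evaluate_timeline <- function(pred, ref, pred_sentences = NULL,
                              ref_sentences = NULL,
                              metrics = c("sleu_hgram", "sleu_positional",
                                          "timid_ap", "timid_rp")) {
  metrics <- match.arg(metrics, several.ok = TRUE)
  out <- list()
  rp <- .timeline_ranks(pred); rr <- .timeline_ranks(ref)
  if ("sleu_hgram" %in% metrics) {
    ps <- if (is.null(pred_sentences)) names(rp) else pred_sentences
    rs <- if (is.null(ref_sentences)) names(rr) else ref_sentences
    sim <- if (is.null(pred_sentences))
      function(a, b) as.numeric(identical(a, b)) else NULL
    out$sleu_hgram <- sleu_hgram(ps, rs, similarity = sim)
  }
  if ("sleu_positional" %in% metrics)
    out$sleu_positional <- sleu_positional(rp, rr)
  if ("timid_ap" %in% metrics) out$timid_ap <- timid_absolute(pred, ref)
  if ("timid_rp" %in% metrics) out$timid_rp <- timid_relative(pred, ref)
  out
}
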