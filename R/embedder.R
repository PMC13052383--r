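#' Tokenize narrative text
#'
#' Splits text into tokens the way the fallback embedder counts them:
#' whitespace-delimited words for alphabetic scripts, and one token per
#' character for CJK ideographs (which carry word-level meaning without
#' whitespace segmentation).
#'
#' @param text Character scalar.
#' @return Character vector of tokens (possibly empty).
#' @export
tokenize_text <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  # Separate CJK ideographs so each becomes its own token.
  spaced <- gsub("([一-鿿])", " \\1 ", text, perl = TRUE)
  spaced <- gsub("[[:punct:]、。，！？]+", " ", spaced, perl = TRUE)
  toks <- strsplit(trimws(spaced), "\\s+", perl = TRUE)[[1]]
  toks[nzchar(toks)]
}

# 32-bit polynomial rolling hash; exact in double arithmetic (< 2^53).
.hash_string <- function(s) {
  h <- 0
  for (cp in utf8ToInt(s)) h <- (h * 31 + cp) %% 2147483647
  h
}

#' Deterministic hashed bag-of-tokens embedder
#'
#' A dependency-free stand-in for a neural sentence encoder. Each lowercased
#' token is hashed into one of `dimension` buckets; the bucket-count vector is
#' L2-normalized. Identical texts embed identically; texts sharing most tokens
#' have high cosine similarity. Deterministic for fixed input, independent of
#' the RNG state.
#'
#' @param dimension Number of hash buckets (embedding dimension).
#' @return An object of class `embedder` with fields `dimension` and
#'   `embed(texts)`, the latter returning a `length(texts) x dimension` matrix.
#' @examples
#' emb <- hash_embedder(32)
#' m <- emb$embed(c("we married in 1962", "we married in 1962"))
#' sum(m[1, ] * m[2, ]) # cosine of identical texts is 1
#' @export
hash_embedder <- function(dimension = 64L) {
  dimension <- as.integer(dimension)
  stopifnot(dimension >= 1L)
  embed <- function(texts) {
    stopifnot(is.character(texts))
    out <- matrix(0, nrow = length(texts), ncol = dimension)
    for (i in seq_along(texts)) {
      toks <- tokenize_text(tolower(texts[[i]]))
      if (length(toks) == 0L) next
      v <- numeric(dimension)
      for (tok in toks) {
        b <- (.hash_string(tok) %% dimension) + 1L
        v[b] <- v[b] + 1
      }
      nrm <- sqrt(sum(v^2))
      if (nrm > 0) v <- v / nrm
      out[i, ] <- v
    }
    if (any(!is.finite(out))) stop("embedder produced non-finite entries")
    out
  }
  structure(list(dimension = dimension, embed = embed), class = "embedder")
}

#' @export
print.embedder <- function(x, ...) {
  cat(sprintf("<embedder: %d-dimensional>\n", x$dimension))
  invisible(x)
}

# Cosine similarity between two numeric vectors; error on zero norm when
# strict (the relevance model requires it), 0 otherwise.
.cosine <- function(x, y, strict = FALSE) {
  nx <- sqrt(sum(x^2)); ny <- sqrt(sum(y^2))
  if (nx == 0 || ny == 0) {
    if (strict) stop("cosine similarity undefined for zero-norm vector")
    return(0)
  }
  sum(x * y) / (nx * ny)
}

# Row-wise cosine similarity matrix.
.cosine_matrix <- function(m, strict = FALSE) {
  nrm <- sqrt(rowSums(m^2))
  if (any(nrm == 0)) {
    if (strict) stop("zero-norm feature row: cosine similarity undefined")
    nrm[nrm == 0] <- 1
  }
  s <- (m / nrm) %*% t(m / nrm)
  s[s > 1] <- 1; s[s < -1] <- -1
  s
}
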