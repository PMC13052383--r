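# Independent scalar/brute-force oracles. Deliberately written as plain
# loops over the mathematical definitions, sharing no code with the package
# internals they check.

cos_pair <- function(x, y) sum(x * y) / sqrt(sum(x^2) * sum(y^2))

oracle_neighbor_sets <- function(X, tau1, tau2) {
  n <- nrow(X)
  direct <- vector("list", n)
  indirect <- vector("list", n)
  for (i in seq_len(n)) {
    d <- integer()
    for (j in seq_len(n)) {
      if (j != i && cos_pair(X[i, ], X[j, ]) > tau1) d <- c(d, j)
    }
    direct[[i]] <- d
  }
  for (i in seq_len(n)) {
    ind <- integer()
    for (k in seq_len(n)) {
      if (k == i || k %in% direct[[i]]) next
      for (j in direct[[i]]) {
        if (cos_pair(X[j, ], X[k, ]) > tau2) { ind <- c(ind, k); break }
      }
    }
    indirect[[i]] <- ind
  }
  list(direct = direct, indirect = indirect)
}

oracle_attention_row <- function(X, W, a, slope, union_i, i) {
  lrelu <- function(x) if (x > 0) x else slope * x
  out_dim <- nrow(W)
  theta <- vapply(union_i, function(j) {
    zi <- as.numeric(W %*% X[i, ]); zj <- as.numeric(W %*% X[j, ])
    lrelu(sum(a * c(zi, zj)))
  }, numeric(1))
  e <- exp(theta - max(theta))
  e / sum(e)
}

oracle_gat_forward <- function(X, params, sets) {
  n <- nrow(X)
  out <- matrix(0, n, params$out_dim)
  elu <- function(x) ifelse(x > 0, x, exp(x) - 1)
  for (i in seq_len(n)) {
    union_i <- sort(c(sets$direct[[i]], sets$indirect[[i]]))
    acc <- numeric(params$out_dim)
    for (hd in seq_len(params$heads)) {
      W <- params$W[[hd]]; a <- params$a[[hd]]
      if (!length(union_i)) {
        acc <- acc + as.numeric(W %*% X[i, ])  # self-attention fallback
      } else {
        alpha <- oracle_attention_row(X, W, a, params$leaky_slope, union_i, i)
        for (t in seq_along(union_i)) {
          acc <- acc + alpha[t] * as.numeric(W %*% X[union_i[t], ])
        }
      }
    }
    pre <- acc / params$heads
    out[i, ] <- switch(params$activation, elu = elu(pre), tanh = tanh(pre),
                       identity = pre)
  }
  out
}

oracle_dbn_forward <- function(v, W, b) {
  h <- numeric(nrow(W))
  for (i in seq_len(nrow(W))) {
    z <- b[i]
    for (j in seq_len(ncol(W))) z <- z + W[i, j] * v[j]
    h[i] <- 1 / (1 + exp(-z))
  }
  h
}

oracle_soft_assignment <- function(H, C, v) {
  n <- nrow(H); k <- nrow(C)
  D <- matrix(0, n, k)
  for (i in seq_len(n)) {
    q <- numeric(k)
    for (j in seq_len(k)) {
      d2 <- sum((H[i, ] - C[j, ])^2)
      q[j] <- (1 + d2 / v)^(-(v + 1) / 2)
    }
    D[i, ] <- q / sum(q)
  }
  D
}

oracle_target_distribution <- function(D) {
  n <- nrow(D); k <- ncol(D)
  f <- numeric(k)
  for (j in seq_len(k)) f[j] <- sum(D[, j])
  P <- matrix(0, n, k)
  for (i in seq_len(n)) {
    w <- numeric(k)
    for (j in seq_len(k)) w[j] <- D[i, j]^2 / f[j]
    P[i, ] <- w / sum(w)
  }
  P
}

oracle_kl <- function(P, Q, eps = 1e-12) {
  s <- 0
  for (i in seq_len(nrow(P))) {
    for (j in seq_len(ncol(P))) {
      s <- s + P[i, j] * log(max(P[i, j], eps) / max(Q[i, j], eps))
    }
  }
  s
}

# Breadth-first shortest hop counts on an eps-neighborhood graph.
oracle_bfs_hops <- function(adj, start) {
  n <- nrow(adj)
  dist <- rep(Inf, n)
  dist[start] <- 0
  queue <- start
  while (length(queue)) {
    p <- queue[1]; queue <- queue[-1]
    for (q in which(adj[p, ])) {
      if (is.infinite(dist[q])) {
        dist[q] <- dist[p] + 1
        queue <- c(queue, q)
      }
    }
  }
  dist
}

# Exhaustive evaluation of the greedy insertion objective for ONE undated
# event against the current timeline, including the tie-break.
oracle_insert_position <- function(tl_ids, tl_seq, rel, alpha, u_id, u_seq) {
  n <- length(tl_ids)
  scores <- numeric(n + 1)
  for (i in 0:n) {
    left <- if (i >= 1) rel[tl_ids[i], u_id] else 0
    right <- if (i < n) rel[u_id, tl_ids[i + 1]] else 0
    scores[i + 1] <- alpha * left + (1 - alpha) * right
  }
  best <- max(scores)
  cand <- which(abs(scores - best) < 1e-12) - 1L
  if (length(cand) > 1 && n > 0 && !is.na(u_seq)) {
    prox <- vapply(cand, function(i) {
      fl <- c(if (i >= 1) tl_seq[i], if (i < n) tl_seq[i + 1])
      fl <- fl[!is.na(fl)]
      if (!length(fl)) return(Inf)
      min(abs(fl - u_seq))
    }, numeric(1))
    cand <- cand[order(prox, cand)]
  }
  list(position = cand[1], score = best, scores = scores)
}

# Exhaustive h-gram matching: enumerate every h-subsequence on both sides
# and count greedy matches without reuse, in lexicographic order.
oracle_sleu_hgram <- function(S, threshold, weights) {
  n <- nrow(S)
  log_s <- 0
  for (t in seq_along(weights)) {
    h <- as.integer(names(weights)[t])
    idx <- t(utils::combn(n, h))
    total <- nrow(idx)
    ok <- S > threshold
    count_side <- function(pred_side) {
      used <- rep(FALSE, total)
      matched <- 0
      for (a in seq_len(total)) {
        for (b in seq_len(total)) {
          if (used[b]) next
          hit <- all(vapply(seq_len(h), function(p) {
            if (pred_side) ok[idx[a, p], idx[b, p]]
            else ok[idx[b, p], idx[a, p]]
          }, logical(1)))
          if (hit) { used[b] <- TRUE; matched <- matched + 1; break }
        }
      }
      matched
    }
    p_h <- min(count_side(TRUE), count_side(FALSE)) / total
    if (p_h == 0) return(0)
    log_s <- log_s + weights[t] * log(p_h)
  }
  unname(exp(log_s))
}

oracle_kendall <- function(rp, rr) {
  n <- length(rp)
  conc <- 0
  disc <- 0
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      s <- (rp[i] - rp[j]) * (rr[i] - rr[j])
      if (s > 0) conc <- conc + 1 else if (s < 0) disc <- disc + 1
    }
  }
  (conc - disc) / choose(n, 2)
}

# Stepwise brute-force MMR: at every step evaluate the objective for every
# remaining candidate explicitly.
oracle_mmr <- function(sentences, salience, k, dw, simfun) {
  picked <- integer()
  avail <- seq_along(sentences)
  while (length(picked) < min(k, length(sentences))) {
    best <- NA; best_val <- -Inf
    for (i in avail) {
      val <- if (!length(picked)) salience[i] else {
        red <- -Inf
        for (p in picked) red <- max(red, simfun(sentences[i], sentences[p]))
        dw * salience[i] - (1 - dw) * red
      }
      if (val > best_val) { best_val <- val; best <- i }
    }
    picked <- c(picked, best)
    avail <- setdiff(avail, best)
  }
  sentences[picked]
}

# Random generators used across property tests.
random_features <- function(n, m, seed) {
  set.seed(seed)
  matrix(rnorm(n * m), n, m)
}

random_stochastic <- function(n, k, seed) {
  set.seed(seed)
  m <- matrix(runif(n * k) + 1e-3, n, k)
  m / rowSums(m)
}

random_rel_matrix <- function(ids, seed) {
  set.seed(seed)
  n <- length(ids)
  m <- matrix(runif(n * n), n, n)
  m <- (m + t(m)) / 2
  diag(m) <- 1
  dimnames(m) <- list(ids, ids)
  m
}
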