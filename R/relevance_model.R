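# Relevance model: multi-hop graph attention over event similarity graphs,
# logistic feature-compression (deep-belief) layers, and a self-supervised
# deep-embedded-clustering loss that aligns both feature streams.

#' Build direct and indirect neighbor sets
#'
#' Direct neighbors of node i are all j with cosine similarity above `tau1`;
#' indirect (second-hop) neighbors are nodes k, outside the direct set and
#' not i itself, reachable through some direct neighbor j with
#' `cos(h_j, h_k) > tau2`.
#'
#' @param features Numeric matrix (rows = nodes); no all-zero rows.
#' @param tau1 Direct-neighbor similarity threshold (default 0.6).
#' @param tau2 Indirect-witness similarity threshold (default 0.8).
#' @return An object of class `neighbor_sets`: lists `direct` and `indirect`
#'   of integer vectors, the thresholds, and the logical `union_mask`
#'   (n x n) of attention-eligible pairs.
#' @export
build_neighbor_sets <- function(features, tau1 = 0.6, tau2 = 0.8) {
  stopifnot(tau1 > 0, tau1 < 1, tau2 > 0, tau2 < 1)
  m <- as.matrix(features)
  n <- nrow(m)
  S <- .cosine_matrix(m, strict = TRUE)
  direct_mask <- S > tau1
  diag(direct_mask) <- FALSE
  witness <- S > tau2
  reach <- (direct_mask %*% witness) > 0
  indirect_mask <- reach & !direct_mask
  diag(indirect_mask) <- FALSE
  structure(list(
    direct = lapply(seq_len(n), function(i) which(direct_mask[i, ])),
    indirect = lapply(seq_len(n), function(i) which(indirect_mask[i, ])),
    tau1 = tau1, tau2 = tau2, n = n,
    union_mask = direct_mask | indirect_mask
  ), class = "neighbor_sets")
}

#' @export
print.neighbor_sets <- function(x, ...) {
  cat(sprintf("<neighbor_sets: %d nodes, tau1=%.2f tau2=%.2f, %d direct / %d indirect links>\n",
              x$n, x$tau1, x$tau2, sum(lengths(x$direct)),
              sum(lengths(x$indirect))))
  invisible(x)
}

#' Graph-attention layer parameters
#'
#' Each of the `heads` attention heads owns a weight matrix `W`
#' (`out_dim x in_dim`) and an attention vector `a` (length `2 * out_dim`)
#' scoring concatenated transformed node pairs.
#'
#' @param in_dim,out_dim Layer dimensions.
#' @param heads Number of attention heads (averaged, not concatenated).
#' @param leaky_slope Negative slope of the LeakyReLU scoring nonlinearity.
#' @param dropout_rate Dropout rate applied to attention coefficients during
#'   training.
#' @param activation Output nonlinearity: `"elu"` (default), `"tanh"`, or
#'   `"identity"`.
#' @param init_sd Standard deviation of the Gaussian initialization (drawn
#'   from the current RNG stream).
#' @return Object of class `gat_layer_params` with list fields `W` and `a`
#'   (one element per head).
#' @export
gat_layer_params <- function(in_dim, out_dim, heads = 1L, leaky_slope = 0.2,
                             dropout_rate = 0.5, activation = "elu",
                             init_sd = 0.1) {
  stopifnot(heads >= 1, dropout_rate >= 0, dropout_rate < 1)
  structure(list(
    W = lapply(seq_len(heads), function(h)
      matrix(stats::rnorm(out_dim * in_dim, sd = init_sd), out_dim, in_dim)),
    a = lapply(seq_len(heads), function(h)
      stats::rnorm(2 * out_dim, sd = init_sd)),
    in_dim = in_dim, out_dim = out_dim, heads = as.integer(heads),
    leaky_slope = leaky_slope, dropout_rate = dropout_rate,
    activation = match.arg(activation, c("elu", "tanh", "identity"))
  ), class = "gat_layer_params")
}

.leaky_relu <- function(x, slope) ifelse(x > 0, x, slope * x)
.elu <- function(x) ifelse(x > 0, x, expm1(x))
.apply_activation <- function(x, which) {
  switch(which, elu = .elu(x), tanh = tanh(x), identity = x)
}
.row_softmax <- function(m) {
  e <- exp(m - apply(m, 1, max))
  e / rowSums(e)
}

#' Multi-hop attention coefficients
#'
#' For each head, computes `theta_ij = LeakyReLU(a^T [W h_i || W h_j])` and
#' normalizes by softmax over the union of direct and indirect neighbors of
#' i. Rows with no neighbors fall back to self-attention (`alpha_ii = 1`).
#'
#' @param h Node feature matrix (n x in_dim).
#' @param params A [gat_layer_params()].
#' @param sets A [build_neighbor_sets()] result for the same n nodes.
#' @return List of n x n attention matrices, one per head (class
#'   `gat_attention`); entries outside the neighbor union are 0.
#' @export
attention_scores <- function(h, params, sets) {
  h <- as.matrix(h)
  n <- nrow(h)
  if (sets$n != n) stop("neighbor sets inconsistent with node count")
  if (ncol(h) != params$in_dim) stop("feature dimension mismatch")
  out <- vector("list", params$heads)
  for (hd in seq_len(params$heads)) {
    Wh <- h %*% t(params$W[[hd]])
    a1 <- params$a[[hd]][seq_len(params$out_dim)]
    a2 <- params$a[[hd]][params$out_dim + seq_len(params$out_dim)]
    theta <- outer(drop(Wh %*% a1), drop(Wh %*% a2), `+`)
    theta <- .leaky_relu(theta, params$leaky_slope)
    if (any(is.nan(theta)))
      stop("NaN attention score at node ",
           which(apply(is.nan(theta), 1, any))[1])
    alpha <- matrix(0, n, n)
    for (i in seq_len(n)) {
      nb <- which(sets$union_mask[i, ])
      if (!length(nb)) {
        alpha[i, i] <- 1
      } else {
        e <- exp(theta[i, nb] - max(theta[i, nb]))
        alpha[i, nb] <- e / sum(e)
      }
    }
    out[[hd]] <- alpha
  }
  structure(out, class = "gat_attention")
}

#' Graph-attention layer forward pass
#'
#' Per head, aggregates transformed neighbor features weighted by attention;
#' the pre-activations of all heads are averaged and passed through the
#' output nonlinearity (the multi-head average is taken inside the
#' activation). With one head this is the single-head update exactly.
#'
#' @inheritParams attention_scores
#' @param dropout_masks Optional list (one n x n 0/1 matrix per head)
#'   applied to the attention coefficients with inverted scaling; `NULL`
#'   disables dropout (inference mode).
#' @return n x out_dim matrix of updated node features.
#' @export
gat_layer_forward <- function(h, params, sets, dropout_masks = NULL) {
  h <- as.matrix(h)
  alphas <- attention_scores(h, params, sets)
  n <- nrow(h)
  pre <- matrix(0, n, params$out_dim)
  for (hd in seq_len(params$heads)) {
    a <- alphas[[hd]]
    if (!is.null(dropout_masks)) {
      a <- a * dropout_masks[[hd]] / (1 - params$dropout_rate)
    }
    pre <- pre + a %*% (h %*% t(params$W[[hd]]))
  }
  .apply_activation(pre / params$heads, params$activation)
}

#' Logistic compression layer parameters
#'
#' @param in_dim,hidden_dim Layer dimensions.
#' @param init_sd Gaussian initialization scale.
#' @return Object of class `dbn_layer_params` with `weights`
#'   (`hidden_dim x in_dim`) and `biases` (length `hidden_dim`).
#' @export
dbn_layer_params <- function(in_dim, hidden_dim, init_sd = 0.1) {
  structure(list(
    weights = matrix(stats::rnorm(hidden_dim * in_dim, sd = init_sd),
                     hidden_dim, in_dim),
    biases = stats::rnorm(hidden_dim, sd = init_sd),
    in_dim = in_dim, hidden_dim = hidden_dim
  ), class = "dbn_layer_params")
}

#' Logistic compression layer forward pass
#'
#' `h+ = sigmoid(weights %*% v + biases)`, elementwise logistic. Accepts a
#' single visible vector or a matrix of row vectors.
#'
#' @param v Numeric vector (length `in_dim`) or matrix (n x in_dim).
#' @param params A [dbn_layer_params()].
#' @return Hidden vector or matrix (n x hidden_dim).
#' @export
dbn_layer_forward <- function(v, params) {
  single <- is.null(dim(v))
  vm <- if (single) matrix(v, nrow = 1) else as.matrix(v)
  if (ncol(vm) != params$in_dim)
    stop("dbn layer dimension mismatch: expected ", params$in_dim,
         " inputs, got ", ncol(vm))
  z <- vm %*% t(params$weights) + rep(params$biases, each = nrow(vm))
  out <- stats::plogis(z)
  if (single) drop(out) else out
}

#' Interleaved graph-attention / compression encoding
#'
#' Round r feeds the concatenation of the previous round's attention output
#' and hidden state into the attention layer (round 1 sees the raw feature
#' matrix alone); each attention output is compressed by the matching
#' logistic layer.
#'
#' @param phi Event feature matrix (n x m).
#' @param gat_stack,dbn_stack Equal-length lists of layer parameter objects.
#' @param sets Neighbor sets shared by all rounds.
#' @param dropout_masks Optional list (per round) of per-head masks.
#' @return List with `O` (final attention output) and `hidden` (list of all
#'   hidden-state matrices).
#' @export
interleaved_encode <- function(phi, gat_stack, dbn_stack, sets,
                               dropout_masks = NULL) {
  rounds <- length(gat_stack)
  if (rounds < 1 || length(dbn_stack) != rounds)
    stop("gat_stack and dbn_stack must have equal length >= 1")
  input <- as.matrix(phi)
  hidden <- vector("list", rounds)
  O <- NULL
  for (r in seq_len(rounds)) {
    if (ncol(input) != gat_stack[[r]]$in_dim)
      stop("interleaving dimension mismatch at round ", r, ": expected ",
           gat_stack[[r]]$in_dim, ", got ", ncol(input))
    O <- gat_layer_forward(input, gat_stack[[r]], sets,
                           if (!is.null(dropout_masks)) dropout_masks[[r]])
    hidden[[r]] <- dbn_layer_forward(O, dbn_stack[[r]])
    input <- cbind(O, hidden[[r]])
  }
  list(O = O, hidden = hidden)
}

#' Student-t soft cluster assignment
#'
#' `d_ij` is proportional to `(1 + ||h_i - c_j||^2 / v_c)^(-(v_c + 1) / 2)`
#' (the Student-t kernel of deep embedded clustering), normalized so each
#' row sums to 1.
#'
#' @param features n x p matrix.
#' @param centroids k x p matrix.
#' @param v_c Positive degrees-of-freedom parameter (default 1).
#' @return n x k row-stochastic matrix `D`.
#' @export
soft_assignment <- function(features, centroids, v_c = 1) {
  f <- as.matrix(features); cm <- as.matrix(centroids)
  stopifnot(v_c > 0, nrow(cm) >= 1)
  if (ncol(f) != ncol(cm)) stop("centroid/feature dimension mismatch")
  d2 <- outer(rowSums(f^2), rep(1, nrow(cm))) +
    outer(rep(1, nrow(f)), rowSums(cm^2)) - 2 * f %*% t(cm)
  d2[d2 < 0] <- 0
  q <- (1 + d2 / v_c)^(-(v_c + 1) / 2)
  q / rowSums(q)
}

#' Sharpened target distribution
#'
#' `p_ij = (d_ij^2 / f_j) / sum_j' (d_ij'^2 / f_j')` with cluster frequency
#' `f_j = sum_i d_ij`: squares emphasize confident assignments and the
#' frequency term counteracts large clusters.
#'
#' @param D Row-stochastic soft-assignment matrix.
#' @return Row-stochastic matrix `P` of the same shape.
#' @export
target_distribution <- function(D) {
  D <- as.matrix(D)
  if (max(abs(rowSums(D) - 1)) > 1e-6) stop("D must be row-stochastic")
  f <- colSums(D)
  if (any(f <= 0)) stop("degenerate cluster: zero total assignment mass")
  w <- sweep(D^2, 2, f, `/`)
  w / rowSums(w)
}

#' Kullback-Leibler divergence between row-stochastic matrices
#'
#' `sum_ij p_ij log(p_ij / q_ij)` with an epsilon floor (1e-12) under the
#' logarithms. Non-negative; 0 iff the matrices are equal.
#'
#' @param P,Q Row-stochastic matrices of equal shape.
#' @param eps Floor applied before taking logs.
#' @return Non-negative scalar.
#' @export
kl_loss <- function(P, Q, eps = 1e-12) {
  P <- as.matrix(P); Q <- as.matrix(Q)
  if (!all(dim(P) == dim(Q))) stop("KL shape mismatch")
  Pf <- pmax(P, eps); Qf <- pmax(Q, eps)
  sum(P * log(Pf / Qf))
}

#' Training configuration for the relevance model
#'
#' Defaults follow the published setting where one exists: thresholds
#' `tau1 = 0.6`, `tau2 = 0.8`; loss weights `lambda1 = 0.7`,
#' `lambda2 = 0.3` (must sum to 1); AdamW weight decay 0.01 with linear
#' warmup over the first 10% of steps; dropout 0.5 in the attention layers;
#' two interleaving rounds.
#'
#' @param tau1,tau2 Neighbor-set thresholds.
#' @param lambda1,lambda2 Weights of the attention-stream and
#'   compression-stream KL losses.
#' @param learning_rate Peak AdamW learning rate.
#' @param weight_decay Decoupled weight decay (weights only, not biases or
#'   centroids).
#' @param warmup_fraction Fraction of total steps spent in linear warmup;
#'   the rate then decays linearly to 0.
#' @param dropout Attention-coefficient dropout rate during training.
#' @param heads Attention heads per layer.
#' @param layer_dims List with `gat_out` and `dbn_hidden`.
#' @param rounds Interleaving rounds (default 2).
#' @param epochs,steps_per_epoch Optimization schedule; the sharpened target
#'   is refrozen and neighbor sets recomputed at each epoch boundary.
#' @param k Number of clusters; `NULL` selects k by silhouette/elbow.
#' @param v_c Student-t parameter of the soft assignment.
#' @param leaky_slope,activation Attention-layer nonlinearity settings.
#' @param seed RNG seed controlling initialization and dropout masks.
#' @return Object of class `training_config`.
#' @export
training_config <- function(tau1 = 0.6, tau2 = 0.8, lambda1 = 0.7,
                            lambda2 = 0.3, learning_rate = 0.05,
                            weight_decay = 0.01, warmup_fraction = 0.10,
                            dropout = 0.5, heads = 1L,
                            layer_dims = list(gat_out = 6L, dbn_hidden = 4L),
                            rounds = 2L, epochs = 3L, steps_per_epoch = 8L,
                            k = NULL, v_c = 1, leaky_slope = 0.2,
                            activation = "elu", seed = 42L) {
  if (abs(lambda1 + lambda2 - 1) > 1e-9)
    stop("lambda1 + lambda2 must equal 1")
  if (warmup_fraction < 0 || warmup_fraction >= 1)
    stop("warmup_fraction must lie in [0, 1)")
  stopifnot(dropout >= 0, dropout < 1, heads >= 1, rounds >= 1,
            epochs >= 1, steps_per_epoch >= 1, v_c > 0)
  structure(list(tau1 = tau1, tau2 = tau2, lambda1 = lambda1,
                 lambda2 = lambda2, learning_rate = learning_rate,
                 weight_decay = weight_decay,
                 warmup_fraction = warmup_fraction, dropout = dropout,
                 heads = as.integer(heads), layer_dims = layer_dims,
                 rounds = as.integer(rounds), epochs = as.integer(epochs),
                 steps_per_epoch = as.integer(steps_per_epoch), k = k,
                 v_c = v_c, leaky_slope = leaky_slope,
                 activation = activation, seed = as.integer(seed)),
            class = "training_config")
}

# ---- parameter flattening --------------------------------------------------

.flatten_params <- function(pl) {
  unlist(list(
    gat = lapply(pl$gat, function(g) list(W = g$W, a = g$a)),
    dbn = lapply(pl$dbn, function(d) list(w = d$weights, b = d$biases)),
    head = list(W = pl$head$W, b = pl$head$b),
    centroids = pl$centroids), use.names = FALSE)
}

.unflatten_params <- function(flat, pl) {
  pos <- 0L
  take <- function(k) { v <- flat[pos + seq_len(k)]; pos <<- pos + k; v }
  for (r in seq_along(pl$gat)) {
    for (hd in seq_along(pl$gat[[r]]$W)) {
      Wd <- dim(pl$gat[[r]]$W[[hd]])
      pl$gat[[r]]$W[[hd]] <- matrix(take(prod(Wd)), Wd[1], Wd[2])
      pl$gat[[r]]$a[[hd]] <- take(length(pl$gat[[r]]$a[[hd]]))
    }
  }
  for (r in seq_along(pl$dbn)) {
    Wd <- dim(pl$dbn[[r]]$weights)
    pl$dbn[[r]]$weights <- matrix(take(prod(Wd)), Wd[1], Wd[2])
    pl$dbn[[r]]$biases <- take(length(pl$dbn[[r]]$biases))
  }
  Wd <- dim(pl$head$W)
  pl$head$W <- matrix(take(prod(Wd)), Wd[1], Wd[2])
  pl$head$b <- take(length(pl$head$b))
  Cd <- dim(pl$centroids)
  pl$centroids <- matrix(take(prod(Cd)), Cd[1], Cd[2])
  if (pos != length(flat)) stop("parameter vector length mismatch")
  pl
}

# Decay mask: 1 for weight matrices and attention vectors, 0 for biases and
# centroids (AdamW convention).
.decay_mask <- function(pl) {
  unlist(list(
    gat = lapply(pl$gat, function(g) list(
      W = lapply(g$W, function(m) m * 0 + 1),
      a = lapply(g$a, function(v) v * 0 + 1))),
    dbn = lapply(pl$dbn, function(d) list(
      w = d$weights * 0 + 1, b = d$biases * 0)),
    head = list(W = pl$head$W * 0 + 1, b = pl$head$b * 0),
    centroids = pl$centroids * 0), use.names = FALSE)
}

# Forward pass + loss given an (unflattened) parameter list.
.relevance_loss <- function(pl, phi, sets, P, config, dropout_masks = NULL) {
  enc <- interleaved_encode(phi, pl$gat, pl$dbn, sets, dropout_masks)
  h <- enc$hidden[[length(enc$hidden)]]
  D <- soft_assignment(h, pl$centroids, config$v_c)
  K <- .row_softmax(enc$O %*% pl$head$W + rep(pl$head$b, each = nrow(phi)))
  config$lambda1 * kl_loss(P, K) + config$lambda2 * kl_loss(P, D)
}

#' Train the relevance model
#'
#' Optimizes `lambda1 * KL(P || K) + lambda2 * KL(P || D)` by AdamW over all
#' attention, compression, cluster-head and centroid parameters, using
#' central finite-difference gradients (the model is desk-scale by design).
#' `P` is the sharpened target, refrozen at every epoch boundary in the
#' usual deep-embedded-clustering alternation; neighbor sets are recomputed
#' from the current hidden features at the same cadence. Centroids are
#' initialized by k-means on the initial hidden features. Fully reproducible
#' for a fixed `config$seed`.
#'
#' @param phi An [event_feature_matrix()] (or plain matrix), n rows.
#' @param config A [training_config()].
#' @return Object of class `relevance_model`: trained `params`, `k`, final
#'   `features` (hidden states), distributions `D`, `P`, `K`, hard
#'   `assignments`, the cosine `correlation` of the learned features, the
#'   per-step `loss_trajectory` (inference-mode loss), and
#'   `initial_centroids`.
#' @export
train_relevance_model <- function(phi, config = training_config()) {
  phi <- as.matrix(phi)
  n <- nrow(phi)
  set.seed(config$seed)
  k <- config$k
  if (is.null(k)) k <- select_k(phi, 2:max(2, min(6, n - 1)))
  if (n < k || k < 2) stop("need n >= k >= 2")
  g_out <- config$layer_dims$gat_out
  d_hid <- config$layer_dims$dbn_hidden
  in_dims <- c(ncol(phi), rep(g_out + d_hid, config$rounds - 1))
  pl <- list(
    gat = lapply(seq_len(config$rounds), function(r)
      gat_layer_params(in_dims[r], g_out, heads = config$heads,
                       leaky_slope = config$leaky_slope,
                       dropout_rate = config$dropout,
                       activation = config$activation)),
    dbn = lapply(seq_len(config$rounds), function(r)
      dbn_layer_params(g_out, d_hid, init_sd = 0.5)),
    head = list(W = matrix(stats::rnorm(g_out * k, sd = 0.1), g_out, k),
                b = stats::rnorm(k, sd = 0.1)),
    centroids = matrix(0, k, d_hid))
  sets <- build_neighbor_sets(phi, config$tau1, config$tau2)
  enc0 <- interleaved_encode(phi, pl$gat, pl$dbn, sets)
  h0 <- enc0$hidden[[length(enc0$hidden)]]
  km0 <- stats::kmeans(h0, centers = k, nstart = 5)
  pl$centroids <- unname(km0$centers)
  initial_centroids <- pl$centroids

  flat <- .flatten_params(pl)
  dmask <- .decay_mask(pl)
  np <- length(flat)
  total_steps <- config$epochs * config$steps_per_epoch
  warmup_steps <- ceiling(config$warmup_fraction * total_steps)
  adam_m <- numeric(np); adam_v <- numeric(np)
  b1 <- 0.9; b2 <- 0.999; adam_eps <- 1e-8; fd_h <- 1e-4
  traj <- numeric(total_steps)
  step_global <- 0L

  # The similarity graph is computed once from the input features and kept
  # fixed: sigmoid-compressed hidden features concentrate near 0.5, so
  # recomputing cosine neighborhoods from them degenerates to a complete
  # graph and erases the cluster structure the attention should exploit.
  for (epoch in seq_len(config$epochs)) {
    pl <- .unflatten_params(flat, pl)
    enc <- interleaved_encode(phi, pl$gat, pl$dbn, sets)
    h <- enc$hidden[[length(enc$hidden)]]
    D_epoch <- soft_assignment(h, pl$centroids, config$v_c)
    P <- target_distribution(D_epoch)
    for (step in seq_len(config$steps_per_epoch)) {
      step_global <- step_global + 1L
      masks <- NULL
      if (config$dropout > 0) {
        masks <- lapply(seq_len(config$rounds), function(r)
          lapply(seq_len(config$heads), function(hd)
            matrix(stats::rbinom(n * n, 1, 1 - config$dropout), n, n)))
      }
      loss_at <- function(fv) {
        .relevance_loss(.unflatten_params(fv, pl), phi, sets, P, config,
                        masks)
      }
      grad <- numeric(np)
      for (p in seq_len(np)) {
        fp <- flat; fp[p] <- fp[p] + fd_h
        fm <- flat; fm[p] <- fm[p] - fd_h
        grad[p] <- (loss_at(fp) - loss_at(fm)) / (2 * fd_h)
      }
      if (any(!is.finite(grad)))
        stop("training diverged (non-finite gradient) at step ", step_global)
      lr_t <- if (step_global <= warmup_steps && warmup_steps > 0) {
        config$learning_rate * step_global / warmup_steps
      } else {
        config$learning_rate *
          max(0, (total_steps - step_global) /
                max(1, total_steps - warmup_steps))
      }
      adam_m <- b1 * adam_m + (1 - b1) * grad
      adam_v <- b2 * adam_v + (1 - b2) * grad^2
      mhat <- adam_m / (1 - b1^step_global)
      vhat <- adam_v / (1 - b2^step_global)
      flat <- flat - lr_t * mhat / (sqrt(vhat) + adam_eps) -
        lr_t * config$weight_decay * dmask * flat
      eval_loss <- .relevance_loss(.unflatten_params(flat, pl), phi, sets,
                                   P, config)
      if (!is.finite(eval_loss))
        stop("training diverged (non-finite loss) at step ", step_global)
      traj[step_global] <- eval_loss
    }
  }

  pl <- .unflatten_params(flat, pl)
  enc <- interleaved_encode(phi, pl$gat, pl$dbn, sets)
  h <- enc$hidden[[length(enc$hidden)]]
  D <- soft_assignment(h, pl$centroids, config$v_c)
  P <- target_distribution(D)
  K <- .row_softmax(enc$O %*% pl$head$W + rep(pl$head$b, each = n))
  corr <- .cosine_matrix(h)
  corr[corr < 0] <- 0
  diag(corr) <- 1
  structure(list(params = pl, k = k, features = h, O = enc$O, D = D, P = P,
                 K = K, assignments = max.col(D), correlation = corr,
                 loss_trajectory = traj,
                 initial_centroids = initial_centroids, config = config),
            class = "relevance_model")
}

#' @export
print.relevance_model <- function(x, ...) {
  cat(sprintf("<relevance_model: n=%d, k=%d, final loss %.4f>\n",
              nrow(x$features), x$k, utils::tail(x$loss_trajectory, 1)))
  invisible(x)
}
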