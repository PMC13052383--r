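# GAT / compression layers, deep-embedded-clustering machinery, training.

test_that("neighbor sets match the brute-force definition", {
  # trivial cases
  one <- build_neighbor_sets(matrix(1:3, 1), 0.6, 0.8)
  expect_length(one$direct[[1]], 0)
  expect_length(one$indirect[[1]], 0)
  ortho <- build_neighbor_sets(diag(3), 0.6, 0.8)
  expect_true(all(lengths(ortho$direct) == 0))
  expect_true(all(lengths(ortho$indirect) == 0))
  expect_error(build_neighbor_sets(rbind(c(1, 0), c(0, 0))), "zero-norm")

  for (s in 1:30) {
    X <- random_features(sample(2:12, 1), 4, seed = 100 + s)
    sets <- build_neighbor_sets(X, 0.6, 0.8)
    orac <- oracle_neighbor_sets(X, 0.6, 0.8)
    expect_identical(lapply(sets$direct, as.integer), orac$direct)
    expect_identical(lapply(sets$indirect, sort), lapply(orac$indirect, sort))
  }
})

test_that("attention rows are softmax-normalized and match the scalar oracle", {
  set.seed(1)
  X <- random_features(5, 3, seed = 5)
  params <- gat_layer_params(3, 4, heads = 1, dropout_rate = 0)
  sets <- build_neighbor_sets(X, 0.2, 0.5)
  alpha <- attention_scores(X, params, sets)[[1]]
  for (i in 1:5) {
    nb <- which(sets$union_mask[i, ])
    if (length(nb)) {
      expect_equal(sum(alpha[i, ]), 1, tolerance = 1e-6)
      expect_equal(alpha[i, nb],
                   oracle_attention_row(X, params$W[[1]], params$a[[1]],
                                        params$leaky_slope, nb, i),
                   tolerance = 1e-10)
    } else {
      expect_equal(alpha[i, i], 1)
    }
  }
  # singleton neighbor set gives attention exactly 1
  X2 <- rbind(c(1, 0), c(1, 0.01), c(-1, 0))
  sets2 <- build_neighbor_sets(X2, 0.9, 0.99)
  p2 <- gat_layer_params(2, 2)
  a2 <- attention_scores(X2, p2, sets2)[[1]]
  expect_equal(a2[1, 2], 1)
  # all-equal scores give the uniform distribution (a = 0)
  p0 <- gat_layer_params(3, 4)
  p0$a[[1]] <- rep(0, 8)
  a0 <- attention_scores(X, p0, sets)[[1]]
  nb1 <- which(sets$union_mask[1, ])
  expect_equal(unname(a0[1, nb1]), rep(1 / length(nb1), length(nb1)))
})

test_that("gat_layer_forward matches the scalar oracle; head averaging", {
  set.seed(2)
  X <- random_features(6, 3, seed = 9)
  sets <- build_neighbor_sets(X, 0.2, 0.5)
  p1 <- gat_layer_params(3, 4, heads = 1, dropout_rate = 0)
  expect_equal(gat_layer_forward(X, p1, sets), oracle_gat_forward(X, p1, sets),
               tolerance = 1e-10)
  # m identical heads equal the single head
  p4 <- gat_layer_params(3, 4, heads = 4, dropout_rate = 0)
  for (hd in 1:4) { p4$W[[hd]] <- p1$W[[1]]; p4$a[[hd]] <- p1$a[[1]] }
  expect_equal(gat_layer_forward(X, p4, sets),
               gat_layer_forward(X, p1, sets), tolerance = 1e-12)
  # distinct multi-head also matches the oracle
  p2 <- gat_layer_params(3, 4, heads = 2, dropout_rate = 0)
  expect_equal(gat_layer_forward(X, p2, sets), oracle_gat_forward(X, p2, sets),
               tolerance = 1e-10)
})

test_that("compression layer is the logistic affine map", {
  p <- dbn_layer_params(3, 2)
  p$weights[] <- 0; p$biases[] <- 0
  expect_equal(dbn_layer_forward(c(1, 2, 3), p), c(0.5, 0.5))
  p$biases[] <- 50
  expect_true(all(dbn_layer_forward(c(1, 2, 3), p) > 0.999))
  expect_error(dbn_layer_forward(c(1, 2), p), "dimension mismatch")
  for (s in 1:20) {
    set.seed(300 + s)
    W <- matrix(rnorm(6), 2, 3); b <- rnorm(2)
    pp <- dbn_layer_params(3, 2); pp$weights <- W; pp$biases <- b
    v <- rnorm(3)
    expect_equal(dbn_layer_forward(v, pp), oracle_dbn_forward(v, W, b),
                 tolerance = 1e-12)
  }
})

test_that("interleaved encoding composes the per-layer oracles", {
  set.seed(3)
  X <- random_features(4, 3, seed = 21)
  sets <- build_neighbor_sets(X, 0.2, 0.5)
  g1 <- gat_layer_params(3, 4, dropout_rate = 0)
  d1 <- dbn_layer_params(4, 2)
  # single round: O = gat(phi); hidden = dbn(O)
  enc <- interleaved_encode(X, list(g1), list(d1), sets)
  expect_equal(enc$O, oracle_gat_forward(X, g1, sets), tolerance = 1e-10)
  expect_equal(enc$hidden[[1]],
               t(apply(enc$O, 1, oracle_dbn_forward, W = d1$weights,
                       b = d1$biases)), tolerance = 1e-10)
  # two rounds: second GAT consumes cbind(O, hidden)
  g2 <- gat_layer_params(6, 4, dropout_rate = 0)
  d2 <- dbn_layer_params(4, 2)
  enc2 <- interleaved_encode(X, list(g1, g2), list(d1, d2), sets)
  sets_in <- sets  # graph is shared across rounds
  O2 <- oracle_gat_forward(cbind(enc$O, enc$hidden[[1]]), g2, sets_in)
  expect_equal(enc2$O, O2, tolerance = 1e-10)
  # duplicated input rows produce duplicated output rows
  Xd <- rbind(X, X[1, ])
  setsd <- build_neighbor_sets(Xd, 0.2, 0.5)
  encd <- interleaved_encode(Xd, list(g1), list(d1), setsd)
  expect_equal(encd$O[1, ], encd$O[5, ], tolerance = 1e-10)
  expect_error(interleaved_encode(X, list(g1, g1), list(d1, d1), sets),
               "dimension mismatch")
})

test_that("soft assignment is the normalized Student-t kernel", {
  # k = 1 is all ones
  H <- matrix(rnorm(6), 3, 2)
  expect_equal(drop(soft_assignment(H, H[1, , drop = FALSE])), rep(1, 3))
  # equidistant point splits 0.5 / 0.5
  D <- soft_assignment(matrix(c(0, 0), 1), rbind(c(1, 0), c(-1, 0)))
  expect_equal(drop(D), c(0.5, 0.5))
  # hand-computed 3x2 fixture at v_c = 1
  H3 <- rbind(c(0, 0), c(1, 0), c(4, 0))
  C2 <- rbind(c(0, 0), c(4, 0))
  D3 <- soft_assignment(H3, C2, v_c = 1)
  expect_equal(D3, rbind(c(17 / 18, 1 / 18), c(5 / 6, 1 / 6),
                         c(1 / 18, 17 / 18)), tolerance = 1e-12)
  expect_equal(D3, oracle_soft_assignment(H3, C2, 1), tolerance = 1e-12)
  expect_error(soft_assignment(H3, matrix(0, 2, 3)), "dimension mismatch")
})

test_that("target distribution sharpens and matches the scalar oracle", {
  # one-hot rows are a fixed point
  D1 <- rbind(c(1, 0), c(0, 1))
  expect_equal(target_distribution(D1), D1)
  # uniform D with equal frequencies stays uniform
  Du <- matrix(1 / 3, 4, 3)
  expect_equal(target_distribution(Du), Du)
  # 2x2 fixture, frozen from the scalar oracle
  D <- rbind(c(0.8, 0.2), c(0.4, 0.6))
  P <- target_distribution(D)
  expect_equal(P, rbind(c(0.914285714285714, 0.0857142857142857),
                        c(0.228571428571429, 0.771428571428571)),
               tolerance = 1e-12)
  expect_equal(P, oracle_target_distribution(D), tolerance = 1e-12)
  # sharpening: the dominant entry grows when frequencies are equal
  Deq <- rbind(c(0.7, 0.3), c(0.3, 0.7))
  Peq <- target_distribution(Deq)
  expect_true(Peq[1, 1] > Deq[1, 1])
  expect_error(target_distribution(rbind(c(1, 0), c(1, 0))), "degenerate")
})

test_that("KL divergence is non-negative, zero iff equal, oracle-exact", {
  P <- random_stochastic(4, 3, seed = 11)
  expect_equal(kl_loss(P, P), 0)
  expect_equal(kl_loss(matrix(c(1, 0), 1), matrix(c(0.5, 0.5), 1)), log(2),
               tolerance = 1e-9)
  for (s in 1:25) {
    A <- random_stochastic(3, 4, seed = 500 + s)
    B <- random_stochastic(3, 4, seed = 600 + s)
    expect_gte(kl_loss(A, B), 0)
    expect_equal(kl_loss(A, B), oracle_kl(A, B), tolerance = 1e-10)
  }
  expect_error(kl_loss(P, P[, 1:2]), "shape mismatch")
})

test_that("training recovers planted clusters and honors its contracts", {
  g <- generate_clustered_features(40, 2, 10, dim = 8, seed = 7)
  m <- train_relevance_model(g$features,
                             training_config(k = 2, epochs = 3,
                                             steps_per_epoch = 8,
                                             seed = 11))
  tab <- table(m$assignments, g$labels)
  agree <- max(sum(diag(tab)), sum(tab) - sum(diag(tab))) / sum(tab)
  expect_gte(agree, 0.9)
  # distributions stay row-stochastic after training
  expect_equal(rowSums(m$D), rep(1, 40), tolerance = 1e-9)
  expect_equal(rowSums(m$P), rep(1, 40), tolerance = 1e-9)
  expect_equal(rowSums(m$K), rep(1, 40), tolerance = 1e-9)
  # the loss trend within each epoch (frozen target) is downward
  tr <- matrix(m$loss_trajectory, ncol = 3)
  for (e in 1:2) {
    expect_lte(mean(tail(tr[, e], 3)), mean(head(tr[, e], 3)) + 1e-3)
  }
  # duplicated events: learned relevance of duplicates dominates
  phi <- as.matrix(g$features)
  phid <- rbind(phi[1:10, ], phi[1, ])
  rownames(phid) <- sprintf("ev-%02d", 1:11)
  md <- train_relevance_model(event_feature_matrix(phid, rownames(phid)),
                              training_config(k = 2, epochs = 1,
                                              steps_per_epoch = 3,
                                              seed = 13))
  expect_gte(md$correlation[1, 11] + 1e-9, max(md$correlation[1, 2:10]))
})

test_that("training is deterministic and masks the centroid path at lambda2=0", {
  g <- generate_clustered_features(12, 2, 8, dim = 6, seed = 3)
  cfg <- training_config(k = 2, epochs = 2, steps_per_epoch = 3, seed = 29,
                         layer_dims = list(gat_out = 4L, dbn_hidden = 3L))
  m1 <- train_relevance_model(g$features, cfg)
  m2 <- train_relevance_model(g$features, cfg)
  expect_identical(m1$loss_trajectory, m2$loss_trajectory)
  expect_identical(m1$features, m2$features)
  # lambda1 = 1: the D-path gradient vanishes, so centroids never move
  cfg1 <- training_config(k = 2, lambda1 = 1, lambda2 = 0, epochs = 2,
                          steps_per_epoch = 3, seed = 29,
                          layer_dims = list(gat_out = 4L, dbn_hidden = 3L))
  mm <- train_relevance_model(g$features, cfg1)
  expect_equal(mm$params$centroids, mm$initial_centroids, tolerance = 1e-12)
})
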