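# Joint adjustment: fuse a centroid-distance (k-means) view and a
# density-connectivity (DBSCAN) view of the learned feature space into the
# final event correlation matrix.

# Mean silhouette width, implemented directly from the definition so the
# test suite can cross-check it against cluster::silhouette.
mean_silhouette <- function(features, labels) {
  X <- as.matrix(features)
  d <- as.matrix(stats::dist(X))
  n <- nrow(X)
  cl <- unique(labels)
  if (length(cl) < 2) return(NA_real_)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(labels == labels[i]); own <- setdiff(own, i)
    if (!length(own)) { s[i] <- 0; next }
    a <- mean(d[i, own])
    b <- min(vapply(setdiff(cl, labels[i]), function(c2)
      mean(d[i, labels == c2]), numeric(1)))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

#' Select the number of clusters
#'
#' Runs k-means for each candidate k and returns the k maximizing the mean
#' silhouette width; ties (within 1e-9) are broken by the elbow criterion
#' (largest second difference of the within-cluster sum of squares), then by
#' the smaller k. Constant (zero-variance) features yield k = 2 with a
#' degenerate-input warning.
#'
#' @param features Numeric matrix, n >= 3 rows.
#' @param k_range Candidate k values within \[2, n - 1\].
#' @return Integer k.
#' @export
select_k <- function(features, k_range = 2:6) {
  X <- as.matrix(features)
  n <- nrow(X)
  if (n < 3) stop("need at least 3 observations to select k")
  k_range <- sort(unique(as.integer(k_range)))
  if (any(k_range < 2 | k_range > n - 1))
    stop("k_range must lie within [2, n - 1]")
  if (all(apply(X, 2, stats::var) < 1e-24)) {
    warning("constant features: k selection is degenerate, returning 2")
    return(2L)
  }
  sil <- numeric(length(k_range)); wss <- numeric(length(k_range))
  for (i in seq_along(k_range)) {
    km <- stats::kmeans(X, centers = k_range[i], nstart = 5)
    sil[i] <- mean_silhouette(X, km$cluster)
    wss[i] <- km$tot.withinss
  }
  best <- which(sil > max(sil) - 1e-9)
  if (length(best) > 1 && length(k_range) >= 3) {
    # elbow: second difference of WSS, defined for interior candidates
    d2 <- rep(-Inf, length(k_range))
    interior <- 2:(length(k_range) - 1)
    d2[interior] <- wss[interior - 1] - 2 * wss[interior] + wss[interior + 1]
    best <- best[order(-d2[best], k_range[best])]
  }
  k_range[best[1]]
}

#' Centroid-distance correlations from k-means
#'
#' Co-clustered events i, j receive
#' `1 - ||h_i - h_j|| / (2 * r_max)` where `r_max` is the largest distance
#' of any member of that cluster to its centroid (floored away from zero);
#' cross-cluster pairs receive 0 and the diagonal is 1. Values are clipped
#' to \[0, 1\]. An empty cluster triggers one re-seeded retry.
#'
#' @param features Numeric matrix.
#' @param k Number of clusters.
#' @return List with `matrix` (n x n), `labels`, `centroids`.
#' @export
kmeans_correlation <- function(features, k) {
  X <- as.matrix(features)
  n <- nrow(X)
  km <- tryCatch(stats::kmeans(X, centers = k, nstart = 5),
                 error = function(e) NULL)
  if (is.null(km) || length(unique(km$cluster)) < k) {
    km <- tryCatch(stats::kmeans(X, centers = k, nstart = 10),
                   error = function(e)
                     stop("k-means produced an empty cluster twice"))
  }
  C <- matrix(0, n, n)
  for (cl in unique(km$cluster)) {
    idx <- which(km$cluster == cl)
    cen <- km$centers[cl, ]
    r_max <- max(sqrt(colSums((t(X[idx, , drop = FALSE]) - cen)^2)))
    r_max <- max(r_max, 1e-12)
    for (a in seq_along(idx)) {
      for (b in seq_along(idx)) {
        if (a == b) next
        dd <- sqrt(sum((X[idx[a], ] - X[idx[b], ])^2))
        C[idx[a], idx[b]] <- 1 - dd / (2 * r_max)
      }
    }
  }
  C[C < 0] <- 0; C[C > 1] <- 1
  diag(C) <- 1
  list(matrix = C, labels = km$cluster, centroids = km$centers)
}

#' Density-based clustering (DBSCAN)
#'
#' Classic DBSCAN over Euclidean distances. A point is a core point when at
#' least `min_pts` points (itself included) lie within `eps`; clusters are
#' the connected components of core points under eps-reachability, border
#' points join the cluster of a reachable core, and everything else is
#' noise (label -1).
#'
#' @param features Numeric matrix.
#' @param eps Neighborhood radius.
#' @param min_pts Core-point density threshold.
#' @return Integer labels (length n); -1 marks noise.
#' @export
dbscan_cluster <- function(features, eps, min_pts = 4L) {
  stopifnot(eps > 0)
  X <- as.matrix(features)
  n <- nrow(X)
  d <- as.matrix(stats::dist(X))
  nb <- lapply(seq_len(n), function(i) which(d[i, ] <= eps))
  core <- lengths(nb) >= min_pts
  labels <- rep(-1L, n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (!core[i] || labels[i] != -1L) next
    cl <- cl + 1L
    queue <- i
    labels[i] <- cl
    while (length(queue)) {
      p <- queue[1]; queue <- queue[-1]
      for (q in nb[[p]]) {
        if (labels[q] == -1L) {
          labels[q] <- cl
          if (core[q]) queue <- c(queue, q)
        }
      }
    }
  }
  labels
}

#' Path-length correlations from DBSCAN
#'
#' Builds the eps-neighborhood graph over non-noise points; events in the
#' same density cluster receive `1 / (1 + hops)` where `hops` is the
#' shortest-path hop count between them, so direct eps-neighbors score 1/2.
#' Noise points and cross-cluster pairs receive 0; the diagonal is 1.
#'
#' @param features Numeric matrix.
#' @param eps Neighborhood radius; default half the median pairwise
#'   distance.
#' @param min_pts Core-point threshold (default 4).
#' @return List with `matrix` (n x n) and `labels`.
#' @export
dbscan_correlation <- function(features, eps = NULL, min_pts = 4L) {
  X <- as.matrix(features)
  n <- nrow(X)
  d <- as.matrix(stats::dist(X))
  if (is.null(eps)) {
    pd <- d[upper.tri(d)]
    eps <- if (length(pd)) stats::median(pd) * 0.5 else 1
    if (eps <= 0) eps <- 1e-6
  }
  labels <- dbscan_cluster(X, eps, min_pts)
  C <- matrix(0, n, n)
  keep <- which(labels != -1L)
  if (length(keep) >= 2) {
    adj <- (d[keep, keep, drop = FALSE] <= eps)
    diag(adj) <- FALSE
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    hops <- igraph::distances(g)
    for (a in seq_along(keep)) {
      for (b in seq_along(keep)) {
        if (a == b) next
        if (labels[keep[a]] == labels[keep[b]] && is.finite(hops[a, b])) {
          C[keep[a], keep[b]] <- 1 / (1 + hops[a, b])
        }
      }
    }
  }
  diag(C) <- 1
  list(matrix = C, labels = labels, eps = eps)
}

#' Fuse the two correlation views
#'
#' `Rel = weight * C_km + (1 - weight) * C_db`. When the density view
#' assigns everything to noise (all zeros off-diagonal) the geometric view
#' is returned alone with a warning rather than diluting it.
#'
#' @param C_km,C_db Same-shape correlation matrices.
#' @param event_ids Ids labeling the rows/columns.
#' @param weight Fusion weight in \[0, 1\] (default 0.5).
#' @return A [correlation_matrix()].
#' @export
fuse_correlations <- function(C_km, C_db, event_ids, weight = 0.5) {
  stopifnot(weight >= 0, weight <= 1)
  if (!all(dim(C_km) == dim(C_db))) stop("correlation shape mismatch")
  off_db <- C_db; diag(off_db) <- 0
  if (all(off_db == 0) && weight < 1) {
    warning("density view is all noise; falling back to the k-means view")
    return(correlation_matrix(C_km, event_ids))
  }
  correlation_matrix(weight * C_km + (1 - weight) * C_db, event_ids)
}

#' Compute the fused event correlation matrix
#'
#' Convenience wrapper: selects k (unless given), computes both clustering
#' views on the same features, and fuses them.
#'
#' @param features Numeric matrix with rownames = event ids (e.g. the
#'   `features` field of a trained relevance model, or an
#'   [event_feature_matrix()]).
#' @param k Number of clusters (`NULL` = select by silhouette/elbow).
#' @param eps,min_pts DBSCAN parameters (see [dbscan_correlation()]).
#' @param weight Fusion weight.
#' @return A [correlation_matrix()].
#' @export
event_correlations <- function(features, k = NULL, eps = NULL,
                               min_pts = 4L, weight = 0.5) {
  X <- as.matrix(features)
  ids <- rownames(X)
  if (is.null(ids)) ids <- sprintf("ev-%06d", seq_len(nrow(X)))
  if (is.null(k)) k <- select_k(X, 2:max(2, min(6, nrow(X) - 1)))
  km <- kmeans_correlation(X, k)
  db <- dbscan_correlation(X, eps, min_pts)
  fuse_correlations(km$matrix, db$matrix, ids, weight)
}

#' Write / read a correlation matrix as labeled TSV
#'
#' @param rel A [correlation_matrix()].
#' @param path File path.
#' @export
write_correlations <- function(rel, path) {
  df <- data.frame(event_id = rownames(rel), as.data.frame(unclass(rel)),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(NULL)
}

#' @rdname write_correlations
#' @export
read_correlations <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, fileEncoding = "UTF-8")
  ids <- df$event_id
  m <- as.matrix(df[, -1, drop = FALSE])
  correlation_matrix(m, ids)
}
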