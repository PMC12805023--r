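#' Depth-normalise and log-transform counts
#'
#' Scales each observation's counts to a common total (the median library
#' size by default) and applies `log1p`. Rank-based signature scores are
#' invariant to any such monotone per-observation transform, so this choice
#' only affects clustering geometry.
#'
#' @param nm a `nucleus_matrix` / `square_bin_matrix`, or a bare counts
#'   matrix (observations x genes).
#' @param target scaling target; default `median(total counts)`.
#' @return A dense/sparse numeric matrix of log-normalised expression with
#'   the input dimnames; attribute `target` records the scaling total.
#' @export
normalize_log <- function(nm, target = NULL) {
  counts <- if (inherits(nm, "bin_matrix")) nm$counts else nm
  tot <- rowSums(counts)
  if (any(tot == 0)) {
    abort("zero-count observation; run QC before normalising",
          class = "nucbin_validation_error")
  }
  target <- target %||% median(tot)
  out <- log1p(counts * (target / tot))
  attr(out, "target") <- target
  out
}

# PC scores of observations; genes centred and unit-scaled (zero-variance
# genes dropped)
pca_embed <- function(norm, n_pcs = 30) {
  x <- as.matrix(norm)
  v <- apply(x, 2, var)
  x <- x[, v > 0, drop = FALSE]
  if (ncol(x) == 0L) {
    # fully degenerate input (all observations identical)
    return(matrix(0, nrow(norm), 1L,
                  dimnames = list(rownames(norm), "PC1")))
  }
  n_pcs <- min(n_pcs, nrow(x) - 1L, ncol(x))
  p <- prcomp(x, center = TRUE, scale. = TRUE, rank. = n_pcs)
  p$x
}

# k nearest neighbours (self excluded) from a dense embedding; returns an
# n x k index matrix. Brute-force distances: intended for desk-scale n.
knn_index <- function(emb, k) {
  d <- as.matrix(dist(emb))
  diag(d) <- Inf
  t(apply(d, 1, function(row) order(row)[seq_len(k)]))
}

#' Graph-based clustering of normalised expression
#'
#' PCA, a shared-nearest-neighbor (Jaccard-weighted) graph, and Leiden
#' modularity community detection. Cluster labels are relabelled in order of
#' decreasing size, so the result is deterministic given the seed.
#'
#' @param norm normalised matrix from [normalize_log()].
#' @param n_pcs number of principal components (capped at `n - 1`).
#' @param n_neighbors k of the nearest-neighbor graph.
#' @param resolution Leiden resolution parameter.
#' @param seed integer seed.
#' @return A `cluster_result`: list with `labels` (factor, named by
#'   observation), `embedding` (PC scores) and `params`.
#' @export
cluster_graph <- function(norm, n_pcs = 30, n_neighbors = 15, resolution = 1,
                          seed = 1L) {
  n <- nrow(norm)
  if (n <= n_neighbors) {
    abort("fewer observations than n_neighbors", class = "nucbin_validation_error")
  }
  emb <- pca_embed(norm, n_pcs)
  if (all(emb == emb[1, 1])) {
    # all observations identical: one community by definition
    labels <- factor(rep(1L, n), levels = 1L)
    names(labels) <- rownames(norm)
    return(structure(list(labels = labels, embedding = emb,
                          params = list(n_pcs = n_pcs,
                                        n_neighbors = n_neighbors,
                                        resolution = resolution, seed = seed)),
                     class = "cluster_result"))
  }
  k <- n_neighbors
  nn <- knn_index(emb, k)
  # shared-neighbor (Jaccard) weights; neighbour sets include self
  adj <- sparseMatrix(i = rep(seq_len(n), k + 1L),
                      j = c(as.vector(nn), seq_len(n)),
                      x = 1, dims = c(n, n))
  shared <- Matrix::tcrossprod(adj)
  tr <- Matrix::summary(shared)
  jac <- tr$x / (2 * (k + 1L) - tr$x)
  keep <- jac >= 1 / 15 & tr$i < tr$j
  g <- igraph::graph_from_data_frame(
    data.frame(from = tr$i[keep], to = tr$j[keep], weight = jac[keep]),
    directed = FALSE,
    vertices = data.frame(name = seq_len(n))
  )
  set.seed(seed)
  comm <- igraph::cluster_leiden(
    g, objective_function = "modularity",
    resolution = resolution, n_iterations = 10
  )
  memb <- igraph::membership(comm)
  memb <- memb[as.character(seq_len(n))]
  sizes <- sort(table(memb), decreasing = TRUE)
  relab <- setNames(seq_along(sizes), names(sizes))
  labels <- factor(relab[as.character(memb)], levels = seq_along(sizes))
  names(labels) <- rownames(norm)
  structure(list(
    labels = labels,
    embedding = emb,
    params = list(n_pcs = n_pcs, n_neighbors = n_neighbors,
                  resolution = resolution, seed = seed)
  ), class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result> %d observations in %d clusters\n",
              length(x$labels), nlevels(x$labels)))
  invisible(x)
}

#' @rdname nucbin-tidiers
#' @method tidy cluster_result
#' @export
tidy.cluster_result <- function(x, ...) {
  tibble(id = names(x$labels) %||% as.character(seq_along(x$labels)),
         cluster = x$labels)
}

#' @rdname nucbin-tidiers
#' @method glance cluster_result
#' @export
glance.cluster_result <- function(x, ...) {
  tibble(n_obs = length(x$labels), n_clusters = nlevels(x$labels),
         resolution = x$params$resolution)
}

#' Neighborhood label-consistency (assignment) score
#'
#' For each observation, the fraction of its `k` nearest neighbours in the
#' embedding (self excluded) that carry the same cluster label. Well-resolved
#' clusters have per-cluster median scores near 1.
#'
#' @param embedding numeric matrix of observation coordinates (e.g. PCs).
#' @param labels cluster labels (factor or vector), one per observation.
#' @param k number of neighbours (1 <= k < n).
#' @return Numeric vector of per-observation scores in `[0, 1]`.
#' @export
assignment_score <- function(embedding, labels, k = 15) {
  n <- nrow(embedding)
  if (k < 1 || k >= n) {
    abort("k must satisfy 1 <= k < n", class = "nucbin_validation_error")
  }
  labels <- as.character(labels)
  nn <- knn_index(embedding, k)
  vapply(seq_len(n), function(i) mean(labels[nn[i, ]] == labels[i]), numeric(1))
}

#' Per-cluster medians of the assignment score
#'
#' @inheritParams assignment_score
#' @return Tibble with `cluster` and `median_score`.
#' @export
assignment_score_medians <- function(embedding, labels, k = 15) {
  s <- assignment_score(embedding, labels, k)
  tibble(cluster = labels, score = s) |>
    dplyr::group_by(.data$cluster) |>
    dplyr::summarise(median_score = median(.data$score), .groups = "drop")
}

#' Adjusted Rand index between two partitions
#'
#' @param a,b label vectors of equal length.
#' @return The adjusted Rand index (1 = identical partitions, ~0 = chance).
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  n <- length(a)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  expected <- si * sj / choose(n, 2)
  mx <- (si + sj) / 2
  if (mx == expected) return(1)
  (sij - expected) / (mx - expected)
}

#' k-NN batch-mixing entropy
#'
#' Mean over observations of the Shannon entropy of batch labels among each
#' observation's `k` nearest neighbours, normalised by `log(n_batches)`;
#' 1 means batches are perfectly mixed locally, 0 means fully separated.
#'
#' @param embedding numeric matrix of observation coordinates.
#' @param batch batch label per observation.
#' @param k number of neighbours.
#' @return Scalar in `[0, 1]`.
#' @export
knn_mixing_entropy <- function(embedding, batch, k = 15) {
  batch <- as.factor(batch)
  nn <- knn_index(embedding, k)
  ent <- vapply(seq_len(nrow(embedding)), function(i) {
    p <- table(batch[nn[i, ]]) / k
    p <- p[p > 0]
    -sum(p * log(p))
  }, numeric(1))
  mean(ent) / log(nlevels(batch))
}
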