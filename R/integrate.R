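# per-gene standardisation (columns centred, unit variance; zero-variance
# genes left at 0)
standardize_genes <- function(x) {
  x <- as.matrix(x)
  mu <- colMeans(x)
  sd_ <- apply(x, 2, sd)
  sd_[sd_ == 0] <- 1
  sweep(sweep(x, 2, mu, "-"), 2, sd_, "/")
}

#' Most variable genes across datasets
#'
#' Ranks genes of the shared panel by their mean within-dataset variance of
#' log-normalised expression.
#'
#' @param norm_list list of normalised matrices (observations x genes).
#' @param n number of genes to keep.
#' @return Character vector of gene names.
#' @export
variable_genes <- function(norm_list, n = 2000) {
  shared <- Reduce(intersect, lapply(norm_list, colnames))
  if (!length(shared)) {
    abort("empty gene intersection across datasets",
          class = "nucbin_validation_error")
  }
  v <- rowMeans(vapply(norm_list, function(m) {
    apply(as.matrix(m[, shared, drop = FALSE]), 2, var)
  }, numeric(length(shared))))
  head(shared[order(v, decreasing = TRUE)], n)
}

#' Canonical-correlation projection of two datasets
#'
#' Diagonal canonical correlation analysis on the shared gene axis: both
#' matrices are standardised per gene, the cross-product
#' `K = X1 %*% t(X2)` is decomposed by SVD, and the left/right singular
#' vectors give paired per-observation embeddings (L2-normalised per
#' observation). The reported canonical correlations are the cosines of the
#' paired gene-space variates; components are ordered so the correlations
#' are non-increasing.
#'
#' @param x1,x2 normalised matrices (observations x genes) sharing gene
#'   names (intersection taken).
#' @param n_cc number of canonical dimensions.
#' @return List with `u` (n1 x n_cc), `v` (n2 x n_cc), `correlations`.
#' @export
cca_project <- function(x1, x2, n_cc = 20) {
  shared <- intersect(colnames(x1), colnames(x2))
  if (!length(shared)) {
    abort("empty gene intersection", class = "nucbin_validation_error")
  }
  n_cc <- min(n_cc, nrow(x1), nrow(x2), length(shared))
  s1 <- standardize_genes(x1[, shared, drop = FALSE])
  s2 <- standardize_genes(x2[, shared, drop = FALSE])
  k <- tcrossprod(s1, s2)
  sv <- if (min(dim(k)) > 400) truncated_svd(k, n_cc) else
    svd(k, nu = n_cc, nv = n_cc)
  u <- sv$u; v <- sv$v
  # cosine of the paired gene-space variates a_i = t(s1) u_i, b_i = t(s2) v_i
  a <- crossprod(s1, u)
  b <- crossprod(s2, v)
  cors <- vapply(seq_len(n_cc), function(i) {
    na <- sqrt(sum(a[, i]^2)); nb <- sqrt(sum(b[, i]^2))
    if (na == 0 || nb == 0) 0 else sum(a[, i] * b[, i]) / (na * nb)
  }, numeric(1))
  ord <- order(cors, decreasing = TRUE)
  u <- u[, ord, drop = FALSE]; v <- v[, ord, drop = FALSE]
  cors <- cors[ord]
  l2 <- function(m) m / pmax(sqrt(rowSums(m^2)), 1e-12)
  list(u = l2(u), v = l2(v), correlations = cors)
}

# randomized truncated SVD (Halko-style, two power iterations). Uses an
# internally seeded projection and restores the caller's RNG state, so
# results are deterministic and independent of the surrounding RNG stream.
truncated_svd <- function(k, rank, oversample = 10L) {
  rank <- min(rank, dim(k))
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(271828L)
  p <- min(rank + oversample, ncol(k))
  omega <- matrix(rnorm(ncol(k) * p), ncol(k), p)
  y <- k %*% omega
  for (it in 1:2) {
    y <- qr.Q(qr(y))
    y <- k %*% crossprod(k, y)
  }
  q <- qr.Q(qr(y))
  b <- crossprod(q, k)
  sb <- svd(b, nu = rank, nv = rank)
  list(u = q %*% sb$u, d = sb$d[seq_len(rank)], v = sb$v)
}

#' Mutual-nearest-neighbor anchors in canonical space
#'
#' An anchor is a pair `(a, b)` where `b` is among `a`'s `k_anchor` nearest
#' neighbours in the second embedding and vice versa. Each anchor is scored
#' by the shared-neighbor overlap fraction of the two cells in the joint
#' embedding (the pair itself excluded).
#'
#' @param u1,u2 paired embeddings from [cca_project()].
#' @param k_anchor neighbours considered for mutuality.
#' @param k_score neighbours used for the overlap score.
#' @return An `anchor_set` tibble `(i, j, score)` with attribute `n_cc`.
#' @export
find_anchors <- function(u1, u2, k_anchor = 5, k_score = 30) {
  n1 <- nrow(u1); n2 <- nrow(u2)
  if (k_anchor >= min(n1, n2)) {
    abort("k_anchor must be smaller than both datasets",
          class = "nucbin_validation_error")
  }
  cross <- as.matrix(dist(rbind(u1, u2)))[seq_len(n1), n1 + seq_len(n2),
                                          drop = FALSE]
  nn12 <- t(apply(cross, 1, function(r) order(r)[seq_len(k_anchor)]))
  nn21 <- t(apply(cross, 2, function(r) order(r)[seq_len(k_anchor)]))
  pairs <- purrr::map_dfr(seq_len(n1), function(a) {
    bs <- nn12[a, ][vapply(nn12[a, ], function(b) a %in% nn21[b, ], logical(1))]
    if (length(bs)) tibble(i = a, j = as.integer(bs)) else NULL
  })
  joint <- rbind(u1, u2)
  k_score <- min(k_score, nrow(joint) - 2L)
  dj <- as.matrix(dist(joint))
  diag(dj) <- Inf
  score <- vapply(seq_len(nrow(pairs)), function(r) {
    a <- pairs$i[r]; b <- n1 + pairs$j[r]
    da <- dj[a, ]; da[b] <- Inf
    db <- dj[b, ]; db[a] <- Inf
    na_ <- order(da)[seq_len(k_score)]
    nb_ <- order(db)[seq_len(k_score)]
    length(intersect(na_, nb_)) / k_score
  }, numeric(1))
  out <- dplyr::mutate(pairs, score = score)
  class(out) <- c("anchor_set", class(out))
  out
}

#' Integrate datasets by anchor-based correction
#'
#' A reduced anchoring workflow: the largest dataset is the reference; every
#' other dataset is projected with the reference by [cca_project()], mutual
#' nearest neighbours become anchors, and each query observation is
#' corrected by a Gaussian-kernel weighted mean of its `k_weight` nearest
#' anchors' (reference - query) expression differences on the shared gene
#' panel. Corrected matrices are concatenated.
#'
#' @param norm_list named list of normalised matrices (observations x
#'   genes).
#' @param n_cc canonical dimensions.
#' @param k_anchor neighbours for anchor mutuality.
#' @param k_weight anchors used per correction (capped at the anchor count).
#' @param n_var number of variable genes for the canonical decomposition.
#' @return List with `corrected` (stacked matrix on the shared panel),
#'   `dataset` (origin per row), `anchors` (per-query anchor tibbles), and
#'   `unanchored` (datasets passed through uncorrected).
#' @export
integrate_datasets <- function(norm_list, n_cc = 20, k_anchor = 5,
                               k_weight = 50, n_var = 2000) {
  if (length(norm_list) < 2L) {
    abort("need at least 2 datasets", class = "nucbin_validation_error")
  }
  if (is.null(names(norm_list))) {
    names(norm_list) <- paste0("dataset", seq_along(norm_list))
  }
  shared <- Reduce(intersect, lapply(norm_list, colnames))
  if (!length(shared)) {
    abort("empty gene intersection", class = "nucbin_validation_error")
  }
  mats <- lapply(norm_list, function(m) as.matrix(m[, shared, drop = FALSE]))
  var_genes <- variable_genes(mats, n_var)
  ref_name <- names(mats)[which.max(vapply(mats, nrow, numeric(1)))]
  ref <- mats[[ref_name]]

  anchors_out <- list()
  unanchored <- character()
  corrected <- lapply(names(mats), function(nm_) {
    q <- mats[[nm_]]
    if (nm_ == ref_name) return(q)
    cc <- cca_project(ref[, var_genes, drop = FALSE],
                      q[, var_genes, drop = FALSE], n_cc)
    anc <- find_anchors(cc$u, cc$v, k_anchor)
    anchors_out[[nm_]] <<- anc
    if (nrow(anc) == 0L) {
      warn(sprintf("no anchors between '%s' and reference '%s'; passed through uncorrected",
                   nm_, ref_name))
      unanchored <<- c(unanchored, nm_)
      return(q)
    }
    diffs <- ref[anc$i, , drop = FALSE] - q[anc$j, , drop = FALSE]
    kw <- min(k_weight, nrow(anc))
    # anchors are located at the midpoint of their two embeddings, so the
    # symmetric pairs (i,j)/(j,i) arising when datasets coincide receive
    # equal weights and their opposite differences cancel exactly
    anchor_pos <- (cc$u[anc$i, , drop = FALSE] + cc$v[anc$j, , drop = FALSE]) / 2
    d_anchor <- as.matrix(dist(rbind(cc$v, anchor_pos)))
    d_anchor <- d_anchor[seq_len(nrow(q)), nrow(q) + seq_len(nrow(anc)),
                         drop = FALSE]
    corr <- matrix(0, nrow(q), ncol(q))
    for (c_i in seq_len(nrow(q))) {
      dd <- d_anchor[c_i, ]
      cut <- sort(dd, partial = kw)[kw]
      # keep boundary ties (with fp tolerance) so symmetric pairs co-select
      sel <- which(dd <= cut * (1 + 1e-9) + 1e-12)
      bw <- max(cut, 1e-12)
      w <- exp(-(dd[sel] / bw)^2) * pmax(anc$score[sel], 1e-6)
      w <- w / sum(w)
      corr[c_i, ] <- colSums(w * diffs[sel, , drop = FALSE])
    }
    q + corr
  })
  names(corrected) <- names(mats)
  out <- do.call(rbind, corrected)
  list(
    corrected = out,
    dataset = rep(names(mats), vapply(mats, nrow, numeric(1))),
    reference = ref_name,
    anchors = anchors_out,
    unanchored = unanchored
  )
}
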