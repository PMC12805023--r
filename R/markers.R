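#' Two-sided Wilcoxon rank-sum test
#'
#' Mann-Whitney test of two samples. The statistic is `U` for `x`. For small
#' untied samples the exact null distribution is used; with ties the exact
#' p-value is obtained by complete enumeration when the pooled size is at
#' most `enum_limit`; otherwise the normal approximation with tie correction
#' and continuity correction is applied.
#'
#' @param x,y numeric samples.
#' @param enum_limit pooled-size cap for complete enumeration under ties.
#' @return One-row tibble: `statistic` (U for `x`), `p_value`, `method`.
#' @export
wilcox_rank_sum <- function(x, y, enum_limit = 14L) {
  n1 <- length(x); n2 <- length(y)
  stopifnot(n1 >= 1, n2 >= 1)
  pooled <- c(x, y)
  r <- rank(pooled)
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- anyDuplicated(pooled) > 0L

  if (!ties && n1 <= 50 && n2 <= 50) {
    p <- if (u > n1 * n2 / 2) {
      2 * (1 - pwilcox(u - 1, n1, n2))
    } else {
      2 * pwilcox(u, n1, n2)
    }
    method <- "exact"
  } else if (n1 + n2 <= enum_limit) {
    idx <- utils::combn(n1 + n2, n1)
    us <- colSums(matrix(r[idx], nrow = n1)) - n1 * (n1 + 1) / 2
    p <- 2 * min(mean(us <= u), mean(us >= u))
    method <- "exact-enumeration"
  } else {
    mu <- n1 * n2 / 2
    nt <- n1 + n2
    tie_tab <- table(pooled)
    sig2 <- n1 * n2 / 12 * ((nt + 1) - sum(tie_tab^3 - tie_tab) / (nt * (nt - 1)))
    z <- u - mu
    z <- (z - sign(z) * 0.5) / sqrt(sig2)
    p <- 2 * pnorm(-abs(z))
    method <- "normal-approximation"
  }
  tibble(statistic = u, p_value = min(1, p), method = method)
}

#' One-vs-rest cluster marker genes
#'
#' For each cluster, each gene is tested one cluster versus all others with
#' the Wilcoxon rank-sum test on normalised expression; the log2 fold-change
#' compares the cluster mean to the rest mean (on de-logged values, with a
#' pseudocount of 1). P-values are Benjamini-Hochberg adjusted within each
#' cluster. Clusters of size 1 are flagged and omitted from the table.
#'
#' For pooled sizes above 20 observations the normal approximation with tie
#' correction is used; smaller problems are tested exactly.
#'
#' @param norm normalised matrix from [normalize_log()].
#' @param labels cluster labels, one per row of `norm`.
#' @return A tibble `(cluster, gene, lfc, p_value, p_adj)` with attribute
#'   `flagged_clusters` (singleton clusters).
#' @export
rank_markers <- function(norm, labels) {
  labels <- as.factor(labels)
  if (nlevels(droplevels(labels)) < 2L) {
    abort("need at least 2 clusters", class = "nucbin_validation_error")
  }
  x <- as.matrix(norm)
  n <- nrow(x)
  genes <- colnames(x) %||% paste0("g", seq_len(ncol(x)))
  sizes <- table(labels)
  flagged <- names(sizes)[sizes == 1L]
  expr <- expm1(x)

  res <- purrr::map_dfr(setdiff(levels(labels), flagged), function(cl) {
    in_cl <- labels == cl
    n1 <- sum(in_cl); n2 <- n - n1
    if (n <= 20L) {
      tests <- purrr::map_dfr(seq_len(ncol(x)), function(j) {
        wilcox_rank_sum(x[in_cl, j], x[!in_cl, j])
      })
      p <- tests$p_value
    } else {
      # vectorised tie-corrected normal approximation over genes
      r <- apply(x, 2, rank)
      u <- colSums(r[in_cl, , drop = FALSE]) - n1 * (n1 + 1) / 2
      sig2 <- vapply(seq_len(ncol(x)), function(j) {
        tt <- table(x[, j])
        n1 * n2 / 12 * ((n + 1) - sum(tt^3 - tt) / (n * (n - 1)))
      }, numeric(1))
      z <- u - n1 * n2 / 2
      z <- ifelse(sig2 > 0, (z - sign(z) * 0.5) / sqrt(sig2), 0)
      p <- 2 * pnorm(-abs(z))
      p <- pmin(1, p)
    }
    mc <- colMeans(expr[in_cl, , drop = FALSE])
    mr <- colMeans(expr[!in_cl, , drop = FALSE])
    tibble(
      cluster = cl,
      gene = genes,
      lfc = log2((mc + 1) / (mr + 1)),
      p_value = p,
      p_adj = p.adjust(p, method = "BH")
    )
  })
  attr(res, "flagged_clusters") <- flagged
  res
}

#' Top markers per cluster
#'
#' Extracts the `k` strongest upregulated genes per cluster, ordered by
#' adjusted p-value then absolute log fold-change.
#'
#' @param markers output of [rank_markers()].
#' @param k markers per cluster (default 3).
#' @return Tibble of at most `k` rows per cluster.
#' @export
top_markers <- function(markers, k = 3) {
  markers |>
    dplyr::filter(.data$lfc > 0) |>
    dplyr::group_by(.data$cluster) |>
    dplyr::arrange(.data$p_adj, dplyr::desc(abs(.data$lfc)), .by_group = TRUE) |>
    dplyr::slice_head(n = k) |>
    dplyr::ungroup()
}
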