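#' Hedges' g standardised mean difference
#'
#' `g = J * (mean(x) - mean(y)) / s_pooled` with the pooled standard
#' deviation `s_pooled = sqrt(((n_x-1) s_x^2 + (n_y-1) s_y^2) /
#' (n_x + n_y - 2))` and the small-sample bias correction
#' `J = 1 - 3 / (4 (n_x + n_y) - 9)`. With zero pooled variance, equal means
#' give 0 and unequal means give signed infinity (flagged via the
#' `degenerate` attribute).
#'
#' @param x,y numeric samples of length >= 2.
#' @return Scalar `g`.
#' @export
hedges_g <- function(x, y) {
  nx <- length(x); ny <- length(y)
  if (nx < 2 || ny < 2) {
    abort("both samples need at least 2 values", class = "nucbin_validation_error")
  }
  sp <- sqrt(((nx - 1) * var(x) + (ny - 1) * var(y)) / (nx + ny - 2))
  j <- 1 - 3 / (4 * (nx + ny) - 9)
  if (sp == 0) {
    d <- mean(x) - mean(y)
    g <- if (d == 0) 0 else sign(d) * Inf
    attr(g, "degenerate") <- d != 0
    return(g)
  }
  j * (mean(x) - mean(y)) / sp
}

#' Pairwise Hedges' g across clusters
#'
#' Computes `hedges_g` for every unordered cluster pair for one or more
#' per-observation metrics (counts and detected features by default),
#' summarising how strongly QC covariates differ between clusters.
#'
#' @param meta per-observation tibble (e.g. `nm$meta`).
#' @param labels cluster label per observation.
#' @param metrics metadata columns to compare.
#' @return Tibble `(metric, cluster_a, cluster_b, g, abs_g)`.
#' @export
cluster_effect_sizes <- function(meta, labels,
                                 metrics = c("total_counts", "n_features")) {
  labels <- as.factor(labels)
  lv <- levels(droplevels(labels))
  lv <- lv[table(labels)[lv] >= 2]
  pairs <- if (length(lv) >= 2) utils::combn(lv, 2) else
    matrix(character(), nrow = 2)
  purrr::map_dfr(metrics, function(m) {
    v <- meta[[m]]
    purrr::map_dfr(seq_len(ncol(pairs)), function(k) {
      a <- pairs[1, k]; b <- pairs[2, k]
      g <- as.numeric(hedges_g(v[labels == a], v[labels == b]))
      tibble(metric = m, cluster_a = a, cluster_b = b, g = g, abs_g = abs(g))
    })
  })
}
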