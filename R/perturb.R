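#' Perturb a ground-truth segmentation
#'
#' Produces an imperfect "predicted" segmentation from a truth label image by
#' dropping a fraction of nuclei, merging a fraction of adjacent pairs,
#' bisecting a fraction of nuclei, and morphologically jittering boundaries
#' (random dilation or erosion of up to `jitter_px` pixels per nucleus).
#' The truth correspondence of every output label is recorded so that
#' downstream precision/recall can be verified against construction.
#'
#' @param img a truth [label_image()].
#' @param drop_rate fraction of nuclei deleted (`round(rate * K)` of them).
#' @param merge_rate fraction of 4-adjacent nucleus pairs merged into one
#'   label.
#' @param split_rate fraction of nuclei bisected across their major axis.
#' @param jitter_px maximum boundary jitter in pixels (>= 0).
#' @param seed integer seed.
#' @return A [label_image()] with attribute `correspondence`, a tibble of
#'   `(pred_label, truth_label)` pairs.
#' @export
perturb_segmentation <- function(img, drop_rate = 0, merge_rate = 0,
                                 split_rate = 0, jitter_px = 0, seed = 1L) {
  stopifnot(inherits(img, "label_image"))
  rates <- c(drop_rate, merge_rate, split_rate)
  if (any(rates < 0) || any(rates > 1) || jitter_px < 0) {
    abort("rates must lie in [0,1] and jitter_px >= 0",
          class = "nucbin_validation_error")
  }
  lab <- img$labels
  nr <- nrow(lab); nc <- ncol(lab)
  truth_of <- setNames(as.list(sort(unique(as.vector(lab[lab > 0L])))),
                       sort(unique(as.vector(lab[lab > 0L]))))
  truth_of <- lapply(truth_of, identity)

  if (any(rates > 0) || jitter_px > 0) {
    set.seed(seed)

    labs <- as.integer(names(truth_of))
    n_drop <- round(drop_rate * length(labs))
    if (n_drop > 0) {
      dropped <- sample(labs, n_drop)
      lab[lab %in% dropped] <- 0L
      truth_of[as.character(dropped)] <- NULL
    }

    if (merge_rate > 0) {
      pairs <- adjacent_label_pairs(lab)
      n_merge <- round(merge_rate * nrow(pairs))
      if (n_merge > 0 && nrow(pairs) > 0) {
        ord <- sample.int(nrow(pairs))
        used <- integer(0); taken <- 0L
        for (k in ord) {
          a <- pairs$a[k]; b <- pairs$b[k]
          if (a %in% used || b %in% used) next
          lab[lab == b] <- a
          truth_of[[as.character(a)]] <- c(truth_of[[as.character(a)]],
                                           truth_of[[as.character(b)]])
          truth_of[as.character(b)] <- NULL
          used <- c(used, a, b)
          taken <- taken + 1L
          if (taken >= n_merge) break
        }
      }
    }

    if (split_rate > 0) {
      labs_now <- as.integer(names(truth_of))
      n_split <- round(split_rate * length(labs_now))
      if (n_split > 0) {
        to_split <- sample(labs_now, n_split)
        next_label <- max(lab) + 1L
        for (l in to_split) {
          idx <- which(lab == l)
          if (length(idx) < 2L) next
          r <- (idx - 1L) %% nr; c <- (idx - 1L) %/% nr
          dr <- r - mean(r); dc <- c - mean(c)
          cv <- cbind(dr, dc)
          ax <- eigen(crossprod(cv) / length(idx), symmetric = TRUE)$vectors[, 1]
          proj <- cv %*% ax
          half <- proj > stats::median(proj)
          if (!any(half) || all(half)) half <- seq_along(idx) > length(idx) / 2
          lab[idx[half]] <- next_label
          truth_of[[as.character(next_label)]] <- truth_of[[as.character(l)]]
          next_label <- next_label + 1L
        }
      }
    }

    if (jitter_px > 0) {
      for (l in as.integer(names(truth_of))) {
        d <- sample(seq(-jitter_px, jitter_px), 1)
        if (d > 0) {
          for (step in seq_len(d)) {
            idx <- which(lab == l)
            nb <- setdiff(neighbors4(idx, nr, nc), idx)
            nb <- nb[lab[nb] == 0L]
            if (!length(nb)) break
            lab[nb] <- l
          }
        } else if (d < 0) {
          for (step in seq_len(-d)) {
            idx <- which(lab == l)
            if (length(idx) <= 1L) break
            keep_core <- vapply(idx, function(p) {
              nb <- neighbors4(p, nr, nc)
              all(lab[nb] == l) && length(nb) == 4L
            }, logical(1))
            boundary <- idx[!keep_core]
            if (length(boundary) >= length(idx)) {
              boundary <- boundary[seq_len(max(0L, length(idx) - 1L))]
            }
            if (!length(boundary)) break
            lab[boundary] <- 0L
          }
        }
      }
    }
  }

  corr <- tibble(
    pred_label = rep(as.integer(names(truth_of)), lengths(truth_of)),
    truth_label = as.integer(unlist(truth_of, use.names = FALSE))
  )
  out <- label_image(lab, pixel_size_um = img$pixel_size_um, offset = img$offset)
  attr(out, "correspondence") <- corr
  out
}

neighbors4 <- function(idx, nr, nc) {
  r <- (idx - 1L) %% nr; c <- (idx - 1L) %/% nr
  cand <- c(
    ifelse(r > 0L, idx - 1L, NA_integer_),
    ifelse(r < nr - 1L, idx + 1L, NA_integer_),
    ifelse(c > 0L, idx - nr, NA_integer_),
    ifelse(c < nc - 1L, idx + nr, NA_integer_)
  )
  cand[!is.na(cand)]
}

# unordered pairs of distinct labels that touch (4-neighborhood)
adjacent_label_pairs <- function(lab) {
  nr <- nrow(lab); nc <- ncol(lab)
  h_a <- lab[, -nc]; h_b <- lab[, -1]
  v_a <- lab[-nr, ]; v_b <- lab[-1, ]
  a <- c(h_a, v_a); b <- c(h_b, v_b)
  keep <- a > 0L & b > 0L & a != b
  a <- a[keep]; b <- b[keep]
  lo <- pmin(a, b); hi <- pmax(a, b)
  u <- unique(cbind(lo, hi))
  tibble(a = as.integer(u[, 1]), b = as.integer(u[, 2]))
}

#' Generate a multi-patient cohort
#'
#' Batches share the cell-type expression profiles but receive multiplicative
#' per-gene batch factors drawn log-normally with standard deviation
#' `batch_effect`. Optionally, a per-batch degradation mask zeroes a subset
#' of one cell type's markers, emulating transcript degradation in archival
#' tissue (the same cell type then splits into batch-specific clusters
#' before integration).
#'
#' @param config a [sim_config()].
#' @param n_batches number of patients/batches (>= 2).
#' @param batch_effect sd of log-normal per-gene batch factors (0 = i.i.d.
#'   batches).
#' @param degrade optional list of lists with elements `batch`, and either
#'   `genes` (character) or `type` + `frac` (fraction of that type's markers
#'   masked).
#' @param seed integer seed.
#' @return List of `n_batches` elements, each `list(spots, truth)`.
#' @export
generate_cohort <- function(config, n_batches = 3L, batch_effect = 0.5,
                            degrade = NULL, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  if (n_batches < 2L) {
    abort("n_batches must be at least 2", class = "nucbin_validation_error")
  }
  set.seed(seed)
  panel <- build_gene_panel(config)
  non_mito <- setdiff(panel$gene_ids, panel$mito)
  factors <- matrix(
    if (batch_effect > 0) rlnorm(length(non_mito) * n_batches, 0, batch_effect)
    else 1,
    nrow = length(non_mito), ncol = n_batches
  )
  degraded <- vector("list", n_batches)
  for (d in degrade %||% list()) {
    genes <- if (!is.null(d$genes)) d$genes else {
      mk <- panel$markers[[d$type]]
      mk[seq_len(round(d$frac * length(mk)))]
    }
    degraded[[d$batch]] <- union(degraded[[d$batch]], genes)
  }
  lapply(seq_len(n_batches), function(b) {
    generate_tissue(config, seed = seed + b,
                    gene_factors = factors[, b],
                    zero_genes = degraded[[b]],
                    batch_id = b)
  })
}
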