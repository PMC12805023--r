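#' Match predicted to truth nuclei by intersection-over-union
#'
#' Builds the sparse IoU overlap table between truth and predicted
#' instances, keeps candidate pairs with IoU at or above the threshold, and
#' finds the one-to-one matching maximising total IoU (optimal assignment;
#' ties resolved in favour of lower truth labels).
#'
#' @param truth,pred [label_image()]s of identical shape.
#' @param iou_threshold minimum IoU for a valid pair, in (0, 1].
#' @return An `instance_matching`: list with `pairs` (tibble of `truth_id`,
#'   `pred_id`, `iou`), `unmatched_truth`, `unmatched_pred`, `iou_threshold`,
#'   `n_truth`, `n_pred`.
#' @export
match_instances <- function(truth, pred, iou_threshold = 0.5) {
  stopifnot(inherits(truth, "label_image"), inherits(pred, "label_image"))
  if (!identical(dim(truth$labels), dim(pred$labels))) {
    abort("truth and predicted label images differ in shape",
          class = "nucbin_validation_error")
  }
  if (iou_threshold <= 0 || iou_threshold > 1) {
    abort("iou_threshold must lie in (0, 1]", class = "nucbin_validation_error")
  }
  tv <- as.vector(truth$labels)
  pv <- as.vector(pred$labels)
  t_ids <- sort(unique(tv[tv > 0L]))
  p_ids <- sort(unique(pv[pv > 0L]))
  t_size <- table(factor(tv[tv > 0L], levels = t_ids))
  p_size <- table(factor(pv[pv > 0L], levels = p_ids))

  both <- tv > 0L & pv > 0L
  cand <- tibble(truth_id = integer(), pred_id = integer(), iou = numeric())
  if (any(both)) {
    ov <- as_tibble(as.data.frame(table(truth_id = tv[both], pred_id = pv[both]),
                                  stringsAsFactors = FALSE))
    ov <- ov[ov$Freq > 0, ]
    ov$truth_id <- as.integer(ov$truth_id)
    ov$pred_id <- as.integer(ov$pred_id)
    inter <- ov$Freq
    union_sz <- as.numeric(t_size[as.character(ov$truth_id)]) +
      as.numeric(p_size[as.character(ov$pred_id)]) - inter
    ov$iou <- inter / union_sz
    cand <- ov[ov$iou >= iou_threshold, c("truth_id", "pred_id", "iou")]
  }

  pairs <- tibble(truth_id = integer(), pred_id = integer(), iou = numeric())
  if (nrow(cand) > 0) {
    rt <- sort(unique(cand$truth_id))
    rp <- sort(unique(cand$pred_id))
    n <- max(length(rt), length(rp))
    w <- matrix(0, n, n)
    ri <- match(cand$truth_id, rt)
    ci <- match(cand$pred_id, rp)
    # tiny bonus for lower truth labels makes tie-breaking deterministic
    # without disturbing genuinely better assignments
    w[cbind(ri, ci)] <- cand$iou + 1e-9 * (length(rt) - ri) / length(rt)
    sel <- solve_assignment(max(w) - w)
    keep <- which(seq_len(n) <= length(rt) & sel <= length(rp))
    m <- tibble(truth_id = rt[seq_len(n)][keep], pred_id = rp[sel[keep]])
    m <- dplyr::inner_join(m, cand, by = c("truth_id", "pred_id"))
    pairs <- dplyr::arrange(m, .data$truth_id)
  }

  structure(list(
    pairs = pairs,
    unmatched_truth = setdiff(t_ids, pairs$truth_id),
    unmatched_pred = setdiff(p_ids, pairs$pred_id),
    iou_threshold = iou_threshold,
    n_truth = length(t_ids),
    n_pred = length(p_ids)
  ), class = "instance_matching")
}

# Hungarian algorithm (shortest augmenting path with potentials), minimising
# total cost of a square matrix; returns the column assigned to each row.
solve_assignment <- function(cost) {
  n <- nrow(cost)
  stopifnot(n == ncol(cost))
  INF <- .Machine$double.xmax / 4
  u <- numeric(n + 1); v <- numeric(n + 1)
  p <- integer(n + 1) # p[j+1] = row matched to column j (0 = free)
  way <- integer(n + 1)
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 0L
    minv <- rep(INF, n + 1)
    used <- rep(FALSE, n + 1)
    repeat {
      used[j0 + 1] <- TRUE
      i0 <- p[j0 + 1]
      delta <- INF
      j1 <- 0L
      for (j in seq_len(n)) {
        if (!used[j + 1]) {
          cur <- cost[i0, j] - u[i0 + 1] - v[j + 1]
          if (cur < minv[j + 1]) {
            minv[j + 1] <- cur
            way[j + 1] <- j0
          }
          if (minv[j + 1] < delta) {
            delta <- minv[j + 1]
            j1 <- j
          }
        }
      }
      for (j in 0:n) {
        if (used[j + 1]) {
          u[p[j + 1] + 1] <- u[p[j + 1] + 1] + delta
          v[j + 1] <- v[j + 1] - delta
        } else {
          minv[j + 1] <- minv[j + 1] - delta
        }
      }
      j0 <- j1
      if (p[j0 + 1] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1]
      p[j0 + 1] <- p[j1 + 1]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  ans <- integer(n)
  for (j in seq_len(n)) if (p[j + 1] > 0L) ans[p[j + 1]] <- j
  ans
}

#' Precision, recall and F1 from an instance matching
#'
#' True positives are matched pairs; `precision = TP / n_pred`,
#' `recall = TP / n_truth`. With no predictions, precision is reported as 0
#' and flagged rather than propagating `NaN`.
#'
#' @param m an `instance_matching` (or `NULL` to supply `tp` directly).
#' @param n_truth,n_pred instance counts (default: taken from `m`).
#' @param tp number of true-positive pairs (default: `nrow(m$pairs)`).
#' @return One-row tibble: `precision`, `recall`, `f1`, `tp`, `n_truth`,
#'   `n_pred`, `no_predictions`.
#' @export
precision_recall <- function(m = NULL, n_truth = m$n_truth, n_pred = m$n_pred,
                             tp = nrow(m$pairs)) {
  if (n_truth < 0 || n_pred < 0 || tp < 0) {
    abort("counts must be non-negative", class = "nucbin_validation_error")
  }
  if (tp > n_truth || tp > n_pred) {
    abort("true positives exceed instance counts",
          class = "nucbin_validation_error")
  }
  precision <- if (n_pred > 0) tp / n_pred else 0
  recall <- if (n_truth > 0) tp / n_truth else 0
  f1 <- if (precision > 0 && recall > 0) {
    2 * precision * recall / (precision + recall)
  } else 0
  tibble(precision = precision, recall = recall, f1 = f1,
         tp = as.integer(tp), n_truth = as.integer(n_truth),
         n_pred = as.integer(n_pred), no_predictions = n_pred == 0)
}

#' @export
print.instance_matching <- function(x, ...) {
  pr <- precision_recall(x)
  cat(sprintf(
    "<instance_matching> %d/%d truth and %d pred matched at IoU >= %.2f (P=%.3f R=%.3f)\n",
    nrow(x$pairs), x$n_truth, x$n_pred, x$iou_threshold, pr$precision, pr$recall))
  invisible(x)
}

#' @rdname nucbin-tidiers
#' @method tidy instance_matching
#' @export
tidy.instance_matching <- function(x, ...) x$pairs

#' @rdname nucbin-tidiers
#' @method glance instance_matching
#' @export
glance.instance_matching <- function(x, ...) precision_recall(x)

#' Per-region segmentation metrics
#'
#' Evaluates the segmentation independently inside each region of interest:
#' truth and predicted nuclei are assigned to the ROI containing their
#' centroid (overlapping ROIs trigger a warning and first-by-index
#' assignment), instances are matched within each ROI, and a pooled row
#' reports the across-ROI means.
#'
#' @param truth,pred [label_image()]s of identical shape.
#' @param roi_masks list of logical matrices (same shape as the images).
#' @param iou_threshold IoU threshold for matching.
#' @return Tibble with one row per ROI plus a `"pooled"` row of means.
#' @export
roi_report <- function(truth, pred, roi_masks, iou_threshold = 0.5) {
  stopifnot(inherits(truth, "label_image"), inherits(pred, "label_image"))
  if (length(roi_masks) > 1) {
    tot <- Reduce(`+`, lapply(roi_masks, function(m) m * 1L))
    if (any(tot > 1L)) {
      warn("overlapping ROIs; nuclei assigned to the first ROI by index")
    }
  }
  roi_of <- function(cent) {
    vapply(seq_len(nrow(cent)), function(i) {
      r <- round(cent$centroid_row[i]) + 1L
      c <- round(cent$centroid_col[i]) + 1L
      hit <- which(vapply(roi_masks, function(m) isTRUE(m[r, c]), logical(1)))
      if (length(hit)) hit[1] else NA_integer_
    }, integer(1))
  }
  ct <- label_centroids(truth$labels)
  cp <- label_centroids(pred$labels)
  ct$roi <- if (nrow(ct)) roi_of(ct) else integer()
  cp$roi <- if (nrow(cp)) roi_of(cp) else integer()

  rows <- purrr::map_dfr(seq_along(roi_masks), function(k) {
    tl <- ct$label[!is.na(ct$roi) & ct$roi == k]
    pl <- cp$label[!is.na(cp$roi) & cp$roi == k]
    t_sub <- truth$labels; t_sub[!(t_sub %in% tl)] <- 0L
    p_sub <- pred$labels; p_sub[!(p_sub %in% pl)] <- 0L
    m <- match_instances(label_image(t_sub, truth$pixel_size_um),
                         label_image(p_sub, pred$pixel_size_um),
                         iou_threshold)
    dplyr::mutate(precision_recall(m), roi = as.character(k), .before = 1)
  })
  pooled <- tibble(
    roi = "pooled",
    precision = mean(rows$precision), recall = mean(rows$recall),
    f1 = mean(rows$f1), tp = sum(rows$tp),
    n_truth = sum(rows$n_truth), n_pred = sum(rows$n_pred),
    no_predictions = all(rows$no_predictions)
  )
  dplyr::bind_rows(rows, pooled)
}
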