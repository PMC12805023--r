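# deterministic toy builders and one small cached simulation shared by tests

toy_spot_grid <- function(counts, nr = NULL, pitch = 2) {
  counts <- as.matrix(counts)
  n <- nrow(counts)
  if (is.null(nr)) nr <- n
  ids <- colnames(counts)
  if (is.null(ids)) ids <- paste0("g", seq_len(ncol(counts)))
  spot_grid(counts,
            spot_row = (seq_len(n) - 1L) %% nr,
            spot_col = (seq_len(n) - 1L) %/% nr,
            gene_ids = ids,
            pitch_um = pitch)
}

toy_labels <- function(mat, pitch = 2) label_image(mat, pixel_size_um = pitch)

# small tissue reused across tests (computed lazily, once)
.fixture_env <- new.env(parent = emptyenv())

small_sim <- function(ambient = 0.1, seed = 42L) {
  key <- paste0("sim_", ambient, "_", seed)
  if (is.null(.fixture_env[[key]])) {
    cfg <- sim_config(n_nuclei = 150L, canvas_px = c(112L, 112L),
                      n_glomeruli = 2L, ambient_fraction = ambient, seed = seed)
    .fixture_env[[key]] <- generate_tissue(cfg)
  }
  .fixture_env[[key]]
}

# random low-count label image pairs for oracle tests
random_label_pair <- function(seed, nr = 12, nc = 12, k_truth = 3, k_pred = 3) {
  set.seed(seed)
  mk <- function(k) {
    m <- matrix(0L, nr, nc)
    for (l in seq_len(k)) {
      r <- sample(nr - 3, 1); c <- sample(nc - 3, 1)
      m[r:(r + sample(2:3, 1)), c:(c + sample(2:3, 1))] <- l
    }
    m
  }
  list(truth = toy_labels(mk(k_truth)), pred = toy_labels(mk(k_pred)))
}

# exhaustive one-to-one matching oracle: maximise total IoU over all
# injective assignments of truth labels to predicted labels
brute_force_matching <- function(truth, pred, iou_threshold) {
  tv <- as.vector(truth$labels); pv <- as.vector(pred$labels)
  t_ids <- sort(unique(tv[tv > 0])); p_ids <- sort(unique(pv[pv > 0]))
  iou <- matrix(0, length(t_ids), length(p_ids),
                dimnames = list(t_ids, p_ids))
  for (i in seq_along(t_ids)) {
    for (j in seq_along(p_ids)) {
      a <- tv == t_ids[i]; b <- pv == p_ids[j]
      iou[i, j] <- sum(a & b) / sum(a | b)
    }
  }
  iou[iou < iou_threshold] <- 0
  nt <- length(t_ids); np <- length(p_ids)
  best <- 0; best_n <- 0L
  if (nt == 0 || np == 0) return(list(total = 0, n_pairs = 0L))
  # enumerate injective maps truth -> pred (with "unmatched" = 0)
  opts <- c(0L, seq_len(np))
  grid <- expand.grid(rep(list(opts), nt))
  for (r in seq_len(nrow(grid))) {
    sel <- as.integer(grid[r, ])
    nz <- sel[sel > 0]
    if (anyDuplicated(nz)) next
    tot <- sum(vapply(seq_len(nt), function(i) {
      if (sel[i] > 0) iou[i, sel[i]] else 0
    }, numeric(1)))
    npair <- sum(sel > 0 & vapply(seq_len(nt), function(i) {
      sel[i] > 0 && iou[i, sel[i]] > 0
    }, logical(1)))
    if (tot > best + 1e-12) {
      best <- tot; best_n <- npair
    }
  }
  list(total = best, n_pairs = best_n)
}
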