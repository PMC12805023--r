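test_that("matching a segmentation against itself is perfect at any threshold", {
  img <- small_sim()$truth$label_image
  for (thr in c(0.25, 0.5, 1)) {
    m <- match_instances(img, img, thr)
    pr <- precision_recall(m)
    expect_equal(pr$precision, 1)
    expect_equal(pr$recall, 1)
    expect_true(all(m$pairs$iou == 1))
  }
})

test_that("empty predictions give zero pairs and flagged precision", {
  img <- toy_labels(matrix(c(1L, 1L, 0L, 2L), 2, 2))
  m <- match_instances(img, toy_labels(matrix(0L, 2, 2)))
  expect_equal(nrow(m$pairs), 0L)
  expect_setequal(m$unmatched_truth, c(1L, 2L))
  pr <- precision_recall(m)
  expect_equal(pr$precision, 0)
  expect_true(pr$no_predictions)
})

test_that("optimal matching equals exhaustive enumeration on small instances", {
  for (seed in 1:8) {
    lp <- random_label_pair(seed)
    for (thr in c(0.2, 0.5)) {
      m <- match_instances(lp$truth, lp$pred, thr)
      oracle <- brute_force_matching(lp$truth, lp$pred, thr)
      expect_equal(sum(m$pairs$iou), oracle$total, tolerance = 1e-9,
                   label = sprintf("total IoU (seed %d, thr %.1f)", seed, thr))
      expect_equal(nrow(m$pairs), oracle$n_pairs,
                   label = sprintf("pair count (seed %d, thr %.1f)", seed, thr))
    }
  }
})

test_that("the assignment solver minimises cost against brute force", {
  for (seed in 1:10) {
    set.seed(seed)
    n <- sample(2:6, 1)
    cost <- matrix(runif(n * n), n, n)
    sel <- nucbin:::solve_assignment(cost)
    got <- sum(cost[cbind(seq_len(n), sel)])
    perms <- gtools_permutations <- function(v) {
      if (length(v) == 1) return(matrix(v))
      out <- NULL
      for (i in seq_along(v)) {
        rest <- Recall(v[-i])
        out <- rbind(out, cbind(v[i], rest))
      }
      out
    }
    all_p <- perms(seq_len(n))
    best <- min(apply(all_p, 1, function(p) sum(cost[cbind(seq_len(n), p)])))
    expect_equal(got, best, tolerance = 1e-12)
  }
})

test_that("raising the IoU threshold never increases matches", {
  img <- small_sim()$truth$label_image
  pred <- perturb_segmentation(img, drop_rate = 0.1, split_rate = 0.1,
                               jitter_px = 1, seed = 2)
  tps <- vapply(c(0.2, 0.35, 0.5, 0.65, 0.8),
                function(t) nrow(match_instances(img, pred, t)$pairs),
                numeric(1))
  expect_true(all(diff(tps) <= 0))
})

test_that("precision and recall arithmetic is exact", {
  pr <- precision_recall(n_truth = 2, n_pred = 1, tp = 1)
  expect_equal(pr$precision, 1)
  expect_equal(pr$recall, 0.5)
  expect_equal(pr$f1, 2 / 3)
  expect_error(precision_recall(n_truth = -1, n_pred = 0, tp = 0),
               class = "nucbin_validation_error")
})

test_that("per-ROI reports match independent per-region recomputation", {
  sim <- small_sim()
  truth_img <- sim$truth$label_image
  pred <- perturb_segmentation(truth_img, drop_rate = 0.2, jitter_px = 1,
                               seed = 5)
  nr <- nrow(truth_img$labels); nc <- ncol(truth_img$labels)

  whole <- matrix(TRUE, nr, nc)
  rep1 <- roi_report(truth_img, pred, list(whole))
  glob <- precision_recall(match_instances(truth_img, pred, 0.5))
  expect_equal(rep1$precision[1], glob$precision)
  expect_equal(rep1$recall[1], glob$recall)

  left <- matrix(FALSE, nr, nc); left[, seq_len(nc %/% 2)] <- TRUE
  right <- !left
  rep2 <- roi_report(truth_img, pred, list(left, right))
  expect_equal(nrow(rep2), 3L)
  expect_equal(rep2$recall[rep2$roi == "pooled"],
               mean(rep2$recall[rep2$roi != "pooled"]))

  # independent recomputation of ROI 1 by masking labels outside it
  ct <- nucbin:::label_centroids(truth_img$labels)
  cp <- nucbin:::label_centroids(pred$labels)
  in_left <- function(cent) {
    left[cbind(round(cent$centroid_row) + 1, round(cent$centroid_col) + 1)]
  }
  t_sub <- truth_img$labels
  t_sub[!(t_sub %in% ct$label[in_left(ct)])] <- 0L
  p_sub <- pred$labels
  p_sub[!(p_sub %in% cp$label[in_left(cp)])] <- 0L
  oracle <- precision_recall(match_instances(toy_labels(t_sub),
                                             toy_labels(p_sub), 0.5))
  expect_equal(rep2$precision[1], oracle$precision)
  expect_equal(rep2$recall[1], oracle$recall)
})

test_that("a mean > 90% precision/recall regime is reproduced under mild errors", {
  sim <- small_sim()
  pred <- perturb_segmentation(sim$truth$label_image, drop_rate = 0.05,
                               seed = 7)
  pr <- precision_recall(match_instances(sim$truth$label_image, pred, 0.5))
  expect_gt(pr$precision, 0.9)
  expect_gte(pr$recall, 0.9)

  # +/- 1 px boundary jitter is severe for ~5-pixel nuclei: at IoU 0.5 many
  # matches dissolve, but a looser overlap criterion recovers them
  jit <- perturb_segmentation(sim$truth$label_image, jitter_px = 1, seed = 7)
  strict <- precision_recall(match_instances(sim$truth$label_image, jit, 0.5))
  loose <- precision_recall(match_instances(sim$truth$label_image, jit, 0.2))
  expect_gt(loose$recall, strict$recall)
  expect_gt(loose$recall, 0.85)
})
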