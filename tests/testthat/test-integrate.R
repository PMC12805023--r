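random_norm <- function(n, g, seed, shift = 0) {
  set.seed(seed)
  x <- matrix(rpois(n * g, 3) + 1, n, g,
              dimnames = list(paste0("c", seq_len(n), "_", seed),
                              paste0("g", seq_len(g))))
  normalize_log(x + shift)
}

test_that("canonical correlations behave at the identity and independence limits", {
  x <- random_norm(60, 40, 1)
  cc_same <- cca_project(x, x, 10)
  expect_gt(cc_same$correlations[1], 0.999)
  expect_true(all(diff(cc_same$correlations) <= 1e-8))

  xl <- random_norm(200, 100, 1)
  yl <- random_norm(200, 100, 2)
  cc_ind <- cca_project(xl, yl, 10)
  # unrelated datasets correlate far below the identity case
  expect_lt(cc_ind$correlations[1], 0.97)
  expect_lt(cc_ind$correlations[1], cc_same$correlations[1] - 0.05)
  expect_true(all(diff(cc_ind$correlations) <= 1e-8))

  # embeddings are L2-normalised per observation
  expect_equal(rowSums(cc_same$u^2), rep(1, 60), tolerance = 1e-8)
  expect_error(cca_project(x, matrix(1, 5, 3,
                                     dimnames = list(NULL, c("zz1", "zz2", "zz3")))),
               class = "nucbin_validation_error")
})

test_that("identical embeddings anchor every observation to its copy", {
  set.seed(3)
  u <- matrix(rnorm(40 * 5), 40, 5)
  anc <- find_anchors(u, u, k_anchor = 3)
  self <- anc[anc$i == anc$j, ]
  expect_equal(nrow(self), 40L)
  expect_true(all(self$score == 1))
  expect_error(find_anchors(u, u, k_anchor = 40),
               class = "nucbin_validation_error")
})

test_that("anchors equal brute-force mutual-nearest-neighbour enumeration", {
  set.seed(4)
  u1 <- matrix(rnorm(30 * 4), 30, 4)
  u2 <- matrix(rnorm(30 * 4), 30, 4)
  k <- 4
  anc <- find_anchors(u1, u2, k)
  d <- as.matrix(dist(rbind(u1, u2)))[1:30, 31:60]
  oracle <- NULL
  for (i in 1:30) {
    for (j in 1:30) {
      if (rank(d[i, ], ties.method = "first")[j] <= k &&
          rank(d[, j], ties.method = "first")[i] <= k) {
        oracle <- rbind(oracle, c(i, j))
      }
    }
  }
  expect_equal(nrow(anc), nrow(oracle))
  expect_setequal(paste(anc$i, anc$j), paste(oracle[, 1], oracle[, 2]))
})

test_that("anchor sets are symmetric under swapping the datasets", {
  set.seed(5)
  u1 <- matrix(rnorm(25 * 4), 25, 4)
  u2 <- matrix(rnorm(20 * 4), 20, 4)
  a12 <- find_anchors(u1, u2, 3)
  a21 <- find_anchors(u2, u1, 3)
  expect_setequal(paste(a12$i, a12$j), paste(a21$j, a21$i))
})

test_that("types absent from one batch contribute no anchors", {
  set.seed(6)
  shared1 <- matrix(rnorm(60, 0, 0.3), 20, 3)
  only1 <- matrix(rnorm(60, 15, 0.3), 20, 3)
  shared2 <- matrix(rnorm(60, 0, 0.3), 20, 3)
  only2 <- matrix(rnorm(60, -15, 0.3), 20, 3)
  anc <- find_anchors(rbind(shared1, only1), rbind(shared2, only2), 3)
  # anchors only among the shared cluster (indices 1..20 on both sides)
  expect_true(all(anc$i <= 20))
  expect_true(all(anc$j <= 20))
  expect_gt(nrow(anc), 0)
})

test_that("integrating a dataset with its copy is a near-no-op", {
  x <- random_norm(60, 40, 7)
  int <- integrate_datasets(list(a = x, b = x), n_cc = 10)
  xa <- as.matrix(x[, colnames(int$corrected)])
  delta <- norm(int$corrected[int$dataset == "b", ] - xa, "F") / norm(xa, "F")
  expect_lt(delta, 1e-6)
})

test_that("integration improves batch mixing and preserves cell types", {
  cfg <- sim_config(n_nuclei = 250L, canvas_px = c(144L, 144L),
                    n_glomeruli = 2L)
  coh <- generate_cohort(cfg, n_batches = 2, batch_effect = 0.5, seed = 8)
  qcs <- lapply(coh, function(b) {
    apply_qc(bin_by_nuclei(b$spots, b$truth$label_image), run_config())$filtered
  })
  norms <- lapply(qcs, normalize_log)
  names(norms) <- c("p1", "p2")
  batch <- rep(names(norms), vapply(norms, nrow, numeric(1)))
  truth_types <- unlist(lapply(seq_along(coh), function(i) {
    coh[[i]]$truth$nuclei$cell_type[qcs[[i]]$meta$label]
  }))
  shared <- intersect(colnames(norms$p1), colnames(norms$p2))
  pre <- rbind(as.matrix(norms$p1[, shared]), as.matrix(norms$p2[, shared]))

  int <- integrate_datasets(norms, n_cc = 20)
  emb_pre <- nucbin:::pca_embed(pre, 30)
  emb_post <- nucbin:::pca_embed(int$corrected, 30)
  ent_pre <- knn_mixing_entropy(emb_pre, batch, 15)
  ent_post <- knn_mixing_entropy(emb_post, batch, 15)
  expect_gt(ent_post, ent_pre)

  ari_pre <- adjusted_rand_index(cluster_graph(pre, seed = 1)$labels,
                                 truth_types)
  ari_post <- adjusted_rand_index(cluster_graph(int$corrected, seed = 1)$labels,
                                  truth_types)
  expect_gte(ari_post, ari_pre)
})

test_that("a no-batch-effect cohort needs almost no correction", {
  cfg <- sim_config(n_nuclei = 150L, canvas_px = c(112L, 112L),
                    n_glomeruli = 1L)
  coh <- generate_cohort(cfg, n_batches = 2, batch_effect = 0, seed = 9)
  norms <- lapply(coh, function(b) {
    normalize_log(apply_qc(bin_by_nuclei(b$spots, b$truth$label_image),
                           run_config())$filtered)
  })
  names(norms) <- c("p1", "p2")
  int <- integrate_datasets(norms, n_cc = 15)
  q <- setdiff(names(norms), int$reference)
  raw <- as.matrix(norms[[q]][, colnames(int$corrected)])
  delta <- norm(int$corrected[int$dataset == q, ] - raw, "F") / norm(raw, "F")
  # anchor averaging shrinks cells toward local reference means, so the
  # correction is modest but not zero; recovery of the true cell types must
  # not be hurt by correcting an already-homogeneous cohort
  expect_lt(delta, 0.4)
  qi <- match(q, names(norms))
  types_q <- coh[[qi]]$truth$nuclei$cell_type[
    apply_qc(bin_by_nuclei(coh[[qi]]$spots, coh[[qi]]$truth$label_image),
             run_config())$filtered$meta$label]
  ari_raw <- adjusted_rand_index(cluster_graph(raw, seed = 1)$labels, types_q)
  ari_cor <- adjusted_rand_index(
    cluster_graph(int$corrected[int$dataset == q, ], seed = 1)$labels, types_q)
  expect_gte(ari_cor, ari_raw - 0.15)
})

test_that("marker degradation splits one type into batch-specific clusters", {
  cfg <- sim_config(n_nuclei = 250L, canvas_px = c(144L, 144L),
                    n_glomeruli = 2L)
  coh <- generate_cohort(cfg, n_batches = 2, batch_effect = 0,
                         degrade = list(list(batch = 1,
                                             type = "proximal_tubule",
                                             frac = 0.7)),
                         seed = 10)
  qcs <- lapply(coh, function(b) {
    apply_qc(bin_by_nuclei(b$spots, b$truth$label_image), run_config())$filtered
  })
  norms <- lapply(qcs, normalize_log)
  shared <- intersect(colnames(norms[[1]]), colnames(norms[[2]]))
  pre <- rbind(as.matrix(norms[[1]][, shared]), as.matrix(norms[[2]][, shared]))
  batch <- rep(1:2, vapply(norms, nrow, numeric(1)))
  types <- unlist(lapply(seq_along(coh), function(i) {
    coh[[i]]$truth$nuclei$cell_type[qcs[[i]]$meta$label]
  }))
  cl <- cluster_graph(pre, seed = 1, resolution = 1.5)$labels
  pt <- types == "proximal_tubule"
  # the degraded type's nuclei separate by batch before integration:
  # the dominant cluster of batch-1 proximal tubule differs from batch 2's
  top1 <- names(which.max(table(cl[pt & batch == 1])))
  top2 <- names(which.max(table(cl[pt & batch == 2])))
  expect_false(identical(top1, top2))
})
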