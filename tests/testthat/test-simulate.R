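test_that("transcript counts are conserved between truth and spot grid", {
  sim <- small_sim(ambient = 0.15)
  expect_equal(sum(sim$spots$counts), sum(sim$truth$nuclei$library_size))
})

test_that("with no ambient spill every transcript stays in its nucleus", {
  sim <- small_sim(ambient = 0)
  nm <- bin_by_nuclei(sim$spots, sim$truth$label_image)
  expect_equal(attr(nm, "unassigned_counts"), 0)
  lib <- sim$truth$nuclei$library_size[nm$meta$label]
  expect_equal(nm$meta$total_counts, as.numeric(lib))
})

test_that("simulation is reproducible from the seed and varies across seeds", {
  cfg <- sim_config(n_nuclei = 60L, canvas_px = c(80L, 80L), n_glomeruli = 1L)
  a <- generate_tissue(cfg, seed = 1)
  b <- generate_tissue(cfg, seed = 1)
  c <- generate_tissue(cfg, seed = 2)
  expect_identical(as.matrix(a$spots$counts), as.matrix(b$spots$counts))
  expect_identical(a$truth$label_image$labels, b$truth$label_image$labels)
  expect_false(identical(as.matrix(a$spots$counts), as.matrix(c$spots$counts)))
})

test_that("nuclear geometry tracks the configured area law", {
  sim <- small_sim()
  tr <- sim$truth$nuclei
  # expected spots per nucleus = mean area / pitch^2 = 5
  expect_gt(mean(tr$n_px), 4)
  expect_lt(mean(tr$n_px), 6)
  expect_true(all(tr$area_um2 > 0))
  # glomerular types stay inside glomerulus disks
  glom <- sim$truth$glomeruli
  gl <- tr[tr$in_glomerulus, ]
  d2 <- outer(gl$centroid_row, glom$row, "-")^2 +
    outer(gl$centroid_col, glom$col, "-")^2
  expect_true(all(sqrt(apply(d2, 1, min)) <= glom$radius_px[1] + 1))
})

test_that("ambient transcripts land in the dilation ring", {
  sim <- small_sim(ambient = 0.3)
  nm <- bin_by_nuclei(sim$spots, sim$truth$label_image)
  f <- attr(nm, "unassigned_fraction")
  # some spill is recaptured by neighbouring nuclei, so the unassigned
  # fraction is positive but at most the ambient fraction
  expect_gt(f, 0.1)
  expect_lt(f, 0.3)
})

test_that("segmentation perturbation honours its contract", {
  sim <- small_sim()
  truth_img <- sim$truth$label_image

  same <- perturb_segmentation(truth_img)
  expect_identical(same$labels, truth_img$labels)

  k <- label_summary(truth_img)$n_labels
  dropped <- perturb_segmentation(truth_img, drop_rate = 0.5, seed = 3)
  expect_equal(label_summary(dropped)$n_labels, k - round(0.5 * k))
  corr <- attr(dropped, "correspondence")
  expect_true(all(corr$pred_label == corr$truth_label))

  merged <- perturb_segmentation(truth_img, merge_rate = 0.2, seed = 3)
  corr_m <- attr(merged, "correspondence")
  expect_gt(sum(duplicated(corr_m$pred_label)), 0)
  expect_lt(label_summary(merged)$n_labels, k)

  split <- perturb_segmentation(truth_img, split_rate = 0.3, seed = 3)
  expect_gt(label_summary(split)$n_labels, k)

  jit <- perturb_segmentation(truth_img, jitter_px = 1, seed = 3)
  expect_equal(label_summary(jit)$n_labels, k)
  # jitter only moves boundaries; every nucleus keeps at least one pixel
  expect_true(all(table(jit$labels[jit$labels > 0]) >= 1))
})

test_that("dropping 20% of nuclei yields precision 1 and recall 0.8", {
  sim <- small_sim()
  truth_img <- sim$truth$label_image
  pred <- perturb_segmentation(truth_img, drop_rate = 0.2, seed = 9)
  m <- match_instances(truth_img, pred, iou_threshold = 0.5)
  pr <- precision_recall(m)
  k <- label_summary(truth_img)$n_labels
  expect_equal(pr$precision, 1)
  expect_equal(pr$recall, (k - round(0.2 * k)) / k)
})

test_that("cohorts share the model but differ by batch factors", {
  cfg <- sim_config(n_nuclei = 60L, canvas_px = c(80L, 80L), n_glomeruli = 1L)
  expect_error(generate_cohort(cfg, n_batches = 1),
               class = "nucbin_validation_error")
  coh <- generate_cohort(cfg, n_batches = 2, batch_effect = 0, seed = 4)
  expect_length(coh, 2)
  expect_equal(coh[[1]]$truth$batch_id, 1L)
  expect_equal(colnames(coh[[1]]$spots$counts), colnames(coh[[2]]$spots$counts))

  deg <- generate_cohort(cfg, n_batches = 2, batch_effect = 0,
                         degrade = list(list(batch = 1,
                                             type = "proximal_tubule",
                                             frac = 0.3)),
                         seed = 4)
  masked <- head(deg[[1]]$truth$markers$proximal_tubule, 3)
  expect_equal(sum(deg[[1]]$spots$counts[, masked]), 0)
  expect_gt(sum(deg[[2]]$spots$counts[, masked]), 0)
})
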