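fake_annotated <- function(calls, cluster_per_obs, scores = NULL) {
  n <- length(cluster_per_obs)
  if (is.null(scores)) {
    scores <- matrix(0.5, n, 1, dimnames = list(NULL, "podocyte"))
  }
  structure(list(
    nm = list(counts = matrix(0, n, 1)),
    clusters = list(labels = factor(cluster_per_obs)),
    scores = scores,
    assignment = list(calls = calls)
  ), class = "annotated_dataset")
}

test_that("cell-type overlap follows set algebra", {
  o <- celltype_overlap(c("A", "B", "C"), c("B", "C", "D"))
  expect_equal(o$n_shared, 2L)
  expect_equal(o$n_unique_a, 1L)
  expect_equal(o$n_unique_b, 1L)
  expect_equal(o$shared[[1]], c("B", "C"))

  same <- celltype_overlap(c("A", "B"), c("B", "A"))
  expect_equal(same$n_unique_a + same$n_unique_b, 0L)

  empty <- celltype_overlap(c("A", "B", "unknown"), "unknown")
  expect_equal(empty$n_shared, 0L)
  expect_equal(empty$n_unique_a, 2L)
})

test_that("unknown fractions count observations in unknown clusters", {
  calls <- tibble::tibble(cluster = c("1", "2"), call = c("podocyte", "unknown"))
  ad <- fake_annotated(calls, c("1", "1", "1", "2"))
  expect_equal(unknown_fraction(ad), 0.25)
  calls2 <- tibble::tibble(cluster = "1", call = "unknown")
  expect_equal(unknown_fraction(fake_annotated(calls2, rep("1", 5))), 1)
  calls3 <- tibble::tibble(cluster = "1", call = "podocyte")
  expect_equal(unknown_fraction(fake_annotated(calls3, rep("1", 5))), 0)
})

test_that("the focal score test matches exact Wilcoxon behaviour", {
  calls <- tibble::tibble(cluster = "1", call = "podocyte")
  mk <- function(v) fake_annotated(calls, rep("1", length(v)),
                                   matrix(v, dimnames = list(NULL, "podocyte")))
  same <- focal_signature_test(mk(c(1, 2, 3) / 10), mk(c(1, 2, 3) / 10))
  expect_equal(same$p_value, 1)

  far <- focal_signature_test(mk(c(1, 2, 3) / 1000), mk(c(101, 102, 103) / 1000))
  expect_equal(far$p_value, 0.1)
  expect_equal(far$ratio_b_over_a, 1)

  unk <- tibble::tibble(cluster = "1", call = "unknown")
  miss <- focal_signature_test(fake_annotated(unk, rep("1", 3)),
                               mk(c(1, 2, 3)))
  expect_true(miss$focal_absent)
  expect_true(is.na(miss$p_value))
})

test_that("swapping the two strategies swaps the report symmetrically", {
  calls <- tibble::tibble(cluster = "1", call = "podocyte")
  mk <- function(v) fake_annotated(calls, rep("1", length(v)),
                                   matrix(v, dimnames = list(NULL, "podocyte")))
  a <- mk(c(0.9, 0.8, 0.7, 0.6))
  b <- mk(c(0.5, 0.4, 0.3))
  ab <- focal_signature_test(a, b)
  ba <- focal_signature_test(b, a)
  expect_equal(ab$median_a, ba$median_b)
  expect_equal(ab$median_b, ba$median_a)
  expect_equal(ab$n_a, ba$n_b)
  expect_equal(ab$p_value, ba$p_value)
  expect_equal(ab$ratio_b_over_a, 1 / ba$ratio_b_over_a)
})

test_that("both branches run with provably identical parameters", {
  sim <- small_sim()
  cfg <- run_config(n_neighbors = 10, seed = 11)
  cmp <- run_both(sim$spots, sim$truth$label_image,
                  signatures = sim_signatures(sim$truth), config = cfg)
  m_n <- cmp$nuclei$manifest
  m_s <- cmp$square$manifest
  expect_identical(m_n$parameters, m_s$parameters)
  expect_false(identical(m_n$binning, m_s$binning))
  expect_equal(m_s$binning$strategy, "square")
  expect_equal(m_s$binning$bin_size_um, 8)

  r <- comparison_report(cmp, focal = "podocyte")
  expect_true(all(r$unknown$unknown_fraction >= 0 &
                    r$unknown$unknown_fraction <= 1))
  expect_equal(r$celltypes$n_shared +
                 r$celltypes$n_unique_a, r$counts$n_called_types[1])

  cmp2 <- run_both(sim$spots, sim$truth$label_image,
                   signatures = sim_signatures(sim$truth), config = cfg)
  expect_identical(cmp$nuclei$clusters$labels, cmp2$nuclei$clusters$labels)
  expect_identical(comparison_report(cmp)$focal, comparison_report(cmp2)$focal)
})

test_that("tidiers expose per-observation calls and one-row summaries", {
  sim <- small_sim()
  cmp <- run_both(sim$spots, sim$truth$label_image,
                  signatures = sim_signatures(sim$truth),
                  config = run_config(n_neighbors = 10))
  td <- tidy(cmp$nuclei)
  expect_true(all(c("cluster", "call", "podocyte") %in% names(td)))
  expect_equal(nrow(td), nrow(cmp$nuclei$nm$counts))
  g <- glance(comparison_report(cmp))
  expect_true(is.finite(g$unknown_square))
})
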