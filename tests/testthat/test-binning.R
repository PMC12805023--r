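test_that("nucleus binning sums spot vectors by label", {
  counts <- cbind(g1 = c(3, 2, 0, 4), g2 = c(0, 1, 0, 0))
  sg <- toy_spot_grid(counts, nr = 2)
  lab <- toy_labels(matrix(1L, 2, 2))
  nm <- bin_by_nuclei(sg, lab)
  expect_equal(nrow(nm$counts), 1L)
  expect_equal(as.numeric(nm$counts[1, "g1"]), 9)
  expect_equal(nm$meta$n_spots, 4L)
  expect_equal(nm$meta$area_um2, 4 * 2^2)
  expect_equal(attr(nm, "unassigned_counts"), 0)
})

test_that("all-background labels yield an empty matrix with everything unassigned", {
  sg <- toy_spot_grid(cbind(g1 = c(1, 2, 3, 4)), nr = 2)
  nm <- bin_by_nuclei(sg, toy_labels(matrix(0L, 2, 2)))
  expect_equal(nrow(nm$counts), 0L)
  expect_equal(attr(nm, "unassigned_fraction"), 1)
})

test_that("assigned plus unassigned counts partition the total exactly", {
  sim <- small_sim(ambient = 0.2)
  nm <- bin_by_nuclei(sim$spots, sim$truth$label_image)
  expect_equal(sum(nm$counts) + attr(nm, "unassigned_counts"),
               sum(sim$spots$counts))
})

test_that("registration offset maps cropped spot grids onto the label image", {
  counts <- cbind(g1 = c(5, 7))
  sg <- spot_grid(counts, spot_row = c(0L, 1L), spot_col = c(0L, 0L),
                  gene_ids = "g1", pitch_um = 2)
  big <- matrix(0L, 4, 4); big[2:3, 2] <- 1L
  lab <- label_image(big, pixel_size_um = 2, offset = c(1L, 1L))
  nm <- bin_by_nuclei(sg, lab)
  expect_equal(as.numeric(nm$meta$total_counts), 12)

  bad <- label_image(matrix(1L, 1, 1))
  expect_error(bin_by_nuclei(sg, bad), class = "nucbin_registration_error")
})

test_that("square binning partitions the grid and conserves counts", {
  set.seed(1)
  counts <- matrix(rpois(16 * 3, 2), 16, 3,
                   dimnames = list(NULL, c("a", "b", "MT-1")))
  sg <- toy_spot_grid(counts, nr = 4)
  sq <- bin_by_square(sg, 8)
  expect_equal(nrow(sq$counts), 1L)
  expect_equal(sq$meta$n_spots, 16L)
  expect_equal(sum(sq$counts), sum(counts))

  # 6x6 grid with 8 um bins: ragged edge bins of 16/8/8/4 spots
  counts6 <- matrix(1, 36, 1, dimnames = list(NULL, "g"))
  sq6 <- bin_by_square(toy_spot_grid(counts6, nr = 6), 8)
  expect_equal(nrow(sq6$counts), 4L)
  expect_setequal(sq6$meta$n_spots, c(16L, 8L, 8L, 4L))
  expect_equal(sum(sq6$meta$edge_bin), 3L)
  expect_equal(sum(sq6$counts), 36)

  expect_error(bin_by_square(sg, 7), class = "nucbin_validation_error")
})

test_that("square binning conserves totals on simulated tissue", {
  sim <- small_sim()
  sq <- bin_by_square(sim$spots, 8)
  expect_equal(sum(sq$counts), sum(sim$spots$counts))
  expect_equal(sum(sq$meta$n_spots), nrow(sim$spots$counts))
})

test_that("area statistics summarise nucleus geometry", {
  sim <- small_sim()
  nm <- bin_by_nuclei(sim$spots, sim$truth$label_image)
  s <- area_stats(nm)
  expect_equal(s$summary$n_nuclei, nrow(nm$meta))
  expect_equal(s$summary$mean_spots, mean(nm$meta$n_spots))
  expect_equal(sum(s$area_histogram$n), nrow(nm$meta))

  one <- nm
  one$counts <- one$counts[1, , drop = FALSE]
  one$meta <- one$meta[1, ]
  one$meta$n_spots <- 5L
  expect_equal(area_stats(one)$summary$mean_spots, 5)

  two <- nm
  two$meta <- two$meta[1:2, ]
  two$meta$area_um2 <- c(16, 24)
  two$counts <- two$counts[1:2, ]
  expect_equal(area_stats(two)$summary$mean_area_um2, 20)
})

test_that("counts-area regression matches closed-form least squares", {
  nm <- bin_by_nuclei(small_sim()$spots, small_sim()$truth$label_image)
  d <- nm
  d$meta <- d$meta[1:5, ]
  d$meta$area_um2 <- c(10, 15, 20, 25, 30)
  d$meta$total_counts <- c(8, 14, 19, 24, 33)
  fit <- counts_area_regression(d)
  # hand-computed OLS: Sxx = 250, Sxy = 300, SST = 365.2, SSR = 360
  expect_equal(fit$slope, 1.2, tolerance = 1e-12)
  expect_equal(fit$intercept, -4.4, tolerance = 1e-12)
  expect_equal(fit$r_squared, 360 / 365.2, tolerance = 1e-12)
  t_stat <- 1.2 / sqrt((5.2 / 3) / 250)
  expect_equal(fit$p_value, 2 * pt(-abs(t_stat), 3), tolerance = 1e-12)

  # perfectly linear counts give R^2 = 1 (lm warns about the perfect fit)
  d$meta$total_counts <- 2 * d$meta$area_um2 + 1
  expect_equal(suppressWarnings(counts_area_regression(d)$r_squared), 1)

  # constant counts give slope 0 and R^2 = 0
  d$meta$total_counts <- rep(7, 5)
  flat <- counts_area_regression(d)
  expect_equal(flat$slope, 0)
  expect_equal(flat$r_squared, 0)

  d$meta$area_um2 <- rep(20, 5)
  d$meta$total_counts <- c(8, 14, 19, 24, 33)
  expect_error(counts_area_regression(d), class = "nucbin_degenerate_error")
})
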