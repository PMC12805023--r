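# shared constructor for nucleus_matrix / square_bin_matrix
new_bin_matrix <- function(counts, meta, genes, pitch_um, kind, bin_size_um = NULL,
                           extra = list()) {
  out <- c(list(counts = counts, meta = meta, genes = genes,
                pitch_um = pitch_um, bin_size_um = bin_size_um), extra)
  structure(out, class = c(kind, "bin_matrix"))
}

bin_meta_stats <- function(counts, mito_flags) {
  total <- rowSums(counts)
  tibble(
    total_counts = as.numeric(total),
    n_features = as.integer(rowSums(counts > 0)),
    pct_mito = ifelse(total > 0,
                      100 * as.numeric(rowSums(counts[, mito_flags, drop = FALSE])) / total,
                      0)
  )
}

#' Aggregate spots into per-nucleus expression profiles
#'
#' The core reconstruction step: each 4 um^2 capture spot is assigned to the
#' nucleus whose label covers the spot's center pixel, and the spot count
#' vectors of a nucleus are summed into one profile. Spots on background
#' (label 0) are excluded and reported; nuclei whose footprint overlaps no
#' spot are omitted and reported.
#'
#' @param spots a [spot_grid()].
#' @param labels a [label_image()] registered to the spot grid (one pixel per
#'   spot, plus the integer offset stored in the image).
#' @return A `nucleus_matrix`: sparse nucleus-by-gene counts plus per-nucleus
#'   metadata (`label`, `area_um2`, `n_spots`, `total_counts`, `n_features`,
#'   `pct_mito`, centroid). Attributes `unassigned_counts`,
#'   `unassigned_fraction` and `omitted_labels` report the complement.
#' @export
bin_by_nuclei <- function(spots, labels) {
  stopifnot(inherits(spots, "spot_grid"), inherits(labels, "label_image"))
  nr <- nrow(labels$labels); nc <- ncol(labels$labels)
  pr <- spots$spots$spot_row + labels$offset[1]
  pc <- spots$spots$spot_col + labels$offset[2]
  if (any(pr < 0L) || any(pr >= nr) || any(pc < 0L) || any(pc >= nc)) {
    abort("spot grid does not fit inside the label image after offset",
          class = "nucbin_registration_error")
  }
  lab <- labels$labels[cbind(pr + 1L, pc + 1L)]
  assigned <- lab > 0L

  total_counts_all <- sum(spots$counts)
  unassigned_counts <- sum(spots$counts[!assigned, , drop = FALSE])

  cent <- label_centroids(labels$labels)
  present <- sort(unique(lab[assigned]))
  omitted <- setdiff(cent$label, present)

  if (!any(assigned)) {
    counts <- methods::as(methods::as(
      Matrix::Matrix(0, nrow = 0, ncol = ncol(spots$counts), sparse = TRUE),
      "CsparseMatrix"), "generalMatrix")
    colnames(counts) <- spots$genes$gene_id
    meta <- tibble(nucleus_id = character(), label = integer(),
                   area_um2 = numeric(), n_spots = integer(),
                   total_counts = numeric(), n_features = integer(),
                   pct_mito = numeric(), centroid_row = numeric(),
                   centroid_col = numeric())
  } else {
    grp <- factor(lab[assigned], levels = present)
    ind <- Matrix::fac2sparse(grp)
    counts <- methods::as(methods::as(ind %*% spots$counts[assigned, , drop = FALSE],
                                      "CsparseMatrix"), "generalMatrix")
    colnames(counts) <- spots$genes$gene_id
    cent_k <- cent[match(present, cent$label), ]
    stats <- bin_meta_stats(counts, spots$genes$mito)
    meta <- tibble(
      nucleus_id = paste0("nuc", present),
      label = as.integer(present),
      area_um2 = cent_k$n_px * labels$pixel_size_um^2,
      n_spots = as.integer(tabulate(grp)),
      total_counts = stats$total_counts,
      n_features = stats$n_features,
      pct_mito = stats$pct_mito,
      centroid_row = cent_k$centroid_row,
      centroid_col = cent_k$centroid_col
    )
    rownames(counts) <- meta$nucleus_id
  }
  out <- new_bin_matrix(counts, meta, spots$genes, pitch_um = spots$pitch_um,
                        kind = "nucleus_matrix")
  attr(out, "unassigned_counts") <- unassigned_counts
  attr(out, "unassigned_fraction") <-
    if (total_counts_all > 0) unassigned_counts / total_counts_all else 0
  attr(out, "omitted_labels") <- as.integer(omitted)
  out
}

#' Aggregate spots into fixed square bins
#'
#' Standard binning: spots are grouped by `floor(index / k)` with
#' `k = bin_size_um / pitch_um`, which partitions the grid into
#' `bin_size_um` x `bin_size_um` squares (64 um^2 by default, i.e. 16
#' adjacent 4 um^2 spots). Edge bins covering fewer than `k^2` spots are
#' kept and flagged.
#'
#' @param spots a [spot_grid()].
#' @param bin_size_um bin side in micrometres; must be a positive multiple of
#'   the spot pitch.
#' @return A `square_bin_matrix` with per-bin metadata (`bin_row`, `bin_col`,
#'   `n_spots`, `total_counts`, `n_features`, `pct_mito`, `edge_bin`).
#' @export
bin_by_square <- function(spots, bin_size_um = 8) {
  stopifnot(inherits(spots, "spot_grid"))
  k <- bin_size_um / spots$pitch_um
  if (bin_size_um <= 0 || abs(k - round(k)) > 1e-9) {
    abort("bin_size_um must be a positive multiple of the spot pitch",
          class = "nucbin_validation_error")
  }
  k <- as.integer(round(k))
  br <- spots$spots$spot_row %/% k
  bc <- spots$spots$spot_col %/% k
  key <- paste(br, bc, sep = "_")
  present <- unique(key[order(br, bc)])
  grp <- factor(key, levels = present)
  ind <- Matrix::fac2sparse(grp)
  counts <- methods::as(methods::as(ind %*% spots$counts, "CsparseMatrix"),
                        "generalMatrix")
  colnames(counts) <- spots$genes$gene_id
  first <- match(present, key)
  stats <- bin_meta_stats(counts, spots$genes$mito)
  meta <- tibble(
    nucleus_id = paste0("bin", present),
    bin_row = br[first],
    bin_col = bc[first],
    n_spots = as.integer(tabulate(grp)),
    total_counts = stats$total_counts,
    n_features = stats$n_features,
    pct_mito = stats$pct_mito,
    centroid_row = (br[first] + 0.5) * k - 0.5,
    centroid_col = (bc[first] + 0.5) * k - 0.5
  )
  meta$edge_bin <- meta$n_spots < k * k
  rownames(counts) <- meta$nucleus_id
  new_bin_matrix(counts, meta, spots$genes, pitch_um = spots$pitch_um,
                 kind = "square_bin_matrix", bin_size_um = bin_size_um)
}

#' @export
print.bin_matrix <- function(x, ...) {
  cat(sprintf("<%s> %d observations x %d genes, %s total counts\n",
              class(x)[1], nrow(x$counts), ncol(x$counts),
              format(sum(x$counts), big.mark = ",")))
  invisible(x)
}

#' @export
dim.bin_matrix <- function(x) dim(x$counts)

#' Tidiers for binned matrices and spot grids
#'
#' `tidy()` returns per-observation metadata (for a `spot_grid`, the long
#' non-zero counts); `glance()` returns a one-row summary.
#'
#' @param x a `nucleus_matrix`, `square_bin_matrix` or `spot_grid`.
#' @param ... unused.
#' @return A tibble.
#' @name nucbin-tidiers
NULL

#' @rdname nucbin-tidiers
#' @method tidy bin_matrix
#' @export
tidy.bin_matrix <- function(x, ...) x$meta

#' @rdname nucbin-tidiers
#' @method glance bin_matrix
#' @export
glance.bin_matrix <- function(x, ...) {
  tibble(
    n_obs = nrow(x$counts),
    n_genes = ncol(x$counts),
    total_counts = sum(x$counts),
    mean_counts = mean(x$meta$total_counts),
    mean_features = mean(x$meta$n_features)
  )
}

#' Area and spots-per-nucleus summary
#'
#' Summarises the nuclear area distribution and the number of 4 um^2 spots
#' binned into each nucleus.
#'
#' @param nm a non-empty `nucleus_matrix`.
#' @param binwidth_um2 histogram bin width for areas (default 4, one spot).
#' @return List with `summary` (one-row tibble: mean/median area and
#'   spots-per-nucleus) and tibbles `area_histogram`, `spots_histogram`.
#' @export
area_stats <- function(nm, binwidth_um2 = 4) {
  stopifnot(inherits(nm, "nucleus_matrix"))
  if (nrow(nm$meta) == 0L) {
    abort("empty nucleus matrix", class = "nucbin_empty_error")
  }
  a <- nm$meta$area_um2
  s <- nm$meta$n_spots
  brks <- seq(0, max(a) + binwidth_um2, by = binwidth_um2)
  ah <- tibble(
    bin_start = brks[-length(brks)],
    bin_end = brks[-1],
    n = as.integer(table(cut(a, brks, right = FALSE)))
  )
  sh <- tibble(n_spots = seq_len(max(s)),
               n = tabulate(s, nbins = max(s)))
  list(
    summary = tibble(
      n_nuclei = length(a),
      mean_area_um2 = mean(a), median_area_um2 = median(a),
      mean_spots = mean(s), median_spots = median(s)
    ),
    area_histogram = ah,
    spots_histogram = sh
  )
}

#' Regression of per-nucleus counts on nuclear area
#'
#' Ordinary least squares of `total_counts` on `area_um2`, quantifying how
#' strongly transcript recovery scales with nuclear size.
#'
#' @param nm a `nucleus_matrix` with at least 3 nuclei and non-degenerate
#'   areas.
#' @return One-row tibble: `slope`, `intercept`, `r_squared`, `p_value`
#'   (two-sided test of the slope), `n`.
#' @export
counts_area_regression <- function(nm) {
  stopifnot(inherits(nm, "nucleus_matrix"))
  d <- nm$meta
  if (nrow(d) < 3L) {
    abort("need at least 3 nuclei", class = "nucbin_validation_error")
  }
  if (var(d$area_um2) == 0) {
    abort("zero variance in nuclear area; regression is degenerate",
          class = "nucbin_degenerate_error")
  }
  if (var(d$total_counts) == 0) {
    # flat response: no association by definition
    return(tibble(slope = 0, intercept = d$total_counts[1], r_squared = 0,
                  p_value = 1, n = nrow(d)))
  }
  fit <- lm(total_counts ~ area_um2, data = d)
  sm <- summary(fit)
  tibble(
    slope = unname(coef(fit)[2]),
    intercept = unname(coef(fit)[1]),
    r_squared = sm$r.squared,
    p_value = sm$coefficients[2, 4],
    n = nrow(d)
  )
}
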