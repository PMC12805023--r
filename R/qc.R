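# refresh count-derived metadata after subsetting genes or observations
refresh_meta <- function(nm) {
  stats <- bin_meta_stats(nm$counts, nm$genes$mito)
  nm$meta$total_counts <- stats$total_counts
  nm$meta$n_features <- stats$n_features
  nm$meta$pct_mito <- stats$pct_mito
  nm
}

#' Filter genes on total counts
#'
#' Keeps genes whose counts summed over all observations reach `min_total`
#' (inclusive), preserving gene order. Count-derived per-observation metadata
#' (totals, features, mitochondrial percentage) is recomputed on the reduced
#' panel.
#'
#' @param nm a `nucleus_matrix` or `square_bin_matrix`.
#' @param min_total minimum summed counts for a gene (>=, default 3).
#' @return The filtered object.
#' @export
filter_genes <- function(nm, min_total = 3) {
  stopifnot(inherits(nm, "bin_matrix"))
  if (min_total < 0) {
    abort("min_total must be non-negative", class = "nucbin_validation_error")
  }
  keep <- colSums(nm$counts) >= min_total
  if (!any(keep)) {
    abort("gene filter removed every gene", class = "nucbin_empty_error")
  }
  nm$counts <- nm$counts[, keep, drop = FALSE]
  nm$genes <- nm$genes[keep, , drop = FALSE]
  refresh_meta(nm)
}

#' Filter observations on counts and mitochondrial percentage
#'
#' Keeps observations with `total_counts > min_counts` and
#' `pct_mito < max_pct_mito`; both inequalities are strict, so boundary
#' values are removed.
#'
#' @param nm a `nucleus_matrix` or `square_bin_matrix`.
#' @param min_counts strict lower bound on total counts (default 10).
#' @param max_pct_mito strict upper bound on mitochondrial percentage
#'   (default 5).
#' @return The filtered object.
#' @export
filter_nuclei <- function(nm, min_counts = 10, max_pct_mito = 5) {
  stopifnot(inherits(nm, "bin_matrix"))
  if (!is.finite(min_counts) || !is.finite(max_pct_mito)) {
    abort("thresholds must be finite", class = "nucbin_validation_error")
  }
  keep <- nm$meta$total_counts > min_counts & nm$meta$pct_mito < max_pct_mito
  if (!any(keep)) {
    abort("nucleus filter removed every observation",
          class = "nucbin_empty_error")
  }
  nm$counts <- nm$counts[keep, , drop = FALSE]
  nm$meta <- nm$meta[keep, , drop = FALSE]
  nm
}

#' Quality-control summary
#'
#' @param nm a non-empty `nucleus_matrix` or `square_bin_matrix`.
#' @return A `qc_report`: list with `summary` (one-row tibble of means and
#'   sample standard deviations of totals and features; `sd_flagged` marks a
#'   single-observation input whose sd is reported as 0) and `scatter`
#'   (per-observation tibble of `total_counts`, `n_features`, `pct_mito`,
#'   `area_um2` for plotting counts against the other three).
#' @export
qc_summary <- function(nm) {
  stopifnot(inherits(nm, "bin_matrix"))
  if (nrow(nm$meta) == 0L) {
    abort("empty input", class = "nucbin_empty_error")
  }
  single <- nrow(nm$meta) == 1L
  sdv <- function(x) if (single) 0 else sd(x)
  area <- if ("area_um2" %in% names(nm$meta)) nm$meta$area_um2 else
    rep(nm$bin_size_um^2, nrow(nm$meta))
  structure(list(
    summary = tibble(
      n_obs = nrow(nm$meta),
      n_genes = ncol(nm$counts),
      mean_counts = mean(nm$meta$total_counts),
      sd_counts = sdv(nm$meta$total_counts),
      mean_features = mean(nm$meta$n_features),
      sd_features = sdv(nm$meta$n_features),
      mean_pct_mito = mean(nm$meta$pct_mito),
      sd_flagged = single
    ),
    scatter = tibble(
      total_counts = nm$meta$total_counts,
      n_features = nm$meta$n_features,
      pct_mito = nm$meta$pct_mito,
      area_um2 = area
    )
  ), class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "<qc_report> %d observations, %d genes; counts %.2f +/- %.2f, features %.2f +/- %.2f\n",
    s$n_obs, s$n_genes, s$mean_counts, s$sd_counts, s$mean_features,
    s$sd_features))
  invisible(x)
}

#' @rdname nucbin-tidiers
#' @method tidy qc_report
#' @export
tidy.qc_report <- function(x, ...) x$scatter

#' @rdname nucbin-tidiers
#' @method glance qc_report
#' @export
glance.qc_report <- function(x, ...) x$summary

#' Apply the full quality-control stage
#'
#' Runs the gene filter first (gene detection is assessed on the unfiltered
#' observation set), then the observation filter, and reports before/after
#' dimensions together with the thresholds used.
#'
#' @param nm a `nucleus_matrix` or `square_bin_matrix`.
#' @param config a [run_config()] supplying `min_gene_total`,
#'   `min_nucleus_counts` and `max_pct_mito`.
#' @return List with `filtered` (the reduced object) and `report` (one-row
#'   tibble of before/after counts, post-filter summaries and parameters).
#' @export
apply_qc <- function(nm, config = run_config()) {
  before <- c(genes = ncol(nm$counts), obs = nrow(nm$counts))
  nm2 <- filter_genes(nm, config$min_gene_total)
  nm2 <- filter_nuclei(nm2, config$min_nucleus_counts, config$max_pct_mito)
  s <- qc_summary(nm2)$summary
  list(
    filtered = nm2,
    report = tibble(
      n_genes_before = unname(before["genes"]),
      n_genes_after = ncol(nm2$counts),
      n_obs_before = unname(before["obs"]),
      n_obs_after = nrow(nm2$counts),
      mean_counts = s$mean_counts, sd_counts = s$sd_counts,
      mean_features = s$mean_features, sd_features = s$sd_features,
      min_gene_total = config$min_gene_total,
      min_nucleus_counts = config$min_nucleus_counts,
      max_pct_mito = config$max_pct_mito,
      filter_order = "genes_then_nuclei"
    )
  )
}
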