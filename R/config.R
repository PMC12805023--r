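#' Analysis configuration
#'
#' Bundles every threshold and algorithm parameter used by the pipeline, so
#' that a whole run is reproducible from `(config, seed)` and both binning
#' strategies can be processed with provably identical parameters.
#'
#' Defaults follow the filtering rules used throughout the package: genes are
#' kept when their summed counts reach `min_gene_total` (inclusive), nuclei
#' when `total_counts > min_nucleus_counts` and `pct_mito < max_pct_mito`
#' (both strict).
#'
#' @param min_gene_total minimum summed counts for a gene to be kept (>=,
#'   default 3).
#' @param min_nucleus_counts nuclei must exceed this total count (strict >,
#'   default 10).
#' @param max_pct_mito nuclei must fall below this mitochondrial percentage
#'   (strict <, default 5).
#' @param unknown_score_threshold absolute floor on a cluster's winning
#'   median signature score for a confident call (see [assign_types()]).
#' @param dominance_ratio required ratio of the winning signature median
#'   over every competing signature's median for a confident call.
#' @param iou_threshold intersection-over-union threshold for instance
#'   matching (default 0.5).
#' @param n_pcs,n_neighbors,resolution clustering parameters (PCA dimensions,
#'   k for the shared-nearest-neighbor graph, Leiden resolution).
#' @param n_cc,k_anchor,k_weight integration parameters (canonical
#'   dimensions, mutual-nearest-neighbor k, anchors used per correction).
#' @param ucell_rmax rank ceiling of the signature score. 1500 is the
#'   whole-transcriptome convention; for small simulated panels use a value
#'   near the typical number of expressed genes per nucleus (the simulator
#'   pipeline uses 100 for its 500-gene panel).
#' @param square_bin_um side of the square bins used for comparison.
#' @param mito_prefix gene-name prefix flagging mitochondrial genes.
#' @param seed integer seed recorded in every manifest.
#' @return A `run_config` (named list).
#' @export
run_config <- function(min_gene_total = 3,
                       min_nucleus_counts = 10,
                       max_pct_mito = 5,
                       unknown_score_threshold = 0.2,
                       dominance_ratio = 2,
                       iou_threshold = 0.5,
                       n_pcs = 30,
                       n_neighbors = 15,
                       resolution = 1,
                       n_cc = 20,
                       k_anchor = 5,
                       k_weight = 50,
                       ucell_rmax = 100,
                       square_bin_um = 8,
                       mito_prefix = "MT-",
                       seed = 1L) {
  cfg <- list(
    min_gene_total = min_gene_total,
    min_nucleus_counts = min_nucleus_counts,
    max_pct_mito = max_pct_mito,
    unknown_score_threshold = unknown_score_threshold,
    dominance_ratio = dominance_ratio,
    iou_threshold = iou_threshold,
    n_pcs = n_pcs,
    n_neighbors = n_neighbors,
    resolution = resolution,
    n_cc = n_cc,
    k_anchor = k_anchor,
    k_weight = k_weight,
    ucell_rmax = ucell_rmax,
    square_bin_um = square_bin_um,
    mito_prefix = mito_prefix,
    seed = as.integer(seed)
  )
  num <- vapply(cfg[setdiff(names(cfg), "mito_prefix")], is.numeric, logical(1))
  if (!all(num) || !all(is.finite(unlist(cfg[setdiff(names(cfg), "mito_prefix")])))) {
    abort("all thresholds and parameters must be finite numbers",
          class = "nucbin_validation_error")
  }
  structure(cfg, class = "run_config")
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config>\n")
  for (nm in names(x)) cat(sprintf("  %s: %s\n", nm, format(x[[nm]])))
  invisible(x)
}
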