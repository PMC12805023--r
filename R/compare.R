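#' Run the full single-sample pipeline on a binned matrix
#'
#' QC (gene filter then observation filter), depth normalisation, graph
#' clustering, signature scoring and per-cluster cell-type assignment — one
#' branch of the binning comparison.
#'
#' @param nm a `nucleus_matrix` or `square_bin_matrix`.
#' @param signatures named list of gene signatures.
#' @param config a [run_config()].
#' @return An `annotated_dataset`: list with `nm` (post-QC matrix),
#'   `clusters` (a `cluster_result`), `scores` (observation x signature),
#'   `assignment` (output of [assign_types()]), `qc_report`, and `manifest`.
#' @export
annotate_dataset <- function(nm, signatures = default_signatures(),
                             config = run_config()) {
  qc <- apply_qc(nm, config)
  norm <- normalize_log(qc$filtered)
  cl <- cluster_graph(norm, n_pcs = config$n_pcs,
                      n_neighbors = config$n_neighbors,
                      resolution = config$resolution, seed = config$seed)
  scores <- signature_score(norm, signatures, rmax = config$ucell_rmax)
  asg <- assign_types(scores, cl$labels,
                      unknown_score_threshold = config$unknown_score_threshold,
                      dominance_ratio = config$dominance_ratio)
  manifest <- list(
    stage = "annotate",
    binning = if (inherits(nm, "square_bin_matrix")) {
      list(strategy = "square", bin_size_um = nm$bin_size_um)
    } else {
      list(strategy = "nuclei")
    },
    parameters = unclass(config)
  )
  structure(list(
    nm = qc$filtered,
    clusters = cl,
    scores = scores,
    assignment = asg,
    qc_report = qc$report,
    manifest = manifest
  ), class = "annotated_dataset")
}

#' @export
print.annotated_dataset <- function(x, ...) {
  calls <- setdiff(unique(x$assignment$calls$call), "unknown")
  cat(sprintf(
    "<annotated_dataset> %d observations, %d clusters, %d called types (unknown fraction %.1f%%)\n",
    nrow(x$nm$counts), nlevels(x$clusters$labels), length(calls),
    100 * unknown_fraction(x)))
  invisible(x)
}

#' @rdname nucbin-tidiers
#' @method tidy annotated_dataset
#' @export
tidy.annotated_dataset <- function(x, ...) {
  calls <- x$assignment$calls
  cl <- as.character(x$clusters$labels)
  dplyr::bind_cols(
    x$nm$meta,
    tibble(cluster = cl,
           call = calls$call[match(cl, calls$cluster)]),
    as_tibble(x$scores)
  )
}

#' @rdname nucbin-tidiers
#' @method glance annotated_dataset
#' @export
glance.annotated_dataset <- function(x, ...) {
  tibble(
    n_obs = nrow(x$nm$counts),
    n_clusters = nlevels(x$clusters$labels),
    n_called_types = length(setdiff(unique(x$assignment$calls$call), "unknown")),
    unknown_fraction = unknown_fraction(x)
  )
}

#' Annotate a multi-patient cohort on a joint integrated embedding
#'
#' The cohort analogue of [annotate_dataset()]: each patient's binned matrix
#' is QC-filtered and normalised, the datasets are integrated with
#' [integrate_datasets()], clustering runs once on the corrected joint
#' matrix, and signature scores are computed per patient on the uncorrected
#' normalised data (ranks are taken within each patient) before per-cluster
#' assignment.
#'
#' @param nm_list list of `nucleus_matrix`/`square_bin_matrix`, one per
#'   patient.
#' @param signatures named list of gene signatures.
#' @param config a [run_config()].
#' @return An `annotated_dataset` whose `nm` holds the stacked post-QC
#'   counts (shared gene panel) with a `batch` metadata column.
#' @export
annotate_cohort <- function(nm_list, signatures = default_signatures(),
                            config = run_config()) {
  stopifnot(length(nm_list) >= 2L)
  if (is.null(names(nm_list))) names(nm_list) <- paste0("p", seq_along(nm_list))
  qcs <- lapply(nm_list, function(x) apply_qc(x, config))
  filt <- lapply(qcs, `[[`, "filtered")
  norms <- lapply(filt, normalize_log)
  int <- integrate_datasets(norms, n_cc = config$n_cc,
                            k_anchor = config$k_anchor,
                            k_weight = config$k_weight)
  cl <- cluster_graph(int$corrected, n_pcs = config$n_pcs,
                      n_neighbors = config$n_neighbors,
                      resolution = config$resolution, seed = config$seed)
  shared <- colnames(int$corrected)
  scores <- do.call(rbind, lapply(norms, function(m) {
    signature_score(m[, shared, drop = FALSE], signatures,
                    rmax = config$ucell_rmax)
  }))
  asg <- assign_types(scores, cl$labels,
                      unknown_score_threshold = config$unknown_score_threshold,
                      dominance_ratio = config$dominance_ratio)
  counts <- do.call(rbind, lapply(filt, function(x) {
    x$counts[, shared, drop = FALSE]
  }))
  meta <- dplyr::bind_rows(lapply(names(filt), function(nm_) {
    dplyr::mutate(filt[[nm_]]$meta, batch = nm_)
  }))
  genes <- filt[[1]]$genes[match(shared, filt[[1]]$genes$gene_id), ]
  stacked <- new_bin_matrix(counts, meta, genes,
                            pitch_um = filt[[1]]$pitch_um,
                            kind = class(nm_list[[1]])[1])
  manifest <- list(
    stage = "annotate_cohort",
    binning = if (inherits(nm_list[[1]], "square_bin_matrix")) {
      list(strategy = "square", bin_size_um = nm_list[[1]]$bin_size_um)
    } else {
      list(strategy = "nuclei")
    },
    integration = list(reference = int$reference,
                       n_datasets = length(nm_list)),
    parameters = unclass(config)
  )
  structure(list(
    nm = stacked,
    clusters = cl,
    scores = scores,
    assignment = asg,
    qc_report = dplyr::bind_rows(lapply(qcs, `[[`, "report")),
    batch = int$dataset,
    manifest = manifest
  ), class = "annotated_dataset")
}

#' Run both binning strategies on a cohort
#'
#' Applies nucleus binning and square binning to every patient of a cohort
#' and annotates each strategy on its own integrated embedding with
#' identical parameters, mirroring a comparison performed on integrated
#' multi-patient data.
#'
#' @param spots_list list of [spot_grid()]s, one per patient.
#' @param labels_list list of [label_image()]s matching `spots_list`.
#' @param signatures named list of gene signatures.
#' @param config a [run_config()].
#' @return A `binning_comparison`.
#' @export
run_both_cohort <- function(spots_list, labels_list,
                            signatures = default_signatures(),
                            config = run_config()) {
  stopifnot(length(spots_list) == length(labels_list))
  nuc <- annotate_cohort(
    purrr::map2(spots_list, labels_list, bin_by_nuclei), signatures, config)
  sq <- annotate_cohort(
    lapply(spots_list, bin_by_square, bin_size_um = config$square_bin_um),
    signatures, config)
  structure(list(nuclei = nuc, square = sq, config = config),
            class = "binning_comparison")
}

#' Run both binning strategies with identical parameters
#'
#' Processes the same spot grid once through nucleus binning and once
#' through fixed square binning, with identical QC thresholds, clustering
#' parameters, signatures and seed; the two manifests differ only in their
#' binning stanza.
#'
#' @param spots a [spot_grid()].
#' @param labels a [label_image()] for the nucleus branch.
#' @param signatures named list of gene signatures.
#' @param config a [run_config()] (supplies `square_bin_um`).
#' @return A `binning_comparison`: list with `nuclei` and `square`
#'   `annotated_dataset`s.
#' @export
run_both <- function(spots, labels, signatures = default_signatures(),
                     config = run_config()) {
  nuc <- annotate_dataset(bin_by_nuclei(spots, labels), signatures, config)
  sq <- annotate_dataset(bin_by_square(spots, config$square_bin_um),
                         signatures, config)
  structure(list(nuclei = nuc, square = sq, config = config),
            class = "binning_comparison")
}

#' Overlap of called cell-type sets
#'
#' @param calls_a,calls_b character vectors of per-cluster calls ("unknown"
#'   is excluded before comparison).
#' @return One-row tibble with `n_shared`, `n_unique_a`, `n_unique_b` and
#'   the member lists as list columns.
#' @export
celltype_overlap <- function(calls_a, calls_b) {
  a <- setdiff(unique(calls_a), "unknown")
  b <- setdiff(unique(calls_b), "unknown")
  tibble(
    n_shared = length(intersect(a, b)),
    n_unique_a = length(setdiff(a, b)),
    n_unique_b = length(setdiff(b, a)),
    shared = list(sort(intersect(a, b))),
    unique_a = list(sort(setdiff(a, b))),
    unique_b = list(sort(setdiff(b, a)))
  )
}

#' Fraction of observations in unconfidently assigned clusters
#'
#' @param ad an `annotated_dataset`.
#' @return Fraction in `[0, 1]` of post-QC observations whose cluster is
#'   called `"unknown"`.
#' @export
unknown_fraction <- function(ad) {
  stopifnot(inherits(ad, "annotated_dataset"))
  calls <- ad$assignment$calls
  cl <- as.character(ad$clusters$labels)
  mean(calls$call[match(cl, calls$cluster)] == "unknown")
}

#' Compare the focal type's signature scores between strategies
#'
#' Collects the per-observation signature scores of the clusters called
#' `focal` in each branch and compares them with a two-sided Wilcoxon
#' rank-sum test; also reports the observation-count ratio between
#' branches.
#'
#' @param ad_a,ad_b `annotated_dataset`s (e.g. nuclei and square branches).
#' @param focal cell type/state of interest (default "podocyte").
#' @param signature signature column used for the score comparison (default
#'   `focal`).
#' @return One-row tibble: `p_value`, `median_a`, `median_b`, `n_a`, `n_b`,
#'   `ratio_b_over_a`, `focal_absent` flag.
#' @export
focal_signature_test <- function(ad_a, ad_b, focal = "podocyte",
                                 signature = focal) {
  grab <- function(ad) {
    calls <- ad$assignment$calls
    focal_clusters <- calls$cluster[calls$call == focal]
    keep <- as.character(ad$clusters$labels) %in% focal_clusters
    ad$scores[keep, signature]
  }
  sa <- grab(ad_a); sb <- grab(ad_b)
  if (!length(sa) || !length(sb)) {
    return(tibble(p_value = NA_real_, median_a = NA_real_,
                  median_b = NA_real_, n_a = length(sa), n_b = length(sb),
                  ratio_b_over_a = NA_real_, focal_absent = TRUE))
  }
  w <- wilcox_rank_sum(sa, sb)
  tibble(
    p_value = w$p_value,
    median_a = median(sa), median_b = median(sb),
    n_a = length(sa), n_b = length(sb),
    ratio_b_over_a = length(sb) / length(sa),
    focal_absent = FALSE
  )
}

#' Full comparison report for two binning strategies
#'
#' @param cmp a `binning_comparison` from [run_both()].
#' @param focal focal cell type for the score comparison.
#' @return A `comparison_report`: list with `celltypes` (overlap tibble),
#'   `unknown` (per-strategy fractions), `focal` (score-test tibble) and
#'   `counts` (post-QC observation totals).
#' @export
comparison_report <- function(cmp, focal = "podocyte") {
  stopifnot(inherits(cmp, "binning_comparison"))
  structure(list(
    celltypes = celltype_overlap(cmp$nuclei$assignment$calls$call,
                                 cmp$square$assignment$calls$call),
    unknown = tibble(
      strategy = c("nuclei", "square"),
      unknown_fraction = c(unknown_fraction(cmp$nuclei),
                           unknown_fraction(cmp$square))
    ),
    focal = focal_signature_test(cmp$nuclei, cmp$square, focal),
    counts = tibble(
      strategy = c("nuclei", "square"),
      n_obs = c(nrow(cmp$nuclei$nm$counts), nrow(cmp$square$nm$counts)),
      n_clusters = c(nlevels(cmp$nuclei$clusters$labels),
                     nlevels(cmp$square$clusters$labels)),
      n_called_types = c(
        length(setdiff(unique(cmp$nuclei$assignment$calls$call), "unknown")),
        length(setdiff(unique(cmp$square$assignment$calls$call), "unknown"))
      )
    ),
    focal_type = focal
  ), class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("<comparison_report>\n")
  cat(sprintf("  called types: %d shared, %d nuclei-only, %d square-only\n",
              x$celltypes$n_shared, x$celltypes$n_unique_a,
              x$celltypes$n_unique_b))
  cat(sprintf("  unknown fraction: nuclei %.1f%%, square %.1f%%\n",
              100 * x$unknown$unknown_fraction[1],
              100 * x$unknown$unknown_fraction[2]))
  if (!x$focal$focal_absent) {
    cat(sprintf("  %s score: medians %.3f vs %.3f, Wilcoxon p = %.3g, n ratio %.2f\n",
                x$focal_type, x$focal$median_a, x$focal$median_b,
                x$focal$p_value, x$focal$ratio_b_over_a))
  }
  invisible(x)
}

#' @rdname nucbin-tidiers
#' @method glance comparison_report
#' @export
glance.comparison_report <- function(x, ...) {
  tibble(
    n_shared_types = x$celltypes$n_shared,
    n_unique_nuclei = x$celltypes$n_unique_a,
    n_unique_square = x$celltypes$n_unique_b,
    unknown_nuclei = x$unknown$unknown_fraction[1],
    unknown_square = x$unknown$unknown_fraction[2],
    focal_p_value = x$focal$p_value,
    focal_n_ratio = x$focal$ratio_b_over_a
  )
}
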