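#' Spot-level count grid
#'
#' Container for unique-molecular-identifier (UMI) counts measured on a
#' regular grid of square capture spots (2 x 2 um by default, as on
#' probe-based subcellular spatial transcriptomics platforms). Rows of the
#' sparse count matrix are spots, columns are genes; spot positions are
#' 0-based integer grid indices, so physical coordinates are
#' `index * pitch_um`.
#'
#' @param counts spot-by-gene matrix of non-negative integers (coerced to a
#'   sparse `Matrix`).
#' @param spot_row,spot_col integer grid indices (0-based), one per spot.
#' @param gene_ids unique gene identifiers, one per matrix column.
#' @param pitch_um spot pitch in micrometres (default 2).
#' @param mito_flags optional logical per gene marking mitochondrial genes;
#'   when `NULL`, derived from `mito_prefix`.
#' @param mito_prefix gene-name prefix identifying mitochondrial genes
#'   (default `"MT-"`).
#'
#' @return A `spot_grid`: list with elements `counts` (dgCMatrix,
#'   spots x genes), `spots` (tibble of grid indices), `genes` (tibble with
#'   `gene_id` and `mito`), and `pitch_um`.
#' @export
spot_grid <- function(counts, spot_row, spot_col, gene_ids, pitch_um = 2,
                      mito_flags = NULL, mito_prefix = "MT-") {
  counts <- methods::as(methods::as(counts, "CsparseMatrix"), "generalMatrix")
  spot_row <- as.integer(spot_row)
  spot_col <- as.integer(spot_col)
  gene_ids <- as.character(gene_ids)
  if (length(spot_row) != nrow(counts) || length(spot_col) != nrow(counts)) {
    abort("spot positions must align with count matrix rows",
          class = "nucbin_format_error")
  }
  if (length(gene_ids) != ncol(counts)) {
    abort("gene identifiers must align with count matrix columns",
          class = "nucbin_format_error")
  }
  if (anyDuplicated(gene_ids)) {
    abort("gene identifiers must be unique", class = "nucbin_validation_error")
  }
  if (anyDuplicated(cbind(spot_row, spot_col))) {
    abort("duplicate (spot_row, spot_col) pairs", class = "nucbin_validation_error")
  }
  if (any(spot_row < 0L) || any(spot_col < 0L)) {
    abort("grid indices must be non-negative", class = "nucbin_validation_error")
  }
  x <- counts@x
  if (any(x < 0) || any(x != round(x))) {
    abort("counts must be non-negative integers", class = "nucbin_validation_error")
  }
  if (!is.numeric(pitch_um) || length(pitch_um) != 1L || pitch_um <= 0) {
    abort("pitch_um must be a positive scalar", class = "nucbin_validation_error")
  }
  if (is.null(mito_flags)) {
    mito_flags <- startsWith(gene_ids, mito_prefix)
  }
  colnames(counts) <- gene_ids
  structure(
    list(
      counts = counts,
      spots = tibble(spot_row = spot_row, spot_col = spot_col),
      genes = tibble(gene_id = gene_ids, mito = as.logical(mito_flags)),
      pitch_um = as.numeric(pitch_um)
    ),
    class = "spot_grid"
  )
}

#' @export
print.spot_grid <- function(x, ...) {
  cat(sprintf(
    "<spot_grid> %d spots x %d genes, pitch %.3g um, %s total counts\n",
    nrow(x$counts), ncol(x$counts), x$pitch_um,
    format(sum(x$counts), big.mark = ",")
  ))
  invisible(x)
}

#' @export
dim.spot_grid <- function(x) dim(x$counts)

#' @rdname nucbin-tidiers
#' @method tidy spot_grid
#' @export
tidy.spot_grid <- function(x, ...) {
  tr <- Matrix::summary(x$counts)
  tibble(
    spot_row = x$spots$spot_row[tr$i],
    spot_col = x$spots$spot_col[tr$i],
    gene_id = x$genes$gene_id[tr$j],
    count = as.integer(tr$x)
  )
}

#' @rdname nucbin-tidiers
#' @method glance spot_grid
#' @export
glance.spot_grid <- function(x, ...) {
  tibble(
    n_spots = nrow(x$counts),
    n_genes = ncol(x$counts),
    total_counts = sum(x$counts),
    pitch_um = x$pitch_um
  )
}
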