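#' Read a spot-by-gene count matrix from Matrix Market + TSV files
#'
#' Expects the layout written by [write_spot_matrix()]: a Matrix Market
#' coordinate file of non-negative integer counts (spots x genes), a gene
#' table and a spot-position table, both row-aligned with the matrix.
#'
#' @param mtx_path Matrix Market file of counts.
#' @param genes_path TSV with column `gene_id` (optional logical `mito`).
#' @param positions_path TSV with columns `spot_row`, `spot_col` (0-based).
#' @param pitch_um spot pitch in micrometres.
#' @param mito_prefix prefix used to flag mitochondrial genes when the gene
#'   table has no `mito` column.
#' @return A [spot_grid()].
#' @export
read_spot_matrix <- function(mtx_path, genes_path, positions_path,
                             pitch_um = 2, mito_prefix = "MT-") {
  m <- Matrix::readMM(mtx_path)
  genes <- utils::read.delim(genes_path, stringsAsFactors = FALSE)
  pos <- utils::read.delim(positions_path, stringsAsFactors = FALSE)
  if (nrow(genes) != ncol(m)) {
    abort(sprintf("gene table '%s' has %d rows but matrix '%s' has %d columns",
                  genes_path, nrow(genes), mtx_path, ncol(m)),
          class = "nucbin_format_error")
  }
  if (nrow(pos) != nrow(m)) {
    abort(sprintf("position table '%s' has %d rows but matrix '%s' has %d rows",
                  positions_path, nrow(pos), mtx_path, nrow(m)),
          class = "nucbin_format_error")
  }
  if (any(m@x < 0) || any(m@x != round(m@x))) {
    abort(sprintf("matrix '%s' contains negative or non-integer entries", mtx_path),
          class = "nucbin_validation_error")
  }
  spot_grid(m, pos$spot_row, pos$spot_col, genes$gene_id,
            pitch_um = pitch_um,
            mito_flags = if ("mito" %in% names(genes)) as.logical(genes$mito) else NULL,
            mito_prefix = mito_prefix)
}

#' Write a spot grid to disk
#'
#' Writes `counts.mtx`, `genes.tsv`, `positions.tsv` and a small
#' `spot_grid.json` metadata file into `dir`.
#'
#' @param sg a [spot_grid()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_spot_matrix <- function(sg, dir) {
  stopifnot(inherits(sg, "spot_grid"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(sg$counts, file.path(dir, "counts.mtx"))
  utils::write.table(sg$genes, file.path(dir, "genes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sg$spots, file.path(dir, "positions.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_json_sorted(list(pitch_um = sg$pitch_um), file.path(dir, "spot_grid.json"))
  invisible(dir)
}

#' Read a nucleus label image from a single-channel integer TIFF
#'
#' @param tiff_path path to a 16-bit (or 8-bit) single-channel TIFF.
#' @param pixel_size_um physical pixel size in micrometres.
#' @param offset integer `(row, col)` registration offset to the spot grid.
#' @return A [label_image()]; warns if the image contains no nuclei.
#' @export
read_label_image <- function(tiff_path, pixel_size_um = 2, offset = c(0L, 0L)) {
  img <- tiff::readTIFF(tiff_path, as.is = TRUE)
  if (length(dim(img)) == 3L) {
    abort(sprintf("'%s' is a multi-channel image; expected single-channel labels",
                  tiff_path),
          class = "nucbin_validation_error")
  }
  if (is.double(img) && any(img != round(img))) {
    abort(sprintf("'%s' holds floating-point samples; expected integer labels",
                  tiff_path),
          class = "nucbin_validation_error")
  }
  out <- label_image(img, pixel_size_um = pixel_size_um, offset = offset)
  if (label_summary(out)$n_labels == 0L) {
    warn("label image contains no nuclei (all background)")
  }
  out
}

#' Write a label image as a 16-bit single-channel TIFF
#'
#' @param img a [label_image()]; labels must not exceed 65535.
#' @param tiff_path output path.
#' @return `tiff_path`, invisibly.
#' @export
write_label_image <- function(img, tiff_path) {
  stopifnot(inherits(img, "label_image"))
  if (max(img$labels) > 65535L) {
    abort("labels exceed the 16-bit range", class = "nucbin_validation_error")
  }
  tiff::writeTIFF(img$labels / 65535, tiff_path, bits.per.sample = 16L,
                  compression = "none")
  invisible(tiff_path)
}

#' Read cell-type gene signatures from a two-column TSV
#'
#' @param path TSV with columns `type` and `gene`.
#' @return Named list of unique gene vectors, one element per type.
#' @export
read_signatures <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("type", "gene") %in% names(tab))) {
    abort(sprintf("'%s' must have columns 'type' and 'gene'", path),
          class = "nucbin_format_error")
  }
  lapply(split(tab$gene, tab$type), unique)
}

#' Write cell-type gene signatures to TSV
#'
#' @param signatures named list of gene vectors.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_signatures <- function(signatures, path) {
  tab <- tibble(
    type = rep(names(signatures), lengths(signatures)),
    gene = unlist(signatures, use.names = FALSE)
  )
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a nucleus (or square-bin) matrix to disk
#'
#' Writes `counts.mtx`, `genes.tsv` and `metadata.tsv` into `dir`.
#'
#' @param nm a `nucleus_matrix` or `square_bin_matrix`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_nucleus_matrix <- function(nm, dir) {
  stopifnot(inherits(nm, "bin_matrix"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(nm$counts, file.path(dir, "counts.mtx"))
  utils::write.table(nm$genes, file.path(dir, "genes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(nm$meta, file.path(dir, "metadata.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_json_sorted(
    list(kind = class(nm)[1], pitch_um = nm$pitch_um,
         bin_size_um = nm$bin_size_um %||% NULL),
    file.path(dir, "bin_matrix.json")
  )
  invisible(dir)
}

#' Read a nucleus (or square-bin) matrix written by [write_nucleus_matrix()]
#'
#' @param dir directory holding `counts.mtx`, `genes.tsv`, `metadata.tsv`.
#' @return A `nucleus_matrix` or `square_bin_matrix`.
#' @export
read_nucleus_matrix <- function(dir) {
  meta <- as_tibble(utils::read.delim(file.path(dir, "metadata.tsv"),
                                      stringsAsFactors = FALSE))
  genes <- as_tibble(utils::read.delim(file.path(dir, "genes.tsv"),
                                       stringsAsFactors = FALSE))
  counts <- methods::as(methods::as(Matrix::readMM(file.path(dir, "counts.mtx")),
                                    "CsparseMatrix"), "generalMatrix")
  info <- jsonlite::read_json(file.path(dir, "bin_matrix.json"))
  colnames(counts) <- genes$gene_id
  new_bin_matrix(counts, meta, genes, pitch_um = info$pitch_um,
                 kind = info$kind, bin_size_um = info$bin_size_um)
}

#' Write a JSON run manifest
#'
#' Every pipeline stage records its inputs, parameters (including the seed)
#' and package versions so that runs are reproducible and parameter identity
#' between branches can be verified by diffing manifests.
#'
#' @param path output JSON path.
#' @param stage stage name (character).
#' @param inputs named list describing input artifacts.
#' @param config a [run_config()] or plain named list of parameters.
#' @return The manifest list, invisibly.
#' @export
write_manifest <- function(path, stage, inputs = list(), config = list()) {
  manifest <- list(
    stage = stage,
    inputs = inputs,
    parameters = unclass(config),
    versions = list(
      r = R.version.string,
      nucbin = as.character(utils::packageVersion("nucbin"))
    )
  )
  write_json_sorted(manifest, path)
  invisible(manifest)
}

# deterministic serialization: names sorted recursively, stable number format
write_json_sorted <- function(x, path) {
  sort_rec <- function(v) {
    if (is.list(v) && !is.null(names(v)) && length(v)) {
      v <- v[order(names(v))]
      lapply(v, sort_rec)
    } else if (is.list(v)) lapply(v, sort_rec) else v
  }
  jsonlite::write_json(sort_rec(x), path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}
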