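#' Nucleus instance-segmentation label image
#'
#' A 2-D integer matrix in which 0 is background and each positive value is
#' one nucleus instance. The pixel grid is registered to the spot grid of a
#' [spot_grid()] one pixel per spot; a cropped region of interest carries an
#' integer `(offset_row, offset_col)` translating spot indices to pixel
#' indices.
#'
#' @param labels integer matrix, values >= 0.
#' @param pixel_size_um physical pixel size in micrometres (default 2).
#' @param offset integer length-2 vector `(row, col)` added to spot grid
#'   indices to obtain pixel indices (default `c(0, 0)`).
#'
#' @return A `label_image` with elements `labels`, `pixel_size_um`, `offset`.
#' @export
label_image <- function(labels, pixel_size_um = 2, offset = c(0L, 0L)) {
  labels <- as.matrix(labels)
  if (!is.numeric(labels) || any(labels < 0) || any(labels != round(labels))) {
    abort("labels must be non-negative integers", class = "nucbin_validation_error")
  }
  if (!is.numeric(pixel_size_um) || pixel_size_um <= 0) {
    abort("pixel_size_um must be positive", class = "nucbin_validation_error")
  }
  storage.mode(labels) <- "integer"
  structure(
    list(labels = labels, pixel_size_um = as.numeric(pixel_size_um),
         offset = as.integer(offset)),
    class = "label_image"
  )
}

#' Summarise the labels present in a label image
#'
#' Reports the number of distinct nucleus instances and whether the label set
#' is contiguous (`{1..K}`) or has gaps.
#'
#' @param img a [label_image()].
#' @return One-row tibble with `n_labels`, `max_label`, `has_gaps`, and the
#'   missing labels as a list column.
#' @export
label_summary <- function(img) {
  stopifnot(inherits(img, "label_image"))
  present <- sort(unique(as.vector(img$labels)))
  present <- present[present > 0L]
  k <- length(present)
  mx <- if (k) max(present) else 0L
  missing <- if (k) setdiff(seq_len(mx), present) else integer()
  tibble(
    n_labels = k,
    max_label = mx,
    has_gaps = length(missing) > 0L,
    missing_labels = list(missing)
  )
}

#' @export
print.label_image <- function(x, ...) {
  s <- label_summary(x)
  cat(sprintf("<label_image> %d x %d px (%.3g um/px), %d nuclei%s\n",
              nrow(x$labels), ncol(x$labels), x$pixel_size_um, s$n_labels,
              if (s$has_gaps) " (non-contiguous labels)" else ""))
  invisible(x)
}

#' @export
dim.label_image <- function(x) dim(x$labels)

# pixel index sets per nonzero label, named by label
label_pixel_sets <- function(labels) {
  v <- as.vector(labels)
  keep <- v > 0L
  split(which(keep), v[keep])
}

# centroids in 0-based (row, col) pixel coordinates
label_centroids <- function(labels) {
  sets <- label_pixel_sets(labels)
  if (!length(sets)) {
    return(tibble(label = integer(), centroid_row = numeric(),
                  centroid_col = numeric(), n_px = integer()))
  }
  nr <- nrow(labels)
  purrr::imap_dfr(sets, function(idx, lab) {
    r <- (idx - 1L) %% nr
    c <- (idx - 1L) %/% nr
    tibble(label = as.integer(lab), centroid_row = mean(r), centroid_col = mean(c),
           n_px = length(idx))
  })
}
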