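#' QC scatter panels
#'
#' Counts per observation against detected features, mitochondrial
#' percentage and nuclear area.
#'
#' @param object a `qc_report` from [qc_summary()].
#' @param ... unused.
#' @return A ggplot.
#' @method autoplot qc_report
#' @export
autoplot.qc_report <- function(object, ...) {
  d <- object$scatter |>
    tidyr::pivot_longer(c("n_features", "pct_mito", "area_um2"),
                        names_to = "metric", values_to = "value")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$total_counts, y = .data$value)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.6) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "UMI counts", y = NULL) +
    ggplot2::theme_bw()
}

#' Nuclear area and spots-per-nucleus histograms
#'
#' @param nm a `nucleus_matrix`.
#' @param binwidth_um2 area histogram bin width.
#' @return A ggplot (area histogram with a spots-per-nucleus inset-style
#'   second facet).
#' @export
plot_area_distribution <- function(nm, binwidth_um2 = 4) {
  s <- area_stats(nm, binwidth_um2)
  d <- dplyr::bind_rows(
    dplyr::transmute(s$area_histogram, x = .data$bin_start + binwidth_um2 / 2,
                     n = .data$n, panel = "nuclear area (um^2)"),
    dplyr::transmute(s$spots_histogram, x = .data$n_spots, n = .data$n,
                     panel = "spots per nucleus")
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$n)) +
    ggplot2::geom_col(width = if (binwidth_um2 > 1) binwidth_um2 * 0.9 else 0.9) +
    ggplot2::facet_wrap(~panel, scales = "free") +
    ggplot2::labs(x = NULL, y = "nuclei") +
    ggplot2::theme_bw()
}

#' Per-cluster signature-score distributions
#'
#' @param ad an `annotated_dataset`.
#' @param signature signature column to plot.
#' @return A ggplot of score distributions by cluster, coloured by call.
#' @export
plot_signature_scores <- function(ad, signature = "podocyte") {
  d <- tidy(ad)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$cluster,
                                  y = .data[[signature]],
                                  fill = .data$call)) +
    ggplot2::geom_boxplot(outlier.size = 0.5) +
    ggplot2::labs(y = paste(signature, "signature score"), x = "cluster") +
    ggplot2::theme_bw()
}

#' Binning-comparison overview
#'
#' Unknown-assignment fraction and called-type counts per strategy.
#'
#' @param object a `comparison_report`.
#' @param ... unused.
#' @return A ggplot.
#' @method autoplot comparison_report
#' @export
autoplot.comparison_report <- function(object, ...) {
  d <- dplyr::left_join(object$unknown, object$counts, by = "strategy") |>
    tidyr::pivot_longer(c("unknown_fraction", "n_called_types"),
                        names_to = "metric", values_to = "value")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$strategy, y = .data$value)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_bw()
}

#' Label-image overview plot
#'
#' @param object a `label_image`.
#' @param ... unused.
#' @return A ggplot raster of nucleus footprints.
#' @method autoplot label_image
#' @export
autoplot.label_image <- function(object, ...) {
  lab <- object$labels
  idx <- which(lab > 0L)
  d <- tibble(
    row = (idx - 1L) %% nrow(lab),
    col = (idx - 1L) %/% nrow(lab),
    label = factor(lab[idx])
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$col, y = .data$row,
                                  fill = .data$label)) +
    ggplot2::geom_raster(show.legend = FALSE) +
    ggplot2::coord_equal() +
    ggplot2::scale_y_reverse() +
    ggplot2::theme_void()
}
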