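#' Plot a pairwise F1 matrix as a heatmap
#'
#' @param object A `"pairwise_f1"` matrix from [pairwise_f1()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pairwise_f1 <- function(object, ...) {
  df <- tibble::as_tibble(as.data.frame(as.table(unclass(object)),
                                        stringsAsFactors = FALSE))
  names(df) <- c("source_a", "source_b", "macro_f1")
  ggplot2::ggplot(df, ggplot2::aes(.data$source_a, .data$source_b,
                                   fill = .data$macro_f1)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(
      label = ifelse(is.na(.data$macro_f1), "", sprintf("%.2f", .data$macro_f1))),
      size = 3) +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1), na.value = "grey90") +
    ggplot2::labs(x = NULL, y = NULL, fill = "macro F1",
                  title = "Pairwise macro F1") +
    ggplot2::theme_minimal()
}

#' Bland-Altman plot
#'
#' Scatter of per-case differences against per-case means with the mean
#' difference and 1.96-SD limits of agreement.
#'
#' @param object A `"bland_altman"` object from [bland_altman()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.bland_altman <- function(object, ...) {
  df <- tidy.bland_altman(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$mean, .data$diff)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_hline(yintercept = object$mean_diff, color = "blue") +
    ggplot2::geom_hline(yintercept = c(object$loa_low, object$loa_high),
                        linetype = "dashed", color = "red") +
    ggplot2::labs(x = "Mean of the two measurements (TPS %)",
                  y = "Difference (TPS %)",
                  title = sprintf("Bland-Altman: mean difference %.2f (LoA %.2f to %.2f)",
                                  object$mean_diff, object$loa_low,
                                  object$loa_high)) +
    ggplot2::theme_minimal()
}

#' Plot an ROI with its annotations
#'
#' Renders the point annotations of one or more sources over the ROI frame,
#' colored by class and shaped by source — the standard side-by-side view
#' of reader and detector output.
#'
#' @param roi An object from [generate_tissue_roi()].
#' @param annotations Optional annotation-set tibble (possibly several
#'   sources); defaults to the ROI's own ground-truth cells.
#' @return A ggplot object.
#' @export
plot_roi <- function(roi, annotations = NULL) {
  stopifnot(inherits(roi, "roi"))
  df <- if (is.null(annotations)) {
    dplyr::mutate(roi$cells, source = "truth")
  } else {
    as_annotation_set(annotations)
  }
  ggplot2::ggplot(df, ggplot2::aes(.data$x_um, .data$y_um,
                                   color = .data$class,
                                   shape = .data$source)) +
    ggplot2::geom_point(size = 2, alpha = 0.8) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed(xlim = c(0, roi$width_um),
                         ylim = c(roi$height_um, 0)) +
    ggplot2::scale_color_manual(values = c(neg_tumor = "#2166ac",
                                           pos_tumor = "#b2182b",
                                           other = "#e6b800")) +
    ggplot2::labs(x = "x (um)", y = "y (um)") +
    ggplot2::theme_minimal()
}
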