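#' Spatial map of cells, plaques and the region outline
#'
#' @param cells Cell table with centroids.
#' @param plaques Plaque table.
#' @param region Region polygon vertex matrix (optional).
#' @param records Proximity records from [compute_proximity()] (optional;
#'   colours cells by label).
#' @return A ggplot object.
#' @export
plot_proximity_map <- function(cells, plaques, region = NULL,
                               records = NULL) {
  df <- tibble::as_tibble(cells)
  if (!is.null(records)) {
    df <- dplyr::left_join(df, dplyr::select(records, "cell_id", "label"),
                           by = "cell_id")
    df$label[is.na(df$label)] <- "outside region"
  } else {
    df$label <- "cell"
  }
  quads <- plaque_vertex_list(plaques)
  poly <- dplyr::bind_rows(lapply(seq_along(quads), function(i) {
    tibble::tibble(plaque_id = plaques$plaque_id[i],
                   x = quads[[i]][, 1], y = quads[[i]][, 2])
  }))
  gg <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x_um, y = .data$y_um)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$label), size = 0.4) +
    ggplot2::geom_polygon(data = poly,
                          ggplot2::aes(x = .data$x, y = .data$y,
                                       group = .data$plaque_id),
                          fill = "grey30", colour = "black") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (µm)", y = "y (µm)", colour = NULL)
  if (!is.null(region)) {
    rdf <- tibble::tibble(x = region[, 1], y = region[, 2])
    gg <- gg + ggplot2::geom_polygon(data = rdf,
                                     ggplot2::aes(x = .data$x, y = .data$y),
                                     fill = NA, colour = "grey50",
                                     linetype = 2)
  }
  gg
}

#' Volcano plot of a marker-detection result
#'
#' @param object A `plaquemap_de` from [find_markers()].
#' @param alpha Adjusted-p significance line (default 0.05).
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.plaquemap_de <- function(object, alpha = 0.05, ...) {
  df <- tidy(object)
  df$significant <- df$p_adjusted < alpha
  ggplot2::ggplot(df, ggplot2::aes(x = .data$log2fc,
                                   y = -log10(.data$p_value),
                                   colour = .data$significant)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "firebrick",
                                            `FALSE` = "grey60")) +
    ggplot2::labs(
      x = sprintf("log2 fold change (%s / %s)",
                  attr(object, "group1"), attr(object, "group2")),
      y = "-log10 p", colour = sprintf("adj. p < %g", alpha))
}

#' Intensity histogram with classification cutoffs
#'
#' @param object A `plaquemap_pu1` from [classify_nuclei()].
#' @param bins Histogram bins (default 60).
#' @param ... Unused.
#' @return A ggplot object, faceted by batch when cutoffs were computed
#'   per sample.
#' @exportS3Method ggplot2::autoplot
autoplot.plaquemap_pu1 <- function(object, bins = 60, ...) {
  df <- tibble::as_tibble(object)
  cuts <- attr(object, "cutoffs")
  cutdf <- dplyr::bind_rows(lapply(names(cuts), function(nm) {
    tibble::tibble(batch = nm,
                   cut = c(cuts[[nm]]$low_cut, cuts[[nm]]$high_cut))
  }))
  df$batch <- if (length(cuts) > 1) df$sample_id else names(cuts)[1]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mean_intensity,
                                   fill = .data$state)) +
    ggplot2::geom_histogram(bins = bins) +
    ggplot2::geom_vline(data = cutdf,
                        ggplot2::aes(xintercept = .data$cut),
                        linetype = 2) +
    ggplot2::facet_wrap(~batch) +
    ggplot2::labs(x = "mean nuclear intensity (a.u.)", y = "nuclei",
                  fill = "state")
}

#' Module-score distributions by group
#'
#' @param scores Data frame with one score column and a grouping column.
#' @param score_col,group_col Column names.
#' @return A ggplot object.
#' @export
plot_module_scores <- function(scores, score_col, group_col) {
  ggplot2::ggplot(scores, ggplot2::aes(x = .data[[group_col]],
                                       y = .data[[score_col]])) +
    ggplot2::geom_violin(fill = "grey85") +
    ggplot2::geom_boxplot(width = 0.15, outlier.size = 0.4) +
    ggplot2::labs(x = NULL, y = score_col)
}
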