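#' Score plot (global or block level)
#'
#' Scatter of two score vectors with samples colored by diet group and
#' shaped by life stage — the view in which diet histories separate along
#' component 1 and life stages along component 2.
#'
#' @param model A \code{cpca_model}.
#' @param sample_meta Sample metadata for the fitted samples.
#' @param level \code{"global"} or a block label.
#' @param components Pair of components (default c(1, 2)).
#' @return A ggplot object.
#' @export
plot_scores <- function(model, sample_meta, level = "global",
                        components = c(1L, 2L)) {
  df <- score_plot_data(model, sample_meta, level, components)
  ev <- model$ev$global[components]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$score_x, y = .data$score_y,
                                   color = .data$diet_group,
                                   shape = .data$stage)) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.2, color = "grey60") +
    ggplot2::geom_vline(xintercept = 0, linewidth = 0.2, color = "grey60") +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(
      x = sprintf("PC%d (%.1f%%)", components[1L], 100 * ev[1L]),
      y = sprintf("PC%d (%.1f%%)", components[2L], 100 * ev[2L]),
      color = "Diet group", shape = "Stage") +
    ggplot2::theme_bw()
}

#' Correlation-loading plot with explained-variance circles
#'
#' Variables plotted at their correlations with two global components. The
#' outer circle (radius 1) marks 100% explained variance; the inner circle
#' marks 50%, drawn at radius sqrt(0.5) because explained variance is the
#' sum of the two squared correlations.
#'
#' @param cl Output of [correlation_loadings()] for two components.
#' @return A ggplot object.
#' @export
plot_correlation_loadings <- function(cl) {
  rcols <- grep("^r[0-9]+$", names(cl), value = TRUE)
  stopifnot(length(rcols) >= 2L)
  circle <- function(r) {
    th <- seq(0, 2 * pi, length.out = 200L)
    data.frame(x = r * cos(th), y = r * sin(th), r = r)
  }
  circ <- rbind(circle(1), circle(sqrt(0.5)))
  ggplot2::ggplot(cl, ggplot2::aes(x = .data[[rcols[1L]]],
                                   y = .data[[rcols[2L]]],
                                   color = .data$block)) +
    ggplot2::geom_path(data = circ,
                       ggplot2::aes(x = .data$x, y = .data$y,
                                    group = .data$r),
                       inherit.aes = FALSE, color = "grey50",
                       linewidth = 0.3) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.2, color = "grey60") +
    ggplot2::geom_vline(xintercept = 0, linewidth = 0.2, color = "grey60") +
    ggplot2::geom_point(size = 1.5, alpha = 0.8) +
    ggplot2::coord_equal(xlim = c(-1.05, 1.05), ylim = c(-1.05, 1.05)) +
    ggplot2::labs(x = paste("Correlation with", rcols[1L]),
                  y = paste("Correlation with", rcols[2L]),
                  color = "Block") +
    ggplot2::theme_bw()
}

#' Row-scaled heatmap of significant species
#'
#' Draws the cluster-grouped heatmap of cell-mean profiles (rows scaled to
#' mean 0 / sd 1) when the pheatmap package is available.
#'
#' @param hm Output of [heatmap_groups()].
#' @param filename Optional output file; NULL draws to the active device.
#' @return Invisibly, the pheatmap object (or NULL if pheatmap is not
#'   installed).
#' @export
plot_da_heatmap <- function(hm, filename = NA) {
  if (!requireNamespace("pheatmap", quietly = TRUE)) {
    message("pheatmap not installed; skipping heatmap")
    return(invisible(NULL))
  }
  ann <- data.frame(group = hm$groups,
                    row.names = names(hm$groups))
  p <- pheatmap::pheatmap(hm$scaled, cluster_rows = hm$hclust,
                          cluster_cols = FALSE, annotation_row = ann,
                          show_rownames = nrow(hm$scaled) <= 60L,
                          filename = filename, silent = TRUE)
  invisible(p)
}
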