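#' Plot a PCoA ordination
#'
#' Scatter of the first two axes, labelled with the percent of positive
#' inertia each explains, optionally coloured by a metadata grouping.
#'
#' @param object A `pcoa_ord`.
#' @param metadata Optional metadata tibble with `sample_id`.
#' @param colour Metadata column to colour by (default `"group"`).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pcoa_ord
#' @export
autoplot.pcoa_ord <- function(object, metadata = NULL, colour = "group", ...) {
  df <- object$coordinates
  if (!is.null(metadata)) {
    df <- dplyr::left_join(df, metadata, by = "sample_id")
  }
  pe <- 100 * object$proportion_explained
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$Axis1, .data$Axis2)) +
    ggplot2::labs(x = sprintf("PCo1 (%.1f%%)", pe[1]),
                  y = sprintf("PCo2 (%.1f%%)", pe[2])) +
    ggplot2::theme_minimal()
  if (!is.null(metadata) && colour %in% names(df)) {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data[[colour]]), size = 2) +
      ggplot2::stat_ellipse(ggplot2::aes(colour = .data[[colour]]))
  } else {
    p + ggplot2::geom_point(size = 2)
  }
}

#' Plot a cross-kingdom network
#'
#' Force-directed layout following the field's display conventions:
#' bacterial genera as yellow circles, fungal genera as green squares, node
#' size proportional to mean relative abundance, positive edges red and
#' negative edges blue.
#'
#' @param object A `ck_network`.
#' @param seed Layout seed.
#' @param label Label nodes with taxon names.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ck_network
#' @export
autoplot.ck_network <- function(object, seed = 1L, label = TRUE, ...) {
  if (!nrow(object$edges)) {
    return(ggplot2::ggplot() +
             ggplot2::annotate("text", 0, 0, label = "empty network") +
             ggplot2::theme_void())
  }
  g <- as_igraph(object)
  set.seed(seed)
  xy <- igraph::layout_with_fr(g)
  nodes <- object$nodes
  nodes$x <- xy[, 1]; nodes$y <- xy[, 2]
  edges <- object$edges
  edges$x <- nodes$x[match(edges$bacterial_taxon, nodes$taxon)]
  edges$y <- nodes$y[match(edges$bacterial_taxon, nodes$taxon)]
  edges$xend <- nodes$x[match(edges$fungal_taxon, nodes$taxon)]
  edges$yend <- nodes$y[match(edges$fungal_taxon, nodes$taxon)]
  p <- ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = edges,
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend,
                   yend = .data$yend, colour = .data$sign),
      alpha = 0.7) +
    ggplot2::geom_point(
      data = nodes,
      ggplot2::aes(.data$x, .data$y, size = .data$mean_abundance,
                   shape = .data$kingdom, fill = .data$kingdom)) +
    ggplot2::scale_colour_manual(values = c(positive = "red", negative = "blue")) +
    ggplot2::scale_shape_manual(values = c(bacteria = 21, fungi = 22)) +
    ggplot2::scale_fill_manual(values = c(bacteria = "gold", fungi = "forestgreen")) +
    ggplot2::labs(title = sprintf("Cross-kingdom network: %s", object$group)) +
    ggplot2::theme_void()
  if (label) {
    p <- p + ggplot2::geom_text(
      data = nodes, ggplot2::aes(.data$x, .data$y, label = .data$taxon),
      vjust = -1, size = 2.5)
  }
  p
}

#' Plot random-forest variable importance
#' @param object An `rf_report`.
#' @param n Features to display.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot rf_report
#' @export
autoplot.rf_report <- function(object, n = 20, ...) {
  df <- head(object$importance, n)
  ggplot2::ggplot(df, ggplot2::aes(.data$mean_decrease_gini,
                                   stats::reorder(.data$feature,
                                                  .data$mean_decrease_gini))) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "MeanDecreaseGini", y = NULL) +
    ggplot2::theme_minimal()
}

#' Bar plot of LDA scores
#' @param lefse Output of [lefse_biomarkers()].
#' @param lda_min Display threshold on the absolute score.
#' @return A ggplot object.
#' @export
plot_lda_scores <- function(lefse, lda_min = 2) {
  df <- lefse[!is.na(lefse$lda_score) & abs(lefse$lda_score) >= lda_min, ]
  ggplot2::ggplot(df, ggplot2::aes(.data$lda_score,
                                   stats::reorder(.data$taxon_id, .data$lda_score),
                                   fill = .data$enriched_group)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "LDA score (log10)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Bar plot of pathway reporter scores
#' @param scores Output of [reporter_scores()].
#' @param threshold Reference lines at +/- threshold.
#' @return A ggplot object.
#' @export
plot_reporter_scores <- function(scores, threshold = 1.5) {
  ggplot2::ggplot(scores, ggplot2::aes(.data$z_adjusted,
                                       stats::reorder(.data$pathway_id,
                                                      .data$z_adjusted),
                                       fill = .data$significant)) +
    ggplot2::geom_col() +
    ggplot2::geom_vline(xintercept = c(-threshold, threshold), linetype = 2) +
    ggplot2::labs(x = "ReporterScore (adjusted)", y = NULL) +
    ggplot2::theme_minimal()
}
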