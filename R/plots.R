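# Optional ggplot2 figures mirroring the standard displays of this kind of
# study: the MST over PC1/PC2 with clone-size-scaled points, the pair-
# distance class bar chart, and per-bin temporal group proportions with
# bootstrap error bars. ggplot2 is a suggested dependency; the analysis
# itself never needs it.

.need_ggplot <- function() {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("install ggplot2 to draw figures")
}

#' Plot the minimum spanning tree over the first two PCA axes
#'
#' Points are genotypes at their PC1/PC2 coordinates, sized log10-
#' proportionally to the number of isolates carrying the genotype and
#' colored by genetic group; MST edges connect them.
#'
#' @param pca A `pca_result`.
#' @param mst A `spanning_tree` built on the same individuals.
#' @param tab The labeled `isolate_table` (for group colors and clone
#'   sizes).
#' @return A ggplot object.
#' @export
plot_structure <- function(pca, mst, tab) {
  .need_ggplot()
  sc <- data.frame(strain_id = rownames(pca$scores),
                   PC1 = pca$scores[, 1], PC2 = pca$scores[, 2],
                   stringsAsFactors = FALSE)
  keys <- genotype_keys(tab)
  clone_size <- table(keys)
  sc$size <- log10(as.integer(clone_size[keys[sc$strain_id]])) + 1
  sc$group <- tab$meta$group_label[match(sc$strain_id, tab$meta$strain_id)]
  seg <- data.frame(
    x = sc$PC1[match(mst$from, sc$strain_id)],
    y = sc$PC2[match(mst$from, sc$strain_id)],
    xend = sc$PC1[match(mst$to, sc$strain_id)],
    yend = sc$PC2[match(mst$to, sc$strain_id)])
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = seg,
                          ggplot2::aes(x = .data$x, y = .data$y,
                                       xend = .data$xend,
                                       yend = .data$yend),
                          color = "grey70", linewidth = 0.3) +
    ggplot2::geom_point(data = sc,
                        ggplot2::aes(x = .data$PC1, y = .data$PC2,
                                     size = .data$size,
                                     color = .data$group)) +
    ggplot2::scale_size_identity() +
    ggplot2::labs(x = "PC1", y = "PC2", color = "genetic group") +
    ggplot2::theme_minimal()
}

#' Bar chart of clone pair distance classes
#'
#' @param classes A `distance_classes` object from [bin_distances()].
#' @return A ggplot object.
#' @export
plot_distance_classes <- function(classes) {
  .need_ggplot()
  df <- as.data.frame(classes)
  df$class <- factor(df$class, levels = df$class)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$class, y = .data$fraction)) +
    ggplot2::geom_col(fill = "grey30") +
    ggplot2::labs(x = "pair distance (km)", y = "fraction of clone pairs") +
    ggplot2::theme_minimal()
}

#' Temporal group proportions with bootstrap error bars
#'
#' @param temporal Output of [temporal_group_proportions()].
#' @return A ggplot object.
#' @export
plot_temporal <- function(temporal) {
  .need_ggplot()
  temporal$bin <- factor(temporal$bin, levels = unique(temporal$bin))
  ggplot2::ggplot(temporal,
                  ggplot2::aes(x = .data$bin, y = .data$fraction,
                               fill = .data$group_name)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.9)) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$ci_lo, ymax = .data$ci_hi),
      position = ggplot2::position_dodge(width = 0.9), width = 0.25) +
    ggplot2::labs(x = "vintage bin", y = "fraction of isolates",
                  fill = "genetic group") +
    ggplot2::theme_minimal()
}
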