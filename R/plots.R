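# Dendrogram geometry for autoplot.mirna_clusters: leaves at integer x in
# hc$order, each merge drawn as two risers and a crossbar.
dendro_segments <- function(hc) {
  n <- length(hc$order)
  x_leaf <- numeric(n)
  x_leaf[hc$order] <- seq_len(n)
  xm <- numeric(nrow(hc$merge))
  node_x <- function(j) if (j < 0) x_leaf[-j] else xm[j]
  node_h <- function(j) if (j < 0) 0 else hc$height[j]
  segs <- vector("list", nrow(hc$merge))
  for (i in seq_len(nrow(hc$merge))) {
    a <- hc$merge[i, 1]
    b <- hc$merge[i, 2]
    xa <- node_x(a)
    xb <- node_x(b)
    xm[i] <- (xa + xb) / 2
    segs[[i]] <- tibble::tibble(
      x = c(xa, xb, xa), xend = c(xa, xb, xb),
      y = c(node_h(a), node_h(b), hc$height[i]),
      yend = rep(hc$height[i], 3))
  }
  dplyr::bind_rows(segs)
}

#' Dendrogram of a miRNA target-similarity clustering
#'
#' @param object A [cluster_mirnas()] result.
#' @param label_size Leaf label text size.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mirna_clusters <- function(object, label_size = 2.5, ...) {
  hc <- object$hclust
  segs <- dendro_segments(hc)
  leaves <- tibble::tibble(x = seq_along(hc$order),
                           label = hc$labels[hc$order])
  ggplot2::ggplot(segs) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$x, xend = .data$xend,
                                       y = .data$y, yend = .data$yend)) +
    ggplot2::geom_text(data = leaves,
                       ggplot2::aes(x = .data$x, y = 0, label = .data$label),
                       angle = 90, hjust = 1.05, size = label_size) +
    ggplot2::scale_y_continuous(expand = ggplot2::expansion(mult = c(0.25, 0.05))) +
    ggplot2::labs(x = NULL, y = sprintf("%s height (%s)", object$linkage,
                                        object$metric)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank(),
                   panel.grid.major.x = ggplot2::element_blank())
}

#' Cross-channel scatter plot of screen scores
#'
#' Relative growth of the cancer channel against the fibroblast channel,
#' with the strict classification thresholds marked; points are coloured by
#' their cross-channel class when [classify_cross_channel()] has been
#' applied.
#'
#' @param scores A score table; a `cross_label` column is used if present.
#' @param inhib,stim Thresholds drawn as reference lines.
#' @return A ggplot object.
#' @export
plot_screen <- function(scores, inhib = 0.9, stim = 1.3) {
  check_columns(scores, c("norm_fib", "norm_cancer"), "Score table")
  aes <- if ("cross_label" %in% names(scores)) {
    ggplot2::aes(x = .data$norm_fib, y = .data$norm_cancer,
                 colour = .data$cross_label)
  } else {
    ggplot2::aes(x = .data$norm_fib, y = .data$norm_cancer)
  }
  ggplot2::ggplot(scores, aes) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::geom_vline(xintercept = c(inhib, stim), linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_hline(yintercept = c(inhib, stim), linetype = "dashed",
                        colour = "grey50") +
    ggplot2::labs(x = "Fibroblast relative growth",
                  y = "Cancer-cell relative growth", colour = NULL) +
    ggplot2::theme_minimal()
}
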