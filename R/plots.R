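#' Predicted-versus-actual scatter for a prognostic model
#'
#' One point per subject with the identity (perfect-prediction) line dashed,
#' the layout used to present LOOCV predictions of post-treatment scores.
#'
#' @param x A `loocv_fit` or `ensemble_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_predictions <- function(x, ...) {
  p <- if (inherits(x, c("loocv_fit", "ensemble_fit"))) x$predictions else as_tibble(x)
  ggplot2::ggplot(p, ggplot2::aes(x = .data$actual, y = .data$predicted)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey50") +
    ggplot2::geom_point(size = 2) +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "Actual post-treatment score",
                  y = "Predicted post-treatment score") +
    ggplot2::theme_minimal()
}

#' @rdname plot_predictions
#' @export
autoplot.loocv_fit <- function(x, ...) plot_predictions(x, ...)

#' @rdname plot_predictions
#' @export
autoplot.ensemble_fit <- function(x, ...) plot_predictions(x, ...)

#' Heatmap of the behavioral association matrix
#'
#' Shaded colour plot of pairwise Kendall tau-b values (red positive, blue
#' negative), measures ordered as given or by the UPGMA leaf order.
#'
#' @param assoc An [groupwise_average_tau()] result.
#' @param order_by_tree Reorder measures by UPGMA leaf order when the matrix
#'   is complete (default TRUE).
#' @return A ggplot object.
#' @export
plot_tau_heatmap <- function(assoc, order_by_tree = TRUE) {
  stopifnot(inherits(assoc, "association_matrix"))
  lev <- assoc$measures
  if (order_by_tree && !anyNA(assoc$tau)) {
    tree <- upgma(correlation_distance(assoc))
    lev <- tree$labels[tree$order]
  }
  tidy(assoc) |>
    dplyr::mutate(measure_1 = factor(.data$measure_1, levels = lev),
                  measure_2 = factor(.data$measure_2, levels = lev)) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$measure_1, y = .data$measure_2,
                                 fill = .data$tau)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white", high = "red",
                                  limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "tau-b") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}

#' @rdname plot_tau_heatmap
#' @export
autoplot.association_matrix <- function(x, ...) plot_tau_heatmap(x)

dendrogram_segments <- function(hc) {
  # leaf x-positions follow the plotting order; internal nodes sit at the mean
  # of their children's positions
  n <- length(hc$order)
  leaf_x <- numeric(n)
  leaf_x[hc$order] <- seq_len(n)
  node_x <- numeric(nrow(hc$merge))
  node_h <- hc$height
  segs <- list()
  pos <- function(id) if (id < 0) leaf_x[-id] else node_x[id]
  hgt <- function(id) if (id < 0) 0 else node_h[id]
  for (m in seq_len(nrow(hc$merge))) {
    a <- hc$merge[m, 1]; b <- hc$merge[m, 2]
    xa <- pos(a); xb <- pos(b)
    node_x[m] <- (xa + xb) / 2
    segs[[length(segs) + 1L]] <- tibble(
      x = c(xa, xb, xa), xend = c(xa, xb, xb),
      y = c(hgt(a), hgt(b), node_h[m]), yend = c(node_h[m], node_h[m], node_h[m]))
  }
  dplyr::bind_rows(segs)
}

#' Plot an UPGMA dendrogram
#'
#' @param tree An [upgma()] result.
#' @return A ggplot object.
#' @export
plot_dendrogram <- function(tree) {
  stopifnot(inherits(tree, "upgma_tree"))
  hc <- tree$hclust
  segs <- dendrogram_segments(hc)
  labs <- tibble(x = seq_along(hc$order), label = hc$labels[hc$order])
  ggplot2::ggplot(segs) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$x, xend = .data$xend,
                                       y = .data$y, yend = .data$yend)) +
    ggplot2::scale_x_continuous(breaks = labs$x, labels = labs$label) +
    ggplot2::labs(x = NULL, y = "Correlation distance") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5),
                   panel.grid.major.x = ggplot2::element_blank())
}

#' @rdname plot_dendrogram
#' @export
autoplot.upgma_tree <- function(x, ...) plot_dendrogram(x)
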