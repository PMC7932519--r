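# ggplot2 visualisations: network diagrams, permutation distributions,
# cross-valence bars, multiverse stability.

circle_layout <- function(nodes) {
  k <- length(nodes)
  ang <- pi / 2 - 2 * pi * (seq_len(k) - 1) / k
  tibble(node = nodes, x = cos(ang), y = sin(ang))
}

#' Plot an affect network
#'
#' Nodes on a circle (positive states on top), directed edges with width
#' proportional to `|b|`, solid for positive and dashed for negative
#' weights. Self-loops are annotated on the nodes.
#'
#' @param object An `affect_network`.
#' @param alpha Show only edges with `p < alpha` (`NULL` = all edges).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot affect_network
#' @export
autoplot.affect_network <- function(object, alpha = 0.05, ...) {
  edges <- tidy(object)
  if (!is.null(alpha)) edges <- edges[edges$p_value < alpha, ]
  lay <- circle_layout(object$nodes)
  auto_w <- edges$from == edges$to
  loops <- edges[auto_w, ]
  edges <- edges[!auto_w & edges$b != 0, ]
  edges <- edges %>%
    left_join(lay, by = c("from" = "node")) %>%
    rename(x0 = "x", y0 = "y") %>%
    left_join(lay, by = c("to" = "node"))
  shrink <- 0.12
  nodes_df <- lay %>%
    mutate(valence = affect_valence()[.data$node],
           auto = ifelse(.data$node %in% loops$from,
                         sprintf("%.2f", loops$b[match(.data$node,
                                                       loops$from)]), ""))
  p <- ggplot2::ggplot()
  if (nrow(edges) > 0) {
    p <- p + ggplot2::geom_curve(
      data = edges,
      ggplot2::aes(x = .data$x0 * (1 - shrink) + .data$x * shrink,
                   y = .data$y0 * (1 - shrink) + .data$y * shrink,
                   xend = .data$x * (1 - shrink) + .data$x0 * shrink,
                   yend = .data$y * (1 - shrink) + .data$y0 * shrink,
                   linewidth = abs(.data$b),
                   linetype = .data$b < 0),
      curvature = 0.15,
      arrow = ggplot2::arrow(length = ggplot2::unit(8, "pt"),
                             type = "closed"))
  }
  p +
    ggplot2::geom_point(data = nodes_df,
                        ggplot2::aes(.data$x, .data$y,
                                     colour = .data$valence), size = 14) +
    ggplot2::geom_text(data = nodes_df,
                       ggplot2::aes(.data$x, .data$y, label = .data$node),
                       vjust = -2.6, size = 3.4) +
    ggplot2::geom_text(data = nodes_df,
                       ggplot2::aes(.data$x, .data$y, label = .data$auto),
                       size = 2.8) +
    ggplot2::scale_linewidth(range = c(0.3, 1.8), guide = "none") +
    ggplot2::scale_linetype_manual(values = c(`FALSE` = "solid",
                                              `TRUE` = "dashed"),
                                   guide = "none") +
    ggplot2::scale_colour_manual(values = c(positive = "#7fbf7f",
                                            negative = "#e08f8f")) +
    ggplot2::coord_equal(xlim = c(-1.45, 1.45), ylim = c(-1.35, 1.35)) +
    ggplot2::theme_void() +
    ggplot2::labs(title = sprintf("Affect network: %s", object$group),
                  colour = NULL)
}

#' Plot a permutation-test distribution
#'
#' Histogram of the permuted metric differences with the observed
#' difference marked.
#'
#' @param object A `permutation_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot permutation_result
#' @export
autoplot.permutation_result <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$difference)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70", colour = "grey40") +
    ggplot2::geom_vline(xintercept = object$observed, colour = "firebrick",
                        linewidth = 1) +
    ggplot2::labs(
      title = sprintf("%s: permuted group differences", object$metric),
      subtitle = sprintf("observed = %.3f, p = %.3f (%d permutations)",
                         object$observed, object$p_value, object$n_perm),
      x = sprintf("difference (%s - %s)", object$groups[2],
                  object$groups[1]),
      y = "count") +
    ggplot2::theme_minimal()
}

#' Plot the descriptive metric comparison
#'
#' Grouped bars of each metric's value per group (the cross-valence
#' panel style of summary).
#'
#' @param object A `network_comparison`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot network_comparison
#' @export
autoplot.network_comparison <- function(object, ...) {
  tb <- object$descriptives %>%
    tidyr::pivot_longer(c("value_a", "value_b"), names_to = "which",
                        values_to = "value") %>%
    mutate(group = ifelse(.data$which == "value_a", object$groups[1],
                          object$groups[2]))
  ggplot2::ggplot(tb, ggplot2::aes(.data$metric, .data$value,
                                   fill = .data$group)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_fill_manual(values = setNames(c("grey75", "grey25"),
                                                 object$groups)) +
    ggplot2::labs(x = NULL, y = "summed |b|", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30,
                                                       hjust = 1))
}

#' Plot multiverse feature stability
#'
#' @param object A `multiverse_report`.
#' @param min_stability Hide features rarer than this fraction.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot multiverse_report
#' @export
autoplot.multiverse_report <- function(object, min_stability = 0, ...) {
  tb <- object$features
  tb <- tb[tb$stability >= min_stability, ]
  ggplot2::ggplot(tb, ggplot2::aes(.data$stability,
                                   stats::reorder(.data$feature,
                                                  .data$stability))) +
    ggplot2::geom_col(fill = "grey40") +
    ggplot2::labs(x = "fraction of assignments with feature", y = NULL) +
    ggplot2::xlim(0, 1) +
    ggplot2::theme_minimal()
}

#' @export
plot.affect_network <- function(x, ...) print(autoplot(x, ...))

#' @export
plot.permutation_result <- function(x, ...) print(autoplot(x, ...))

#' @export
plot.network_comparison <- function(x, ...) print(autoplot(x, ...))
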