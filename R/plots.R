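#' Volcano plot of a differential-expression result
#'
#' @param object a `de_result` from [run_de()].
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.de_result <- function(object, ...) {
  d <- object$full |>
    mutate(significant = .data$probeset_id %in% object$sig$probeset_id,
           log2_fold = sign(.data$fold_change) *
             log2(pmax(1, abs(.data$fold_change))))
  ggplot2::ggplot(d, ggplot2::aes(.data$log2_fold,
                                  -log10(pmax(.data$p_value, 1e-300)),
                                  colour = .data$significant)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "log2 fold change (tumor vs normal)",
                  y = "-log10 p", colour = "significant",
                  title = sprintf("%s differential expression",
                                  object$species)) +
    ggplot2::theme_minimal()
}

#' Forest plot of a per-gene survival screen
#'
#' Hazard ratios with their Wald intervals, by gene and treatment arm;
#' finite fits only.
#'
#' @param object a `cox_screen` from [screen_genes()].
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.cox_screen <- function(object, ...) {
  d <- filter(object$fits, is.finite(.data$se))
  ggplot2::ggplot(d, ggplot2::aes(.data$hazard_ratio, .data$gene_symbol,
                                  colour = .data$arm)) +
    ggplot2::geom_vline(xintercept = 1, linetype = 2, colour = "grey40") +
    ggplot2::geom_pointrange(
      ggplot2::aes(xmin = .data$ci_low, xmax = .data$ci_high),
      position = ggplot2::position_dodge(width = 0.5), fatten = 1.5) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "hazard ratio per expression unit (log scale)",
                  y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot an expanded interaction subnetwork
#'
#' Seeds, the added nodes and the induced edges (width by confidence), laid
#' out with a force-directed algorithm; deterministic given the layout seed.
#'
#' @param object an `expansion_result` from [expand_network()].
#' @param layout_seed seed for the layout (default 1).
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.expansion_result <- function(object, layout_seed = 1, ...) {
  g <- igraph::graph_from_data_frame(
    object$edges[c("node_a", "node_b")], directed = FALSE,
    vertices = data.frame(name = object$members$node))
  xy <- with_seed(layout_seed, igraph::layout_with_fr(g))
  nodes <- object$members |>
    mutate(x = xy[, 1], y = xy[, 2])
  segs <- object$edges |>
    left_join(select(nodes, "node", xa = "x", ya = "y"),
              by = c(node_a = "node")) |>
    left_join(select(nodes, "node", xb = "x", yb = "y"),
              by = c(node_b = "node"))
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = segs,
      ggplot2::aes(x = .data$xa, y = .data$ya, xend = .data$xb,
                   yend = .data$yb, linewidth = .data$confidence),
      colour = "grey70") +
    ggplot2::scale_linewidth(range = c(0.2, 1.2), guide = "none") +
    ggplot2::geom_point(
      data = nodes,
      ggplot2::aes(.data$x, .data$y, colour = .data$is_seed), size = 3) +
    ggplot2::geom_text(
      data = nodes,
      ggplot2::aes(.data$x, .data$y, label = .data$node),
      vjust = -1, size = 2.8) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "firebrick",
                                            `FALSE` = "steelblue"),
                                 labels = c(`TRUE` = "seed",
                                            `FALSE` = "added"),
                                 name = NULL) +
    ggplot2::theme_void()
}

#' Bar chart of the concordance filtering cascade
#'
#' @param cascade the tibble returned by [summarize_cascade()] (or the
#'   `cascade` element of a pipeline result).
#' @return a ggplot.
#' @export
plot_cascade <- function(cascade) {
  d <- mutate(cascade, stage = factor(.data$stage, levels = rev(.data$stage)))
  ggplot2::ggplot(d, ggplot2::aes(.data$count, .data$stage)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = .data$count),
                       hjust = -0.1, size = 3) +
    ggplot2::labs(x = "count", y = NULL) +
    ggplot2::theme_minimal()
}
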