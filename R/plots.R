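# ggplot2 displays for graphs, fits and stability reports.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a mixed graph
#'
#' Nodes are laid out with a force-directed layout (or left-to-right by tier
#' when a [knowledge()] object is supplied); fully directed edges are drawn in
#' a different colour from circle-marked and bidirected edges, mirroring the
#' usual display convention without attaching semantics to colour.
#'
#' @param object A `mixed_graph`.
#' @param k Optional [knowledge()] used to arrange tiers left-to-right.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mixed_graph
#' @export
autoplot.mixed_graph <- function(object, k = NULL, ...) {
  ed <- tidy(object)
  ig <- igraph::make_empty_graph(n = length(object$nodes), directed = FALSE)
  ig <- igraph::set_vertex_attr(ig, "name", value = object$nodes)
  if (nrow(ed)) {
    ig <- igraph::add_edges(ig, rbind(match(ed$from, object$nodes),
                                      match(ed$to, object$nodes)))
  }
  set.seed(42)  # layout only
  xy <- igraph::layout_with_fr(ig)
  if (!is.null(k) && length(k$tiers)) {
    tier <- vapply(object$nodes, function(v) {
      t <- tier_of(k, v); if (is.na(t)) 0L else t
    }, integer(1))
    xy[, 1] <- tier + stats::runif(length(tier), -0.15, 0.15)
  }
  nodes <- tibble::tibble(name = object$nodes, x = xy[, 1], y = xy[, 2])
  p <- ggplot2::ggplot()
  if (nrow(ed)) {
    seg <- dplyr::left_join(ed, nodes, by = c("from" = "name"))
    seg <- dplyr::left_join(seg, nodes, by = c("to" = "name"),
                            suffix = c("", "end"))
    seg$directed <- ifelse(seg$type == "-->", "directed", "possible/latent")
    p <- p + ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend,
                   yend = .data$yend, colour = .data$directed),
      arrow = ggplot2::arrow(length = ggplot2::unit(0.18, "cm"), type = "closed"),
      linewidth = 0.6) +
      ggplot2::scale_colour_manual(
        values = c(directed = "forestgreen", `possible/latent` = "steelblue"),
        name = NULL)
  }
  p + ggplot2::geom_label(data = nodes,
                          ggplot2::aes(x = .data$x, y = .data$y, label = .data$name),
                          size = 3) +
    ggplot2::theme_void()
}

#' Plot SEM effect sizes
#'
#' Dot-and-whisker display of raw path and covariance estimates with
#' approximate 95% intervals.
#'
#' @param object A `sem_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot sem_fit
#' @export
autoplot.sem_fit <- function(object, ...) {
  est <- object$estimates
  est <- est[est$op != "variance", , drop = FALSE]
  ggplot2::ggplot(est, ggplot2::aes(x = .data$estimate,
                                    y = stats::reorder(.data$term, .data$estimate),
                                    colour = .data$op)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$estimate - 1.96 * .data$std.error,
                   xmax = .data$estimate + 1.96 * .data$std.error),
      height = 0.2, na.rm = TRUE) +
    ggplot2::labs(x = "raw effect size", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot edge-stability concordance
#'
#' @param object A `stability_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot stability_report
#' @export
autoplot.stability_report <- function(object, ...) {
  tab <- object$table
  tab$pair <- paste(tab$from, "-", tab$to)
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$percent, y = .data$pair)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(~feature) +
    ggplot2::labs(x = "% concordant replicates", y = NULL) +
    ggplot2::theme_minimal()
}
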