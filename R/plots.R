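#' Plot DEG fold changes by co-expression pathway
#'
#' Scatter of the two step log2 ratios, coloured by pathway label; the fold
#' and significance gates shape the visible cross pattern.
#'
#' @param object A labelled `deg_table`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.deg_table <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(
    x = log2(.data$ratio_step1), y = log2(.data$ratio_step2),
    colour = .data$pathway
  )) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::geom_hline(yintercept = 0, linetype = 3) +
    ggplot2::geom_vline(xintercept = 0, linetype = 3) +
    ggplot2::labs(
      x = "log2 ratio, step 1 (vs baseline)",
      y = "log2 ratio, step 2 (vs baseline)",
      colour = "pathway"
    ) +
    ggplot2::theme_minimal()
}

#' Heat map of TF-pathway associations
#'
#' Tiles of -log10(hypergeometric p), rows and columns in dendrogram leaf
#' order when [cluster_associations()] has been applied.
#'
#' @param object A `tf_association`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.tf_association <- function(object, ...) {
  df <- object$table %>%
    mutate(
      tf = factor(.data$tf, levels = object$row_order),
      pathway = factor(.data$pathway, levels = object$col_order)
    )
  ggplot2::ggplot(df, ggplot2::aes(.data$pathway, .data$tf, fill = .data$neg_log10_p)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "steelblue", high = "red") +
    ggplot2::labs(x = "co-expression pathway", y = "TF", fill = "-log10 p") +
    ggplot2::theme_minimal()
}

#' Heat map of chromatin-state cluster vs pathway Pearson residuals
#'
#' @param object An `integration_table`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.integration_table <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$pathway, .data$cluster, fill = .data$residual)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "steelblue", mid = "grey95", high = "gold") +
    ggplot2::labs(x = "co-expression pathway", y = "state transition cluster", fill = "Pearson\nresidual") +
    ggplot2::theme_minimal()
}

#' Plot a reduced gene regulatory network
#'
#' Fruchterman-Reingold layout (deterministic under a fixed seed) with nodes
#' coloured by pathway segment and shaped by role, edges grey by provenance.
#'
#' @param object A `grn`.
#' @param seed Layout seed.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.grn <- function(object, seed = 1, ...) {
  xy <- with_seed(seed, igraph::layout_with_fr(object$graph))
  nodes <- object$nodes %>%
    mutate(x = xy[match(.data$id, igraph::V(object$graph)$name), 1],
           y = xy[match(.data$id, igraph::V(object$graph)$name), 2])
  edges <- object$edges %>%
    left_join(nodes %>% select("id", x0 = "x", y0 = "y"), by = c(from = "id")) %>%
    left_join(nodes %>% select("id", x1 = "x", y1 = "y"), by = c(to = "id"))
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = edges,
      ggplot2::aes(x = .data$x0, y = .data$y0, xend = .data$x1, yend = .data$y1,
                   linetype = .data$provenance),
      colour = "grey70", linewidth = 0.3
    ) +
    ggplot2::geom_point(
      data = nodes,
      ggplot2::aes(.data$x, .data$y, colour = .data$pathway, shape = .data$role),
      size = 2
    ) +
    ggplot2::theme_void()
}

#' Bar chart of the chromatin-state transition-cluster census
#'
#' @param trajectories A `state_trajectories` object.
#' @param top Show the `top` most populated clusters.
#' @return A ggplot object.
#' @export
plot_state_census <- function(trajectories, top = 20) {
  census <- cluster_census(trajectories) %>% head(top)
  ggplot2::ggplot(census, ggplot2::aes(
    x = stats::reorder(.data$cluster, .data$n_genes), y = .data$n_genes
  )) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = "state transition cluster", y = "genes") +
    ggplot2::theme_minimal()
}
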