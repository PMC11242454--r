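# broom-style tidiers and ggplot2 autoplot methods for the package's
# result objects.

#' @describeIn kmeans_cluster Tidy a `growth_clusters` object into a plain
#'   tibble of cultivar-to-cluster assignments.
#' @param x A `growth_clusters` object.
#' @param ... Unused.
#' @export
tidy.growth_clusters <- function(x, ...) {
  tibble(cultivar = x$cultivar, cluster = x$cluster)
}

#' @describeIn kmeans_cluster One-row summary of a clustering (k, method,
#'   and total within-cluster sum of squares where available).
#' @export
glance.growth_clusters <- function(x, ...) {
  fit <- attr(x, "fit")
  tibble(
    k = attr(x, "k"),
    method = attr(x, "method"),
    tot_withinss = if (inherits(fit, "kmeans")) fit$tot.withinss else NA_real_
  )
}

#' @describeIn assembly_analysis Return the pairwise table as a plain
#'   tibble.
#' @param x An `assembly_result` object.
#' @param ... Unused.
#' @export
tidy.assembly_result <- function(x, ...) {
  as_tibble(unclass(x)[c("sample_a", "sample_b", "group", "bmntd",
                         "bnti", "rcbray", "process")])
}

#' @describeIn assembly_analysis One row per group with process fractions
#'   in wide form.
#' @export
glance.assembly_result <- function(x, ...) {
  fr <- summarize_fractions(x)
  tidyr::pivot_wider(
    dplyr::select(fr, "group", "process", "fraction"),
    names_from = "process", values_from = "fraction"
  )
}

#' @describeIn build_network Tidy the retained edges of a network.
#' @param x An `assoc_network` object.
#' @param ... Unused.
#' @export
tidy.assoc_network <- function(x, ...) {
  ed <- x$edges[x$edges$keep, , drop = FALSE]
  as_tibble(ed[setdiff(names(ed), "keep")])
}

#' @describeIn build_network One-row topology summary (the comparison
#'   metrics).
#' @export
glance.assoc_network <- function(x, ...) {
  x$properties
}

#' @describeIn core_microbiome Per-taxon core membership rows.
#' @param x A `core_partition` object.
#' @param ... Unused.
#' @export
tidy.core_partition <- function(x, ...) {
  tidyr::unnest(
    as_tibble(unclass(x)[c("region", "read_proportion", "taxa")]),
    "taxa"
  )
}

#' @describeIn beta_nti Long tibble of per-pair betaNTI values.
#' @param x A `beta_nti` object.
#' @param ... Unused.
#' @export
tidy.beta_nti <- function(x, ...) {
  ij <- which(upper.tri(x$bnti), arr.ind = TRUE)
  ids <- rownames(x$bnti)
  tibble(
    sample_a = ids[ij[, 1]], sample_b = ids[ij[, 2]],
    bmntd = x$bmntd[ij], bnti = x$bnti[ij],
    degenerate = x$degenerate[ij]
  )
}

#' Stacked-bar plot of assembly-process fractions per group
#'
#' @param object An `assembly_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.assembly_result <- function(object, ...) {
  fr <- summarize_fractions(object)
  ggplot2::ggplot(fr, ggplot2::aes(x = .data$group, y = .data$fraction,
                                   fill = .data$process)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "Fraction of sample pairs",
                  fill = "Assembly process") +
    ggplot2::theme_minimal()
}

#' Force-directed plot of an association network
#'
#' Fruchterman-Reingold layout; edge colour encodes correlation sign,
#' node size mean relative abundance, thick outline marks hubs.
#'
#' @param object An `assoc_network`.
#' @param seed Layout seed.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.assoc_network <- function(object, seed = 1, ...) {
  g <- object$graph
  xy <- withr::with_seed(seed, igraph::layout_with_fr(g))
  nd <- object$nodes
  nd$x <- xy[, 1]
  nd$y <- xy[, 2]
  ed <- tidy.assoc_network(object)
  ed$x <- nd$x[match(ed$from, nd$node)]
  ed$y <- nd$y[match(ed$from, nd$node)]
  ed$xend <- nd$x[match(ed$to, nd$node)]
  ed$yend <- nd$y[match(ed$to, nd$node)]
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = ed,
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend,
                   yend = .data$yend, colour = .data$sign),
      alpha = 0.6
    ) +
    ggplot2::geom_point(
      data = nd,
      ggplot2::aes(x = .data$x, y = .data$y,
                   size = .data$mean_rel_abundance,
                   shape = .data$hub),
      fill = "grey30"
    ) +
    ggplot2::scale_colour_manual(values = c(positive = "darkgreen",
                                            negative = "firebrick")) +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 16, `TRUE` = 21)) +
    ggplot2::theme_void() +
    ggplot2::labs(colour = "Edge sign", size = "Mean rel. abundance",
                  shape = "Hub")
}

#' Diagnostic curve for the choice of k
#'
#' @param object A `k_selection` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.k_selection <- function(object, ...) {
  yvar <- if (object$criterion == "wss") "wss" else "silhouette"
  ggplot2::ggplot(object$curve,
                  ggplot2::aes(x = .data$k, y = .data[[yvar]])) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$k, linetype = 2) +
    ggplot2::labs(y = yvar, title = sprintf("Selected k = %d", object$k)) +
    ggplot2::theme_minimal()
}

#' Scatter plot of a PCoA ordination
#'
#' @param ordination Result of [pcoa_ordination()].
#' @param metadata Optional data frame with `sample_id` and the colour
#'   column.
#' @param colour Name of the metadata column to colour by.
#' @return A ggplot object.
#' @export
plot_pcoa <- function(ordination, metadata = NULL, colour = NULL) {
  co <- ordination$coordinates
  rel <- ordination$rel_eig
  if (!is.null(metadata) && !is.null(colour)) {
    co <- dplyr::left_join(co, metadata, by = "sample_id")
  }
  p <- ggplot2::ggplot(co, ggplot2::aes(x = .data$Axis.1, y = .data$Axis.2))
  p <- if (!is.null(colour)) {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data[[colour]]), size = 2)
  } else {
    p + ggplot2::geom_point(size = 2)
  }
  p +
    ggplot2::labs(
      x = sprintf("Axis 1 (%.1f%%)", 100 * rel[1]),
      y = sprintf("Axis 2 (%.1f%%)", 100 * rel[2])
    ) +
    ggplot2::theme_minimal()
}
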