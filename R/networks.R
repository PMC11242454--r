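# Genus-level compositional co-occurrence networks: clr transform, Pearson
# sparsification (|r|, t-test p, local FDR), greedy modularity modules,
# eigenvector-centrality hubs, and the topology/robustness metrics used to
# compare networks across groups.

#' Agglomerate a feature table at the genus level
#'
#' Counts are summed over taxa sharing a genus; taxa unclassified at the
#' genus rank are pooled under `"U. <deepest classified rank>"` (e.g.
#' `"U. Family_03"`), so reads are conserved.
#'
#' @param table Feature table of counts.
#' @param taxonomy Data frame `taxon_id`, `domain`, ..., `genus`;
#'   missing ranks are `NA`.
#' @return Genus-level feature table (tibble).
#' @export
agglomerate_genus <- function(table, taxonomy) {
  mat <- ft_matrix(table)
  idx <- match(colnames(mat), taxonomy$taxon_id)
  if (anyNA(idx)) {
    abort(paste0("Taxa missing from taxonomy: ",
                 paste(colnames(mat)[is.na(idx)], collapse = ", ")))
  }
  tx <- taxonomy[idx, , drop = FALSE]
  ranks <- intersect(c("genus", "family", "order", "class", "phylum", "domain"),
                     names(tx))
  label <- rep(NA_character_, nrow(tx))
  for (i in seq_len(nrow(tx))) {
    if (!is.na(tx$genus[i])) {
      label[i] <- tx$genus[i]
    } else {
      deeper <- ranks[-1]
      hit <- deeper[which(!is.na(as.character(tx[i, deeper])))[1]]
      if (is.na(hit)) abort(sprintf("Taxon `%s` has an empty lineage.",
                                    tx$taxon_id[i]))
      label[i] <- paste0("U. ", tx[[hit]][i])
    }
  }
  agg <- t(rowsum(t(mat), group = label))
  ft_tibble(agg)
}

#' Centered log-ratio transform
#'
#' Per sample: `x' = ln(x + pseudocount) - mean(ln(x + pseudocount))`, so
#' every row has mean exactly 0. Addresses the compositionality bias of
#' correlating relative abundances.
#'
#' @param table Feature table of counts (>= 0).
#' @param pseudocount Added before the log (default 1).
#' @return Numeric matrix (samples x taxa) of clr values.
#' @export
clr_transform <- function(table, pseudocount = 1) {
  mat <- ft_matrix(table)
  lx <- log(mat + pseudocount)
  lx - rowMeans(lx)
}

# Empirical-null local false discovery rate on z-transformed correlations:
# a two-component mixture where the null component is a Gaussian fitted by
# central matching (median / MAD) and the marginal density is estimated by
# kernel smoothing. Requires a reasonably large family of tests.
#' @noRd
lfdr_empirical_null <- function(z) {
  mu0 <- median(z)
  s0 <- stats::mad(z)
  if (s0 <= 0) s0 <- sd(z)
  if (!is.finite(s0) || s0 <= 0) return(rep(0, length(z)))
  f <- density(z, n = 1024, cut = 4)
  fz <- approx(f$x, f$y, xout = z, rule = 2)$y
  f0_at_mode <- approx(f$x, f$y, xout = mu0, rule = 2)$y
  pi0 <- min(1, f0_at_mode / dnorm(mu0, mu0, s0))
  pmin(1, pi0 * dnorm(z, mu0, s0) / pmax(fz, 1e-300))
}

#' Pearson correlation edges with conjunctive sparsification
#'
#' Computes Pearson correlations between all taxon pairs of a clr matrix
#' and keeps an edge only if all enabled criteria hold: `|r| >= r_min`,
#' two-sided t-test `p <= alpha` (with `t = r sqrt((n-2)/(1-r^2))`), and
#' local FDR `<= lfdr_max`. The local FDR uses an empirical-null mixture
#' on the Fisher-z correlations; with fewer than 200 tests it falls back
#' to Benjamini-Hochberg q-values (a message notes the fallback).
#'
#' @param clr Matrix of clr-transformed abundances (samples x taxa), as
#'   returned by [clr_transform()].
#' @param r_min Absolute correlation threshold (default 0.3).
#' @param alpha t-test significance level (0.0001 for the bacterial
#'   workflow, 0.05 for fungal).
#' @param lfdr_max Local FDR ceiling (default 0.2); `NULL` disables.
#' @return Tibble of all tested pairs: `from`, `to`, `r`, `p`, `lfdr`,
#'   `sign`, `keep`. Zero-variance taxa are excluded with a warning.
#' @export
correlation_edges <- function(clr, r_min = 0.3, alpha = 0.0001,
                              lfdr_max = 0.2) {
  clr <- as.matrix(clr)
  n <- nrow(clr)
  if (n < 4) abort("Need at least 4 samples.")
  if (alpha <= 0 || alpha >= 1) abort("`alpha` must be in (0, 1).")
  v <- apply(clr, 2, var)
  if (any(v == 0)) {
    warn(paste0("Excluding zero-variance taxa: ",
                paste(colnames(clr)[v == 0], collapse = ", ")))
    clr <- clr[, v > 0, drop = FALSE]
  }
  taxa <- colnames(clr)
  if (length(taxa) < 2) abort("Fewer than two variable taxa.")

  R <- cor(clr)
  ij <- which(upper.tri(R), arr.ind = TRUE)
  r <- R[ij]
  r_t <- pmin(pmax(r, -1 + 1e-15), 1 - 1e-15)
  tstat <- r_t * sqrt((n - 2) / (1 - r_t^2))
  p <- 2 * pt(-abs(tstat), df = n - 2)

  if (length(r) >= 200) {
    z <- atanh(r_t) * sqrt(n - 3)
    lfdr <- lfdr_empirical_null(z)
  } else {
    message("Fewer than 200 correlation tests; using Benjamini-Hochberg ",
            "q-values in place of the empirical-null local FDR.")
    lfdr <- p.adjust(p, method = "BH")
  }

  keep <- abs(r) >= r_min & p <= alpha
  if (!is.null(lfdr_max)) keep <- keep & lfdr <= lfdr_max

  tibble(
    from = taxa[ij[, 1]], to = taxa[ij[, 2]],
    r = r, p = p, lfdr = lfdr,
    sign = ifelse(r >= 0, "positive", "negative"),
    keep = keep
  )
}

#' @noRd
edges_to_graph <- function(edges) {
  kept <- edges[edges$keep, , drop = FALSE]
  g <- igraph::graph_from_data_frame(
    kept[c("from", "to")], directed = FALSE,
    vertices = unique(c(kept$from, kept$to))
  )
  igraph::E(g)$weight <- abs(kept$r)
  igraph::E(g)$r <- kept$r
  g
}

#' Detect modules by greedy modularity maximisation
#'
#' Clauset-Newman-Moore agglomeration on absolute edge weights
#' ([igraph::cluster_fast_greedy]), applied to the network's connected
#' part. Q >= 0.4 flags a modular topology.
#'
#' @param network An `assoc_network` (see [build_network()]) or an igraph
#'   graph with a `weight` edge attribute.
#' @return List with `membership` (named integer vector), `modularity`
#'   (`NA` for an empty network), `n_modules`, and `modular` (Q >= 0.4).
#' @export
detect_modules <- function(network) {
  g <- if (inherits(network, "assoc_network")) network$graph else network
  if (igraph::ecount(g) == 0) {
    return(list(membership = setNames(integer(0), character(0)),
                modularity = NA_real_, n_modules = 0L, modular = NA))
  }
  cl <- igraph::cluster_fast_greedy(g, weights = abs(igraph::E(g)$weight))
  mem <- igraph::membership(cl)
  q <- igraph::modularity(g, mem, weights = abs(igraph::E(g)$weight))
  list(membership = setNames(as.integer(mem), names(mem)),
       modularity = q, n_modules = length(unique(mem)), modular = q >= 0.4)
}

#' Hub taxa by eigenvector centrality
#'
#' Eigenvector centrality is computed on the absolute-weight adjacency of
#' the largest connected component(s) (ties share the honour); hubs are
#' the scored nodes strictly above the `quantile` empirical quantile of
#' the centrality distribution. When every scored node ties (e.g. a
#' regular ring) the hub set is empty.
#'
#' @param network An `assoc_network` or igraph graph.
#' @param quantile Centrality quantile a hub must exceed (default 0.95).
#' @return Character vector of hub node names (possibly empty). The full
#'   centrality vector is attached as attribute `"centrality"`.
#' @export
hub_taxa <- function(network, quantile = 0.95) {
  g <- if (inherits(network, "assoc_network")) network$graph else network
  if (igraph::ecount(g) == 0) {
    return(structure(character(0), centrality = numeric(0)))
  }
  comp <- igraph::components(g)
  biggest <- which(comp$csize == max(comp$csize))
  keep <- comp$membership %in% biggest
  sub <- igraph::induced_subgraph(g, which(keep))
  cent <- igraph::eigen_centrality(
    sub, weights = abs(igraph::E(sub)$weight)
  )$vector
  thr <- stats::quantile(cent, quantile, names = FALSE)
  # strict comparison with a numeric guard so exact ties (e.g. regular
  # graphs) never promote nodes through eigensolver jitter
  structure(names(cent)[cent > thr + 1e-9], centrality = cent)
}

#' @noRd
natural_connectivity <- function(adj) {
  if (nrow(adj) == 0) return(0)
  ev <- eigen(adj, symmetric = TRUE, only.values = TRUE)$values
  mx <- max(ev)
  mx + log(mean(exp(ev - mx)))
}

#' Topology metrics of an association network
#'
#' Computes the comparison metrics of the workflow: components are counted
#' over the full node universe (isolated genera are singleton components);
#' the clustering coefficient is the mean local transitivity over nodes of
#' degree >= 2; robustness is the natural connectivity
#' `ln((1/N) sum exp(lambda_i))` of the unweighted adjacency over the
#' whole node universe (isolated genera contribute zero eigenvalues),
#' normalised by `N - ln(N)`, so networks over a shared genus universe
#' are comparable regardless of how many nodes end up connected (the raw
#' value is also returned); average path length is over reachable pairs
#' of connected nodes.
#'
#' @param network An `assoc_network` or igraph graph.
#' @param node_universe Character vector of all candidate nodes (>= the
#'   connected nodes); defaults to the network's own node set.
#' @return One-row tibble: `n_nodes`, `n_edges`, `n_components`,
#'   `clustering_coefficient`, `modularity`, `positive_edge_pct`,
#'   `edge_density`, `robustness`, `robustness_raw`,
#'   `average_path_length`, `n_modules`.
#' @export
network_properties <- function(network, node_universe = NULL) {
  g <- if (inherits(network, "assoc_network")) network$graph else network
  if (is.null(node_universe) && inherits(network, "assoc_network")) {
    node_universe <- network$node_universe
  }
  nodes <- igraph::V(g)$name
  node_universe <- node_universe %||% nodes
  if (length(node_universe) == 0) abort("Empty node universe.")
  if (!all(nodes %in% node_universe)) {
    abort("`node_universe` must contain every network node.")
  }

  n_edges <- igraph::ecount(g)
  comp <- igraph::components(g)
  n_components <- comp$no + (length(node_universe) - length(nodes))

  deg <- igraph::degree(g)
  local_cc <- igraph::transitivity(g, type = "local", isolates = "NaN")
  cc <- if (any(deg >= 2)) mean(local_cc[deg >= 2], na.rm = TRUE) else NA_real_

  mod <- detect_modules(g)

  pos_pct <- if (n_edges > 0) 100 * mean(igraph::E(g)$r > 0) else NA_real_
  n_u <- length(node_universe)
  density <- if (n_u >= 2) n_edges / choose(n_u, 2) else NA_real_

  adj <- igraph::as_adjacency_matrix(g, sparse = FALSE)
  adj <- (adj != 0) + 0
  # embed into the universe: isolated genera are all-zero rows/columns
  adj_u <- matrix(0, n_u, n_u, dimnames = list(node_universe, node_universe))
  if (length(nodes) > 0) adj_u[nodes, nodes] <- adj
  nc_raw <- natural_connectivity(adj_u)
  n_conn <- length(nodes)
  nc_norm <- if (n_u > 1) nc_raw / (n_u - log(n_u)) else NA_real_

  apl <- if (n_edges > 0) {
    # hop counts, not correlation weights
    igraph::mean_distance(g, weights = NA, directed = FALSE,
                          unconnected = TRUE)
  } else {
    NA_real_
  }

  tibble(
    n_nodes = n_conn, n_edges = n_edges, n_components = n_components,
    clustering_coefficient = cc, modularity = mod$modularity,
    positive_edge_pct = pos_pct, edge_density = density,
    robustness = nc_norm, robustness_raw = nc_raw,
    average_path_length = apl, n_modules = mod$n_modules
  )
}

#' Build a genus-level association network
#'
#' Chains genus agglomeration (optional), clr transformation, correlation
#' sparsification, module detection and hub identification into one
#' network object.
#'
#' @param table Feature table of counts (ASV- or genus-level).
#' @param taxonomy Optional taxonomy for genus agglomeration; `NULL` if
#'   `table` is already genus-level.
#' @param r_min,alpha,lfdr_max Sparsification thresholds, see
#'   [correlation_edges()].
#' @param pseudocount clr pseudocount.
#' @param hub_quantile Centrality quantile for hubs.
#' @return An `assoc_network` object: list with `graph`, `edges` (all
#'   tested pairs), `nodes` (connected nodes with module, hub flag and
#'   mean relative abundance), `node_universe`, `modules`, `hubs`, and
#'   `properties`.
#' @export
build_network <- function(table, taxonomy = NULL, r_min = 0.3,
                          alpha = 0.0001, lfdr_max = 0.2, pseudocount = 1,
                          hub_quantile = 0.95) {
  if (!is.null(taxonomy)) table <- agglomerate_genus(table, taxonomy)
  mat <- ft_matrix(table)
  universe <- colnames(mat)[colSums(mat) > 0]
  # never-observed taxa would enter the clr as constant-log columns that
  # track the row mean; they are not part of this group's community
  mat <- mat[, universe, drop = FALSE]
  clr <- clr_transform(mat, pseudocount = pseudocount)
  edges <- suppressMessages(
    correlation_edges(clr, r_min = r_min, alpha = alpha, lfdr_max = lfdr_max)
  )
  g <- edges_to_graph(edges)
  mod <- detect_modules(g)
  hubs <- hub_taxa(g, quantile = hub_quantile)

  rel <- mat / pmax(rowSums(mat), 1)
  mean_ab <- colMeans(rel)
  nodes <- tibble(
    node = igraph::V(g)$name,
    degree = unname(igraph::degree(g)),
    module = unname(mod$membership[igraph::V(g)$name]),
    hub = igraph::V(g)$name %in% hubs,
    mean_rel_abundance = unname(mean_ab[igraph::V(g)$name])
  )
  net <- structure(
    list(graph = g, edges = edges, nodes = nodes, node_universe = universe,
         modules = mod, hubs = hubs,
         params = list(r_min = r_min, alpha = alpha, lfdr_max = lfdr_max,
                       pseudocount = pseudocount,
                       hub_quantile = hub_quantile)),
    class = "assoc_network"
  )
  net$properties <- network_properties(net)
  net
}

#' @export
print.assoc_network <- function(x, ...) {
  cat("<assoc_network>", nrow(x$nodes), "connected nodes /",
      length(x$node_universe), "genera,",
      sum(x$edges$keep), "edges,",
      x$modules$n_modules, "modules,",
      length(x$hubs), "hubs\n")
  invisible(x)
}

#' Build and compare one network per group
#'
#' Constructs a network for every group with identical parameters and
#' reports the topology metrics side by side together with hub overlap:
#' core hubs (present in every group's network) versus group-specific
#' hubs.
#'
#' @param table Feature table of counts.
#' @param groups Data frame `sample_id`/`group` or named label vector.
#' @param taxonomy Optional taxonomy for genus agglomeration.
#' @param min_samples Groups with fewer samples are skipped with a
#'   warning (default 4, the minimum for the correlation t-test).
#' @inheritParams build_network
#' @return A `network_comparison` object: list with `networks` (named
#'   list of `assoc_network`), `properties` (tibble, one row per group),
#'   `core_hubs`, `group_hubs`.
#' @export
compare_networks <- function(table, groups, taxonomy = NULL, r_min = 0.3,
                             alpha = 0.0001, lfdr_max = 0.2,
                             pseudocount = 1, hub_quantile = 0.95,
                             min_samples = 4) {
  mat <- ft_matrix(table)
  if (is.data.frame(groups)) {
    groups <- setNames(as.character(groups$group), groups$sample_id)
  }
  g <- groups[rownames(mat)]
  if (anyNA(g)) abort("Every sample needs a group label.")
  lev <- unique(unname(g))
  if (length(lev) < 2) abort("Need at least two groups.")

  nets <- list()
  for (gr in lev) {
    sub <- mat[g == gr, , drop = FALSE]
    if (nrow(sub) < min_samples) {
      warn(sprintf("Group `%s` has fewer than %d samples; skipped.",
                   gr, min_samples))
      next
    }
    nets[[gr]] <- build_network(ft_tibble(sub), taxonomy = taxonomy,
                                r_min = r_min, alpha = alpha,
                                lfdr_max = lfdr_max,
                                pseudocount = pseudocount,
                                hub_quantile = hub_quantile)
  }
  if (length(nets) == 0) abort("No group had enough samples.")

  props <- purrr::map_dfr(names(nets), function(gr) {
    dplyr::bind_cols(tibble(group = gr), nets[[gr]]$properties)
  })
  hub_sets <- lapply(nets, function(x) x$hubs)
  core <- Reduce(intersect, hub_sets)
  specific <- lapply(hub_sets, function(h) setdiff(h, core))
  structure(
    list(networks = nets, properties = props,
         core_hubs = core, group_hubs = specific),
    class = "network_comparison"
  )
}

#' @export
print.network_comparison <- function(x, ...) {
  cat("<network_comparison> of", length(x$networks), "groups\n")
  print(x$properties)
  cat("core hubs:", if (length(x$core_hubs)) paste(x$core_hubs, collapse = ", ")
      else "(none)", "\n")
  invisible(x)
}
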