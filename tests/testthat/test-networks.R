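tax_toy <- tibble::tibble(
  taxon_id = paste0("a", 1:4),
  domain = "Bacteria", phylum = "P1", class = "C1",
  order = c("O1", "O1", "Vicinamibacterales", "O2"),
  family = c("F1", "F1", NA, "F2"),
  genus = c("Massilia", "Massilia", NA, "Arthrobacter")
)

test_that("genus agglomeration sums counts and labels unclassified taxa", {
  mat <- rbind(S1 = c(a1 = 3, a2 = 5, a3 = 2, a4 = 7),
               S2 = c(a1 = 1, a2 = 0, a3 = 4, a4 = 2))
  out <- agglomerate_genus(make_ft(mat), tax_toy)
  m <- as.matrix(out[-1])
  rownames(m) <- out$sample_id
  expect_equal(m["S1", "Massilia"], 8)  # two ASVs of one genus add up
  expect_equal(rowSums(m), rowSums(mat))  # reads conserved
  # classified only to order -> "U. <order>"
  expect_true("U. Vicinamibacterales" %in% colnames(m))

  bad <- tax_toy
  bad[3, -1] <- NA
  expect_error(agglomerate_genus(make_ft(mat), bad), "lineage")
})

test_that("clr transform centres rows and matches hand values", {
  mat <- rbind(S1 = c(1, 1, 1, 1), S2 = c(3, 7, 2, 9))
  colnames(mat) <- paste0("g", 1:4)
  z <- clr_transform(make_ft(mat))
  expect_equal(unname(z["S1", ]), rep(0, 4))
  expect_true(all(abs(rowMeans(z)) < 1e-12))

  z2 <- clr_transform(make_ft(rbind(S1 = c(a = 9, b = 99))))
  expect_equal(unname(z2[1, ]), c(-1.1513, 1.1513), tolerance = 1e-4)
})

test_that("edge sparsification is a strict conjunction of its criteria", {
  withr::with_seed(8, {
    n <- 20
    block1 <- matrix(rnorm(n), n, 1)[, rep(1, 5)] + matrix(rnorm(n * 5, sd = 0.4), n, 5)
    block2 <- matrix(rnorm(n), n, 1)[, rep(1, 5)] + matrix(rnorm(n * 5, sd = 0.4), n, 5)
    noise <- matrix(rnorm(n * 6), n, 6)
  })
  clr <- cbind(block1, block2, noise)
  colnames(clr) <- paste0("g", 1:16)
  rownames(clr) <- paste0("S", 1:n)

  ed <- correlation_edges(clr, r_min = 0.3, alpha = 0.001, lfdr_max = NULL)

  # brute-force testing of every pair
  for (row in seq_len(nrow(ed))) {
    r <- cor(clr[, ed$from[row]], clr[, ed$to[row]])
    tt <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * pt(-abs(tt), n - 2)
    expect_equal(ed$r[row], r, tolerance = 1e-12)
    expect_equal(ed$p[row], p, tolerance = 1e-10)
    expect_equal(ed$keep[row], abs(r) >= 0.3 && p <= 0.001)
  }

  # within-block pairs are retained, cross-block and noise pairs are not
  kept <- ed[ed$keep, ]
  blocks <- list(paste0("g", 1:5), paste0("g", 6:10))
  same_block <- mapply(function(f, t) {
    any(vapply(blocks, function(b) f %in% b && t %in% b, logical(1)))
  }, kept$from, kept$to)
  expect_true(all(same_block))
  expect_gte(nrow(kept), 8)  # most within-block pairs survive

  # perfectly collinear pair
  coll <- cbind(x = 1:10, y = 2 * (1:10) + 5, z = rnorm(10))
  rownames(coll) <- paste0("S", 1:10)
  edc <- correlation_edges(coll, r_min = 0.3, alpha = 0.05, lfdr_max = NULL)
  expect_true(edc$keep[edc$from == "x" & edc$to == "y"])
  expect_equal(edc$r[edc$from == "x" & edc$to == "y"], 1)

  # an |r| below the threshold is rejected regardless of p
  n2 <- 2000
  withr::with_seed(9, {
    u <- rnorm(n2)
    v <- 0.25 * u + sqrt(1 - 0.25^2) * rnorm(n2)
    w <- rnorm(n2)
  })
  clr2 <- cbind(u = u, v = v, w = w)
  rownames(clr2) <- paste0("S", 1:n2)
  ed2 <- correlation_edges(clr2, r_min = 0.3, alpha = 0.5, lfdr_max = NULL)
  uv <- ed2[ed2$from == "u" & ed2$to == "v", ]
  expect_lt(uv$p, 1e-10)           # overwhelming significance
  expect_false(uv$keep)            # but |r| ~ 0.25 < 0.3

  # relaxing any one criterion can only add edges
  ed_strict <- correlation_edges(clr, r_min = 0.3, alpha = 0.001,
                                 lfdr_max = 0.2)
  ed_no_r <- correlation_edges(clr, r_min = 0, alpha = 0.001, lfdr_max = 0.2)
  ed_no_p <- correlation_edges(clr, r_min = 0.3, alpha = 0.999,
                               lfdr_max = 0.2)
  ed_no_l <- correlation_edges(clr, r_min = 0.3, alpha = 0.001,
                               lfdr_max = NULL)
  key <- function(e) paste(e$from, e$to)[e$keep]
  expect_true(all(key(ed_strict) %in% key(ed_no_r)))
  expect_true(all(key(ed_strict) %in% key(ed_no_p)))
  expect_true(all(key(ed_strict) %in% key(ed_no_l)))

  # zero-variance taxa are excluded with a warning
  clr3 <- cbind(clr2[1:10, ], flat = rep(1, 10))
  expect_warning(correlation_edges(clr3, lfdr_max = NULL), "flat")
})

test_that("module detection matches exhaustive search on small graphs", {
  # two disconnected 4-cliques
  g <- igraph::make_full_graph(4) + igraph::make_full_graph(4)
  igraph::V(g)$name <- paste0("n", 1:8)
  igraph::E(g)$weight <- 1
  igraph::E(g)$r <- 1
  mod <- detect_modules(g)
  expect_equal(mod$n_modules, 2)
  expect_equal(length(unique(mod$membership[1:4])), 1)
  expect_equal(length(unique(mod$membership[5:8])), 1)
  expect_true(mod$modular)  # Q comfortably above 0.4

  # 6-node barbell: two triangles joined by one edge; compare with
  # exhaustive modularity maximisation over all set partitions
  adj <- matrix(0, 6, 6, dimnames = list(paste0("n", 1:6), paste0("n", 1:6)))
  for (e in list(c(1, 2), c(1, 3), c(2, 3), c(4, 5), c(4, 6), c(5, 6),
                 c(3, 4))) {
    adj[e[1], e[2]] <- adj[e[2], e[1]] <- 1
  }
  gb <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  igraph::E(gb)$weight <- 1
  igraph::E(gb)$r <- 1
  modb <- detect_modules(gb)
  best <- oracle_best_partition(adj)
  expect_equal(modb$modularity, best$modularity, tolerance = 1e-10)
  same <- outer(modb$membership, modb$membership, "==")
  same_best <- outer(best$membership, best$membership, "==")
  expect_true(all(same == same_best))  # identical partition up to labels
})

test_that("hub detection follows eigenvector centrality quantiles", {
  # star graph: the centre is the sole hub
  star <- igraph::make_star(6, mode = "undirected", center = 1)
  igraph::V(star)$name <- paste0("n", 1:6)
  igraph::E(star)$weight <- 1
  igraph::E(star)$r <- 1
  expect_equal(as.character(hub_taxa(star)), "n1")

  # regular ring: all centralities tie, nobody is strictly above
  ring <- igraph::make_ring(8)
  igraph::V(ring)$name <- paste0("n", 1:8)
  igraph::E(ring)$weight <- 1
  igraph::E(ring)$r <- 1
  expect_length(hub_taxa(ring), 0)

  # planted-hub graph vs independent power iteration
  withr::with_seed(12, {
    adj <- matrix(0, 20, 20)
    for (i in 2:20) adj[1, i] <- adj[i, 1] <- 1  # hub node 1
    extra <- which(upper.tri(adj) & adj == 0)
    on <- sample(extra, 25)
    adj[on] <- 1
    adj <- pmax(adj, t(adj))
  })
  dimnames(adj) <- list(paste0("n", 1:20), paste0("n", 1:20))
  gp <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  igraph::E(gp)$weight <- 1
  igraph::E(gp)$r <- 1
  cent_oracle <- oracle_eigen_centrality(adj)
  thr <- quantile(cent_oracle, 0.95)
  expect_setequal(as.character(hub_taxa(gp)),
                  rownames(adj)[cent_oracle > thr])
})

test_that("network properties have their closed forms on canonical graphs", {
  k5 <- igraph::make_full_graph(5)
  igraph::V(k5)$name <- paste0("n", 1:5)
  igraph::E(k5)$weight <- 1
  igraph::E(k5)$r <- 1
  pr <- network_properties(k5)
  expect_equal(pr$clustering_coefficient, 1)
  expect_equal(pr$edge_density, 1)
  expect_equal(pr$average_path_length, 1)
  expect_equal(pr$n_components, 1)
  expect_equal(pr$positive_edge_pct, 100)

  # path graph P3: APL = (1+1+2)/3, checked against the BFS oracle
  p3 <- igraph::make_graph(c(1, 2, 2, 3), directed = FALSE)
  igraph::V(p3)$name <- paste0("n", 1:3)
  igraph::E(p3)$weight <- 1
  igraph::E(p3)$r <- 1
  pr3 <- network_properties(p3)
  expect_equal(pr3$average_path_length, 4 / 3)
  adj3 <- matrix(0, 3, 3)
  adj3[1, 2] <- adj3[2, 1] <- adj3[2, 3] <- adj3[3, 2] <- 1
  expect_equal(pr3$average_path_length, oracle_apl(adj3))

  # edgeless graph: the natural-connectivity core term is exactly 0
  expect_equal(rhizocomm:::natural_connectivity(matrix(0, 4, 4)), 0)

  # isolated genera count as singleton components of the universe
  pr_u <- network_properties(p3, node_universe = c(paste0("n", 1:3),
                                                   "iso1", "iso2"))
  expect_equal(pr_u$n_components, 3)
  expect_equal(pr_u$edge_density, 2 / choose(5, 2))
})

test_that("natural connectivity strictly decreases when edges are deleted", {
  withr::with_seed(13, {
    g <- igraph::sample_gnp(10, 0.5)
    while (igraph::components(g)$no > 1) g <- igraph::sample_gnp(10, 0.5)
  })
  adj <- as.matrix(igraph::as_adjacency_matrix(g))
  nc_full <- rhizocomm:::natural_connectivity(adj)
  edges <- which(upper.tri(adj) & adj == 1)
  for (e in edges[1:5]) {
    adj2 <- adj
    adj2[e] <- 0
    adj2 <- pmin(adj2, t(adj2))
    expect_lt(rhizocomm:::natural_connectivity(adj2), nc_full)
  }
})

test_that("group comparison flags the group lacking a correlated block", {
  pt <- planted_two_group_tables(seed = 14)
  cmp <- compare_networks(pt$table, pt$groups, alpha = 0.001,
                          lfdr_max = NULL, min_samples = 4)
  pa <- cmp$properties[cmp$properties$group == "A", ]
  pb <- cmp$properties[cmp$properties$group == "B", ]
  expect_gt(pa$n_nodes, pb$n_nodes)
  expect_gt(pa$n_edges, pb$n_edges)
  expect_gt(pa$robustness, pb$robustness)

  # modules of group A recover the planted blocks
  memA <- cmp$networks$A$modules$membership
  planted <- unlist(pt$blocks)
  scored <- intersect(names(memA), planted)
  truth <- ifelse(scored %in% pt$blocks$block1, 1L, 2L)
  expect_gte(mclust::adjustedRandIndex(memA[scored], truth), 0.8)

  # identical tables give identical networks and full hub overlap
  mat <- as.matrix(pt$table[-1])
  rownames(mat) <- pt$table$sample_id
  tbl2 <- rbind(mat[1:16, ], mat[1:16, ])
  rownames(tbl2) <- paste0("S", 1:32)
  grp2 <- tibble::tibble(sample_id = rownames(tbl2),
                         group = rep(c("A", "B"), each = 16))
  cmp2 <- compare_networks(make_ft(tbl2), grp2, alpha = 0.01,
                           lfdr_max = NULL)
  expect_equal(cmp2$properties[cmp2$properties$group == "A", -1],
               cmp2$properties[cmp2$properties$group == "B", -1])
  expect_setequal(cmp2$networks$A$hubs, cmp2$networks$B$hubs)
  expect_length(unlist(cmp2$group_hubs), 0)
})

test_that("build_network assembles edges, modules and hubs coherently", {
  ds <- simulate_dataset(n_cultivars = 5, n_replicates = 3, n_taxa = 60,
                         depth = 2000, seed = 6)
  net <- build_network(ds$table, taxonomy = ds$taxonomy, alpha = 0.05,
                       lfdr_max = NULL)
  expect_s3_class(net, "assoc_network")
  # every hub is a connected node
  expect_true(all(net$hubs %in% net$nodes$node))
  expect_true(all(net$nodes$degree >= 1))
  # no self-edges, unique unordered pairs
  kept <- net$edges[net$edges$keep, ]
  expect_false(any(kept$from == kept$to))
  expect_false(any(duplicated(paste(pmin(kept$from, kept$to),
                                    pmax(kept$from, kept$to)))))
  # glance returns the properties row
  expect_equal(glance(net), net$properties)
})
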