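# Independent brute-force oracles used to validate the package's
# implementations. These deliberately use naive algorithms (path walks,
# double loops, exhaustive enumeration, power iteration) and never call
# the functions they check.

# Feature-table tibble from a plain matrix.
make_ft <- function(mat) {
  dplyr::bind_cols(
    tibble::tibble(sample_id = rownames(mat)),
    tibble::as_tibble(mat, .name_repair = "minimal")
  )
}

# Patristic distance by explicit root-path walking: distance(a, b) =
# depth(a) + depth(b) - 2 * depth(mrca) computed from edge lists.
oracle_cophenetic <- function(tree) {
  n <- length(tree$tip.label)
  parent <- integer(n + tree$Nnode)
  elen <- numeric(n + tree$Nnode)
  for (i in seq_len(nrow(tree$edge))) {
    parent[tree$edge[i, 2]] <- tree$edge[i, 1]
    elen[tree$edge[i, 2]] <- tree$edge.length[i]
  }
  path_to_root <- function(v) {
    nodes <- v
    while (parent[v] != 0) {
      v <- parent[v]
      nodes <- c(nodes, v)
    }
    nodes
  }
  depth_of <- function(v) {
    d <- 0
    while (parent[v] != 0) {
      d <- d + elen[v]
      v <- parent[v]
    }
    d
  }
  D <- matrix(0, n, n, dimnames = list(tree$tip.label, tree$tip.label))
  for (a in seq_len(n - 1)) {
    pa <- path_to_root(a)
    for (b in seq(a + 1, n)) {
      pb <- path_to_root(b)
      mrca <- intersect(pa, pb)[1]
      D[a, b] <- D[b, a] <- depth_of(a) + depth_of(b) - 2 * depth_of(mrca)
    }
  }
  D
}

# Abundance-weighted betaMNTD by literal double loop over present taxa.
oracle_bmntd <- function(p_a, p_b, d) {
  a <- p_a[p_a > 0] / sum(p_a[p_a > 0])
  b <- p_b[p_b > 0] / sum(p_b[p_b > 0])
  s1 <- 0
  for (i in names(a)) s1 <- s1 + a[[i]] * min(d[i, names(b)])
  s2 <- 0
  for (j in names(b)) s2 <- s2 + b[[j]] * min(d[j, names(a)])
  0.5 * (s1 + s2)
}

# Weighted UniFrac by explicit branch enumeration: every edge's descendant
# tip set is found by a recursive walk, then terms are summed branch by
# branch.
oracle_unifrac <- function(p_a, p_b, tree, normalized = TRUE) {
  n <- length(tree$tip.label)
  children <- split(tree$edge[, 2], tree$edge[, 1])
  tips_under <- function(v) {
    if (v <= n) return(tree$tip.label[v])
    unlist(lapply(children[[as.character(v)]], tips_under))
  }
  num <- 0
  den <- 0
  for (i in seq_len(nrow(tree$edge))) {
    tips <- tips_under(tree$edge[i, 2])
    wa <- sum(p_a[tips])
    wb <- sum(p_b[tips])
    num <- num + tree$edge.length[i] * abs(wa - wb)
    den <- den + tree$edge.length[i] * (wa + wb)
  }
  if (!normalized) return(num)
  if (den > 0) num / den else 0
}

# Average shortest-path length over reachable pairs by breadth-first
# search on an adjacency matrix.
oracle_apl <- function(adj) {
  n <- nrow(adj)
  total <- 0
  count <- 0
  for (s in seq_len(n)) {
    dist <- rep(NA_integer_, n)
    dist[s] <- 0L
    queue <- s
    while (length(queue) > 0) {
      v <- queue[1]
      queue <- queue[-1]
      for (u in which(adj[v, ] > 0)) {
        if (is.na(dist[u])) {
          dist[u] <- dist[v] + 1L
          queue <- c(queue, u)
        }
      }
    }
    reach <- which(!is.na(dist) & seq_len(n) != s)
    total <- total + sum(dist[reach])
    count <- count + length(reach)
  }
  if (count == 0) return(NA_real_)
  total / count
}

# All set partitions of 1..n (n small), for exhaustive modularity search.
all_partitions <- function(n) {
  if (n == 1) return(list(list(1L)))
  out <- list()
  for (p in all_partitions(n - 1)) {
    for (k in seq_along(p)) {
      q <- p
      q[[k]] <- c(q[[k]], n)
      out[[length(out) + 1]] <- q
    }
    out[[length(out) + 1]] <- c(p, list(n))
  }
  out
}

# Newman modularity of a partition, written out from the definition
# Q = sum_ij (A_ij - k_i k_j / 2m) delta(c_i, c_j) / 2m.
oracle_modularity <- function(adj, membership) {
  m2 <- sum(adj)  # 2m for an undirected graph stored symmetrically
  if (m2 == 0) return(NA_real_)
  k <- rowSums(adj)
  q <- 0
  n <- nrow(adj)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (membership[i] == membership[j]) {
        q <- q + adj[i, j] - k[i] * k[j] / m2
      }
    }
  }
  unname(q / m2)
}

# Best partition by exhaustive search (n <= 6 nodes).
oracle_best_partition <- function(adj) {
  n <- nrow(adj)
  best_q <- -Inf
  best <- NULL
  for (p in all_partitions(n)) {
    mem <- integer(n)
    for (k in seq_along(p)) mem[p[[k]]] <- k
    q <- oracle_modularity(adj, mem)
    if (q > best_q) {
      best_q <- q
      best <- mem
    }
  }
  list(membership = best, modularity = best_q)
}

# Eigenvector centrality by power iteration to 1e-12 convergence,
# normalised to max 1.
oracle_eigen_centrality <- function(adj) {
  n <- nrow(adj)
  v <- rep(1 / sqrt(n), n)
  for (i in seq_len(100000)) {
    w <- adj %*% v
    w <- w / sqrt(sum(w^2))
    if (max(abs(w - v)) < 1e-12) break
    v <- w
  }
  v <- as.vector(v)
  v / max(v)
}

# ANOSIM R statistic from ranked distances, written out from the
# definition (used for exhaustive-permutation checks on tiny inputs).
oracle_anosim_r <- function(d, labels) {
  dm <- as.matrix(d)
  n <- nrow(dm)
  ij <- which(upper.tri(dm), arr.ind = TRUE)
  r <- rank(dm[upper.tri(dm)])
  within <- labels[ij[, 1]] == labels[ij[, 2]]
  (mean(r[!within]) - mean(r[within])) / (n * (n - 1) / 4)
}

rand_blob_data <- function(n_per, centers, sd, seed) {
  withr::with_seed(seed, {
    do.call(rbind, lapply(seq_len(nrow(centers)), function(k) {
      matrix(rnorm(n_per * ncol(centers), mean = 0, sd = sd),
             n_per, ncol(centers)) +
        matrix(centers[k, ], n_per, ncol(centers), byrow = TRUE)
    }))
  })
}

# All permutations of a label vector (tiny n only).
combinat_perms <- function(labs) {
  n <- length(labs)
  idx_perms <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in idx_perms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    }
    out
  }
  lapply(idx_perms(seq_len(n)), function(ix) labs[ix])
}

# Two sample groups over the same genus universe: both carry correlated
# block 1, only group A carries correlated block 2; everything else is
# independent log-normal noise. Block loadings alternate in sign so the
# blocks do not bleed into the clr row mean. Used for
# network-discrimination checks.
planted_two_group_tables <- function(seed, n_per_group = 24,
                                     block_size = 8, n_noise = 24) {
  n_taxa <- 2 * block_size + n_noise
  gen_group <- function(with_block2) {
    lat1 <- rnorm(n_per_group)
    lat2 <- rnorm(n_per_group)
    sgn <- rep(c(1, -1), length.out = block_size)
    logx <- cbind(
      sapply(seq_len(block_size),
             function(i) sgn[i] * 0.7 * lat1 + rnorm(n_per_group, sd = 0.3)),
      sapply(seq_len(block_size), function(i) {
        if (with_block2) sgn[i] * 0.7 * lat2 + rnorm(n_per_group, sd = 0.3)
        else rnorm(n_per_group, sd = 0.6)
      }),
      matrix(rnorm(n_per_group * n_noise, sd = 0.6), n_per_group, n_noise)
    )
    round(300 * exp(logx))
  }
  withr::with_seed(seed, {
    a <- gen_group(TRUE)
    b <- gen_group(FALSE)
  })
  tbl <- rbind(a, b)
  rownames(tbl) <- paste0("S", seq_len(2 * n_per_group))
  colnames(tbl) <- paste0("g", seq_len(n_taxa))
  list(
    table = make_ft(tbl),
    groups = tibble::tibble(
      sample_id = rownames(tbl),
      group = rep(c("A", "B"), each = n_per_group)),
    blocks = list(block1 = paste0("g", seq_len(block_size)),
                  block2 = paste0("g", block_size + seq_len(block_size)))
  )
}
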