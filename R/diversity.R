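# Alpha diversity, weighted-UniFrac beta diversity with PCoA, PERMANOVA
# factor testing, and pairwise Wilcoxon differential abundance with FDR
# control.

#' Alpha diversity metrics
#'
#' Computes observed richness, Shannon index (nats) and Simpson's
#' dominance per sample. Within-sample proportions are recomputed
#' internally, so counts and relative abundances give identical results.
#'
#' @param table Feature table (counts or relative abundances).
#' @return Tibble: `sample_id`, `richness`, `shannon`, `simpson_dominance`
#'   (lambda = sum p_i^2) and its complement `simpson_diversity` (1 -
#'   lambda); both orientations are reported because "Simpson index"
#'   is used for either in the literature.
#' @export
alpha_diversity <- function(table) {
  mat <- ft_matrix(table)
  rs <- rowSums(mat)
  if (any(rs == 0)) {
    abort(paste0("Empty sample(s): ",
                 paste(rownames(mat)[rs == 0], collapse = ", ")))
  }
  p <- mat / rs
  shannon <- apply(p, 1, function(x) {
    x <- x[x > 0]
    -sum(x * log(x))
  })
  lambda <- rowSums(p^2)
  tibble(
    sample_id = rownames(mat),
    richness = as.integer(rowSums(mat > 0)),
    shannon = unname(shannon),
    simpson_dominance = unname(lambda),
    simpson_diversity = unname(1 - lambda)
  )
}

#' Weighted UniFrac distances
#'
#' For each sample pair A, B the distance is
#' `sum_i b_i |A_i - B_i| / sum_i b_i (A_i + B_i)` where the sum runs over
#' all branches, `b_i` is the branch length and `A_i` the total relative
#' abundance of the tips descending from branch `i`. The normalised form
#' (default) lies in \[0, 1\]; `normalized = FALSE` returns the raw
#' branch-length-weighted sum.
#'
#' @param table Feature table; rows are renormalised to proportions.
#' @param tree Rooted phylogeny with branch lengths covering all taxa.
#' @param normalized Divide by the branch-abundance total (default TRUE).
#' @return Symmetric distance matrix with sample ids as dimnames.
#' @export
weighted_unifrac <- function(table, tree, normalized = TRUE) {
  mat <- ft_matrix(table)
  missing <- setdiff(colnames(mat), tree$tip.label)
  if (length(missing) > 0) {
    abort(paste0("Taxa missing from tree: ", paste(missing, collapse = ", ")))
  }
  rs <- rowSums(mat)
  if (any(rs == 0)) abort("Empty sample in feature table.")
  p <- mat / rs

  tr <- ape::reorder.phylo(tree, "postorder")
  n_tip <- length(tr$tip.label)
  n_node <- n_tip + tr$Nnode
  A <- matrix(0, nrow(p), n_node)
  A[, match(colnames(p), tr$tip.label)] <- p
  for (i in seq_len(nrow(tr$edge))) {
    A[, tr$edge[i, 1]] <- A[, tr$edge[i, 1]] + A[, tr$edge[i, 2]]
  }
  ew <- A[, tr$edge[, 2], drop = FALSE]  # samples x branches
  len <- tr$edge.length

  n <- nrow(p)
  D <- matrix(0, n, n, dimnames = list(rownames(p), rownames(p)))
  for (a in seq_len(n - 1)) {
    for (b in seq(a + 1, n)) {
      num <- sum(len * abs(ew[a, ] - ew[b, ]))
      d <- if (normalized) {
        den <- sum(len * (ew[a, ] + ew[b, ]))
        if (den > 0) num / den else 0
      } else {
        num
      }
      D[a, b] <- D[b, a] <- d
    }
  }
  D
}

#' Principal coordinates analysis
#'
#' Gower-centred eigendecomposition of a distance matrix via [ape::pcoa].
#' Negative eigenvalues are reported, never silently dropped.
#'
#' @param dist Symmetric distance matrix.
#' @param k Number of axes to return (default all positive axes).
#' @return List with `coordinates` (tibble: `sample_id`, `Axis.1`, ...),
#'   `eigenvalues`, and `rel_eig` (relative eigenvalues, signed).
#' @export
pcoa_ordination <- function(dist, k = NULL) {
  d <- assert_square_dist(dist)
  fit <- ape::pcoa(stats::as.dist(d))
  vec <- fit$vectors
  if (!is.null(k)) vec <- vec[, seq_len(min(k, ncol(vec))), drop = FALSE]
  coords <- dplyr::bind_cols(
    tibble(sample_id = rownames(d)),
    as_tibble(vec, .name_repair = "minimal")
  )
  list(
    coordinates = coords,
    eigenvalues = fit$values$Eigenvalues,
    rel_eig = fit$values$Relative_eig
  )
}

#' One-factor PERMANOVA per metadata factor
#'
#' Distance-based variance partition (pseudo-F, R-squared) with a free
#' permutation test of the labels, via [vegan::adonis2]. Each factor is
#' tested in its own one-factor model, so the reported R-squared values are
#' order-independent.
#'
#' @param dist Symmetric distance matrix over samples.
#' @param metadata Data frame with `sample_id` and the factor columns.
#' @param factors Character vector of metadata columns to test.
#' @param n_perm Number of permutations (default 999).
#' @param seed Integer seed.
#' @return Tibble: `factor`, `df`, `R2`, `F`, `p`, `n_perm`.
#' @export
permanova_test <- function(dist, metadata, factors, n_perm = 999, seed = 1) {
  d <- assert_square_dist(dist)
  idx <- match(rownames(d), metadata$sample_id)
  if (anyNA(idx)) abort("Every sample in `dist` needs metadata.")
  md <- metadata[idx, , drop = FALSE]
  missing <- setdiff(factors, names(md))
  if (length(missing) > 0) {
    abort(paste0("Unknown factor(s): ", paste(missing, collapse = ", ")))
  }
  purrr::map_dfr(seq_along(factors), function(i) {
    f <- factors[i]
    lab <- as.factor(md[[f]])
    if (nlevels(lab) < 2) abort(sprintf("Factor `%s` has a single level.", f))
    df <- data.frame(.f = lab)
    fit <- withr::with_seed(derive_seed(seed, 10L + i), {
      vegan::adonis2(stats::as.dist(d) ~ .f, data = df,
                     permutations = n_perm)
    })
    tibble(factor = f, df = fit$Df[1], R2 = fit$R2[1], F = fit$F[1],
           p = fit$`Pr(>F)`[1], n_perm = n_perm)
  })
}

#' Pairwise Wilcoxon tests with FDR adjustment
#'
#' Two-sided rank-sum tests for every pair of groups and every feature,
#' with Benjamini-Hochberg adjustment across the whole family of tests.
#'
#' @param data Feature table (`sample_id` + one numeric column per
#'   feature) or a data frame of per-sample metrics in the same layout.
#' @param groups Data frame with `sample_id` and `group`, or a vector of
#'   labels named by sample id.
#' @param alpha Significance level on the adjusted p-values (default 0.05).
#' @return Tibble: `feature`, `group1`, `group2`, `statistic`, `p`, `q`,
#'   `significant`.
#' @export
pairwise_wilcoxon_fdr <- function(data, groups, alpha = 0.05) {
  # plain value matrix: unlike abundance tables, per-sample metrics may
  # legitimately be negative (e.g. clr values)
  mat <- if (is.matrix(data)) {
    data
  } else {
    id_col <- if ("sample_id" %in% names(data)) "sample_id" else names(data)[1]
    m <- as.matrix(data[setdiff(names(data), id_col)])
    rownames(m) <- as.character(data[[id_col]])
    m
  }
  if (!is.numeric(mat)) abort("Feature columns must be numeric.")
  if (is.data.frame(groups)) {
    groups <- setNames(as.character(groups$group), groups$sample_id)
  }
  g <- groups[rownames(mat)]
  if (anyNA(g)) abort("Every sample needs a group label.")
  lev <- unique(unname(g))
  if (length(lev) < 2) abort("Need at least two groups.")
  if (any(table(g) < 2)) abort("Each group needs >= 2 samples.")
  pairs <- combn(lev, 2, simplify = FALSE)

  out <- purrr::map_dfr(colnames(mat), function(feat) {
    purrr::map_dfr(pairs, function(pr) {
      x <- mat[g == pr[1], feat]
      y <- mat[g == pr[2], feat]
      if (length(unique(c(x, y))) == 1) {
        warn(sprintf("All values tied for feature `%s` (%s vs %s); p = 1.",
                     feat, pr[1], pr[2]))
        return(tibble(feature = feat, group1 = pr[1], group2 = pr[2],
                      statistic = length(x) * length(y) / 2, p = 1))
      }
      wt <- suppressWarnings(wilcox.test(x, y, exact = NULL))
      tibble(feature = feat, group1 = pr[1], group2 = pr[2],
             statistic = unname(wt$statistic), p = wt$p.value)
    })
  })
  out$q <- p.adjust(out$p, method = "BH")
  out$significant <- out$q < alpha
  out
}
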