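# Null-model partitioning of community assembly: betaMNTD, betaNTI against
# tip-shuffling nulls, Raup-Crick Bray-Curtis, and the five-process
# classification with per-group summaries.

#' Patristic (cophenetic) distances between taxa
#'
#' Sum of branch lengths along the tip-to-tip path, via
#' [ape::cophenetic.phylo].
#'
#' @param tree Phylogeny with branch lengths.
#' @return Symmetric taxon distance matrix with zero diagonal.
#' @export
cophenetic_distances <- function(tree) {
  if (!inherits(tree, "phylo")) abort("`tree` must be a `phylo` object.")
  ape::cophenetic.phylo(tree)
}

#' Beta mean-nearest-taxon distance between two communities
#'
#' `0.5 * [ sum_i p_a(i) min_j d(i, j) + sum_j p_b(j) min_i d(j, i) ]`,
#' where the minima run over taxa with nonzero abundance in the other
#' community; a taxon shared by both communities contributes distance 0.
#' With `weighted = FALSE` all present taxa get equal weight.
#'
#' @param p_a,p_b Abundance vectors named by taxon (renormalised to
#'   proportions internally).
#' @param taxon_dist Taxon distance matrix covering all present taxa.
#' @param weighted Abundance-weight the contributions (default TRUE).
#' @return The betaMNTD value (scalar).
#' @export
beta_mntd <- function(p_a, p_b, taxon_dist, weighted = TRUE) {
  a <- p_a[p_a > 0]
  b <- p_b[p_b > 0]
  if (length(a) == 0 || length(b) == 0) abort("Empty community.")
  if (!weighted) {
    a[] <- 1
    b[] <- 1
  }
  a <- a / sum(a)
  b <- b / sum(b)
  d <- assert_square_dist(taxon_dist)
  miss <- setdiff(c(names(a), names(b)), rownames(d))
  if (length(miss) > 0) {
    abort(paste0("Taxa missing from distance matrix: ",
                 paste(miss, collapse = ", ")))
  }
  dab <- d[names(a), names(b), drop = FALSE]
  0.5 * (sum(a * apply(dab, 1, min)) + sum(b * apply(dab, 2, min)))
}

#' Observed betaMNTD for all sample pairs
#'
#' @param table Feature table (counts or relative; rows renormalised).
#' @param tree Phylogeny covering all table taxa, or a precomputed taxon
#'   distance matrix.
#' @return Symmetric sample-by-sample betaMNTD matrix.
#' @export
beta_mntd_all <- function(table, tree) {
  mat <- ft_matrix(table)
  d <- taxon_dist_for(mat, tree)
  res <- bnti_engine(mat, d, matrix(integer(0), 0, ncol(mat)))
  out <- res$obs
  dimnames(out) <- list(rownames(mat), rownames(mat))
  out
}

#' @noRd
taxon_dist_for <- function(mat, tree) {
  if (inherits(tree, "phylo")) {
    miss <- setdiff(colnames(mat), tree$tip.label)
    if (length(miss) > 0) {
      abort(paste0("Taxa missing from tree: ", paste(miss, collapse = ", ")))
    }
    d <- cophenetic_distances(tree)
  } else {
    d <- assert_square_dist(tree)
  }
  d[colnames(mat), colnames(mat), drop = FALSE]
}

#' Beta nearest-taxon index (betaNTI)
#'
#' Standardised effect size of betaMNTD against a null distribution
#' obtained by random shuffles of the taxa across the phylogeny tips
#' (one shared permutation per null iteration, abundances untouched):
#' `(obs - mean(null)) / sd(null)` per sample pair. Pairs whose null
#' distribution has zero spread (e.g. on a star phylogeny) are flagged
#' degenerate and returned as `NA` rather than 0.
#'
#' @inheritParams beta_mntd_all
#' @param n_null Number of null shuffles (>= 100; the workflow default is
#'   1000).
#' @param seed Integer seed.
#' @return A `beta_nti` object: list with matrices `bnti`, `bmntd`,
#'   `null_mean`, `null_sd`, logical `degenerate`, and `n_null`.
#' @export
beta_nti <- function(table, tree, n_null = 1000, seed = 1) {
  if (n_null < 100) abort("`n_null` must be >= 100.")
  mat <- ft_matrix(table)
  if (nrow(mat) < 2) abort("Need at least two samples.")
  d <- taxon_dist_for(mat, tree)
  S <- ncol(mat)
  perms <- withr::with_seed(derive_seed(seed, 20L), {
    t(vapply(seq_len(n_null), function(k) sample.int(S), integer(S)))
  })
  res <- bnti_engine(mat, d, perms)
  degen <- res$null_sd < 1e-12
  bnti <- (res$obs - res$null_mean) / res$null_sd
  bnti[degen] <- NA_real_
  diag(bnti) <- 0
  diag(degen) <- FALSE
  ids <- rownames(mat)
  for (m in c("obs", "null_mean", "null_sd")) dimnames(res[[m]]) <- list(ids, ids)
  dimnames(bnti) <- dimnames(degen) <- list(ids, ids)
  structure(
    list(bnti = bnti, bmntd = res$obs, null_mean = res$null_mean,
         null_sd = res$null_sd, degenerate = degen, n_null = n_null),
    class = "beta_nti"
  )
}

#' @export
print.beta_nti <- function(x, ...) {
  n <- nrow(x$bnti)
  cat("<beta_nti>", n, "samples,", x$n_null, "nulls;",
      sum(x$degenerate[upper.tri(x$degenerate)]), "degenerate pair(s)\n")
  invisible(x)
}

#' @noRd
bray_curtis_pairs <- function(x, y) {
  # columns of x vs matching columns of y
  1 - 2 * colSums(pmin(x, y)) / (colSums(x) + colSums(y))
}

#' Raup-Crick Bray-Curtis (RCbray)
#'
#' For each sample pair, null communities preserve each sample's observed
#' richness and total abundance: species are drawn without replacement
#' with probability proportional to their occurrence frequency across
#' samples, then reads are allocated multinomially with probability
#' proportional to the mean relative abundance of the drawn species.
#' The observed Bray-Curtis dissimilarity is located within the null
#' distribution and rescaled to \[-1, 1\]:
#' `2 * [(#null < obs) + 0.5 (#null = obs)] / n_null - 1`.
#'
#' @param table Feature table of counts.
#' @param n_null Number of null assemblies (>= 100; workflow default 1000).
#' @param seed Integer seed.
#' @return Symmetric matrix of RCbray values in \[-1, 1\].
#' @export
raup_crick_bray <- function(table, n_null = 1000, seed = 1) {
  if (n_null < 100) abort("`n_null` must be >= 100.")
  mat <- ft_matrix(table)
  assert_counts(mat, "the Raup-Crick null")
  rich <- rowSums(mat > 0)
  if (any(rich == 0)) {
    abort(paste0("Sample(s) with zero richness: ",
                 paste(rownames(mat)[rich == 0], collapse = ", ")))
  }
  n <- nrow(mat)
  S <- ncol(mat)
  totals <- rowSums(mat)
  freq <- colMeans(mat > 0)
  mean_rel <- colMeans(mat / totals)
  occurring <- which(freq > 0)

  nulls <- withr::with_seed(derive_seed(seed, 21L), {
    lapply(seq_len(n), function(s) {
      r <- min(rich[s], length(occurring))
      out <- matrix(0, S, n_null)
      for (k in seq_len(n_null)) {
        sp <- occurring[sample.int(length(occurring), r,
                                   prob = freq[occurring])]
        out[sp, k] <- rmultinom(1, totals[s], mean_rel[sp])
      }
      out
    })
  })

  rc <- matrix(0, n, n, dimnames = list(rownames(mat), rownames(mat)))
  for (a in seq_len(n - 1)) {
    for (b in seq(a + 1, n)) {
      obs <- 1 - 2 * sum(pmin(mat[a, ], mat[b, ])) / (totals[a] + totals[b])
      nb <- bray_curtis_pairs(nulls[[a]], nulls[[b]])
      below <- sum(nb < obs - 1e-12)
      ties <- sum(abs(nb - obs) <= 1e-12)
      rc[a, b] <- rc[b, a] <- 2 * (below + 0.5 * ties) / n_null - 1
    }
  }
  rc
}

#' Classify the assembly process of a sample pair
#'
#' Applies the standard two-stage thresholds: betaNTI > 2 heterogeneous
#' selection, betaNTI < -2 homogeneous selection; among stochastic pairs
#' (|betaNTI| <= 2), RCbray > 0.95 dispersal limitation, RCbray < -0.95
#' homogenizing dispersal, otherwise undominated. Boundary values
#' (|betaNTI| = 2, |RCbray| = 0.95) fall on the stochastic/undominated
#' side.
#'
#' @param bnti,rcbray Numeric vectors (recycled to a common length);
#'   `NA` in `bnti` (degenerate nulls) gives `NA`.
#' @return Character vector of process labels.
#' @export
classify_process <- function(bnti, rcbray) {
  k <- max(length(bnti), length(rcbray))
  bnti <- rep_len(bnti, k)
  rcbray <- rep_len(rcbray, k)
  if (any(is.nan(bnti)) || any(is.nan(rcbray))) {
    abort("NaN in betaNTI or RCbray input.")
  }
  dplyr::case_when(
    is.na(bnti) ~ NA_character_,
    bnti > 2 ~ "heterogeneous_selection",
    bnti < -2 ~ "homogeneous_selection",
    rcbray > 0.95 ~ "dispersal_limitation",
    rcbray < -0.95 ~ "homogenizing_dispersal",
    TRUE ~ "undominated"
  )
}

#' Full pairwise assembly analysis
#'
#' Runs betaNTI (on within-sample proportions) and RCbray (on counts) and
#' classifies every retained sample pair. By default only within-group
#' pairs are classified, matching per-group assembly summaries; use
#' `pairs = "all"` to classify every pair.
#'
#' @param table Feature table of counts.
#' @param tree Phylogeny (or taxon distance matrix).
#' @param groups Optional group labels (data frame `sample_id`/`group` or
#'   named vector). Required for `pairs = "within"` with more than one
#'   group; when omitted all samples form one group.
#' @param pairs `"within"` (default) or `"all"`.
#' @param n_null Null iterations for both null models.
#' @param seed Integer seed.
#' @return An `assembly_result` tibble: `sample_a`, `sample_b`, `group`,
#'   `bmntd`, `bnti`, `rcbray`, `process` (NA = unclassifiable pair).
#' @export
assembly_analysis <- function(table, tree, groups = NULL,
                              pairs = c("within", "all"),
                              n_null = 1000, seed = 1) {
  pairs <- match.arg(pairs)
  mat <- ft_matrix(table)
  assert_counts(mat, "assembly analysis")
  if (is.null(groups)) {
    groups <- setNames(rep("all", nrow(mat)), rownames(mat))
  } else if (is.data.frame(groups)) {
    groups <- setNames(as.character(groups$group), groups$sample_id)
  }
  g <- groups[rownames(mat)]
  if (anyNA(g)) abort("Every sample needs a group label.")

  bn <- beta_nti(mat / rowSums(mat), tree, n_null = n_null, seed = seed)
  rc <- raup_crick_bray(mat, n_null = n_null, seed = seed)

  n <- nrow(mat)
  ij <- which(upper.tri(bn$bnti), arr.ind = TRUE)
  out <- tibble(
    sample_a = rownames(mat)[ij[, 1]],
    sample_b = rownames(mat)[ij[, 2]],
    group_a = unname(g[ij[, 1]]),
    group_b = unname(g[ij[, 2]]),
    bmntd = bn$bmntd[ij],
    bnti = bn$bnti[ij],
    rcbray = rc[ij]
  )
  if (pairs == "within") {
    out <- dplyr::filter(out, .data$group_a == .data$group_b)
  }
  out <- dplyr::mutate(
    out,
    group = dplyr::if_else(.data$group_a == .data$group_b,
                           .data$group_a, "between"),
    process = classify_process(.data$bnti, .data$rcbray)
  )
  out <- dplyr::select(out, "sample_a", "sample_b", "group",
                       "bmntd", "bnti", "rcbray", "process")
  structure(out, class = c("assembly_result", class(tibble())),
            n_null = n_null, pairs = pairs)
}

#' Summarise assembly-process fractions per group
#'
#' Fraction of classified sample pairs assigned to each of the five
#' processes, per group; unclassifiable (degenerate-null) pairs are
#' reported separately and excluded from the denominator, so the five
#' fractions sum to 1.
#'
#' @param pairwise An `assembly_result` (or any data frame with `group`
#'   and `process` columns).
#' @return Tibble: `group`, `process`, `fraction`, `n_pairs`, with one
#'   `n_unclassifiable` value per group carried as a column.
#' @export
summarize_fractions <- function(pairwise) {
  processes <- c("heterogeneous_selection", "homogeneous_selection",
                 "dispersal_limitation", "homogenizing_dispersal",
                 "undominated")
  purrr::map_dfr(split(pairwise, pairwise$group), function(d) {
    if (nrow(d) < 1) return(NULL)
    cl <- d$process[!is.na(d$process)]
    n_un <- sum(is.na(d$process))
    if (length(cl) == 0) {
      warn(sprintf("Group `%s` has no classifiable pairs.", d$group[1]))
      return(NULL)
    }
    tibble(
      group = d$group[1],
      process = processes,
      fraction = as.numeric(table(factor(cl, levels = processes))) / length(cl),
      n_pairs = length(cl),
      n_unclassifiable = n_un
    )
  })
}
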