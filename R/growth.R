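# Growth-based clustering of cultivars: trait scaling, choice of k,
# k-means and Ward hierarchical clustering, performance ranking of the
# clusters, and ANOSIM separation testing.

#' Scale growth traits to z-scores
#'
#' @param traits Data frame with a `cultivar` identifier column and one
#'   numeric column per trait (replicate means); a planted `true_cluster`
#'   column is ignored if present.
#' @return Numeric matrix of column-wise z-scores (mean 0, sd 1 with n-1
#'   denominator), cultivars as row names.
#' @export
scale_traits <- function(traits) {
  if (!is.data.frame(traits)) abort("`traits` must be a data frame.")
  id_col <- if ("cultivar" %in% names(traits)) "cultivar" else names(traits)[1]
  keep <- setdiff(names(traits), c(id_col, "true_cluster"))
  mat <- as.matrix(traits[keep])
  if (!is.numeric(mat)) abort("Trait columns must be numeric.")
  if (nrow(mat) < 2) abort("Need at least two cultivars.")
  sds <- apply(mat, 2, sd)
  if (any(sds == 0)) {
    abort(paste0("Zero-variance trait(s): ",
                 paste(keep[sds == 0], collapse = ", ")))
  }
  out <- scale(mat)
  rownames(out) <- as.character(traits[[id_col]])
  attr(out, "scaled:center") <- NULL
  attr(out, "scaled:scale") <- NULL
  out
}

#' Select the number of clusters
#'
#' `criterion = "wss"` picks the elbow of the total within-cluster sum of
#' squares curve over k = 1..k_max (the k maximising the second difference
#' of the curve); `criterion = "silhouette"` picks the k in 2..k_max with
#' the largest mean silhouette width and warns about weak structure when
#' that width is below 0.25.
#'
#' @param scaled Scaled trait matrix (see [scale_traits()]).
#' @param k_max Largest k to consider (2 <= k_max < number of rows).
#' @param criterion `"wss"` (default) or `"silhouette"`.
#' @param seed Integer seed for the k-means restarts.
#' @param n_init Random restarts per k.
#' @return A `k_selection` object: list with `k`, `criterion`, and the
#'   diagnostic `curve` tibble.
#' @export
select_k <- function(scaled, k_max = 10, criterion = c("wss", "silhouette"),
                     seed = 1, n_init = 25) {
  criterion <- match.arg(criterion)
  scaled <- as.matrix(scaled)
  n <- nrow(scaled)
  if (k_max < 2) abort("`k_max` must be >= 2.")
  if (k_max >= n) abort("`k_max` must be smaller than the number of rows.")

  fits <- withr::with_seed(derive_seed(seed, 7L), {
    lapply(seq_len(k_max), function(k) {
      kmeans(scaled, centers = k, nstart = n_init, iter.max = 100)
    })
  })
  wss <- vapply(fits, function(f) f$tot.withinss, numeric(1))

  if (criterion == "wss") {
    # geometric elbow: the k whose point on the wss curve lies farthest
    # from the chord joining (1, wss_1) and (k_max, wss_kmax); robust to
    # gradient-structured clusters where a plain second difference always
    # bends at k = 2
    k <- if (k_max < 3) {
      2L
    } else {
      x <- seq_len(k_max)
      y <- wss / max(wss)
      vx <- (k_max - 1) / k_max
      vy <- (y[k_max] - y[1])
      dist_chord <- abs(vx * (y[1] - y) - (x[1] / k_max - x / k_max) * vy)
      cand <- seq(2, k_max - 1)
      cand[which.max(dist_chord[cand])]
    }
    curve <- tibble(k = seq_len(k_max), wss = wss)
  } else {
    d <- dist(scaled)
    sil <- vapply(seq(2, k_max), function(k) {
      mean(cluster::silhouette(fits[[k]]$cluster, d)[, "sil_width"])
    }, numeric(1))
    k <- which.max(sil) + 1L
    # Kaufman-Rousseeuw rule of thumb: below 0.5 the structure is weak
    if (max(sil) < 0.5) {
      warn(sprintf(
        "Weak cluster structure: best mean silhouette width is %.3f.",
        max(sil)))
    }
    curve <- tibble(k = seq(2, k_max), silhouette = sil, wss = wss[-1])
  }
  structure(list(k = k, criterion = criterion, curve = curve),
            class = "k_selection")
}

#' @export
print.k_selection <- function(x, ...) {
  cat("<k_selection> k =", x$k, "by", x$criterion, "criterion\n")
  invisible(x)
}

new_growth_clusters <- function(cultivar, cluster, k, method, fit = NULL) {
  structure(
    tibble(cultivar = cultivar, cluster = as.character(cluster)),
    class = c("growth_clusters", class(tibble())),
    k = k, method = method, fit = fit
  )
}

#' k-means clustering of cultivars
#'
#' Euclidean k-means on scaled traits, keeping the best of `n_init` seeded
#' restarts by total within-cluster sum of squares.
#'
#' @inheritParams select_k
#' @param k Number of clusters (<= number of cultivars).
#' @return A `growth_clusters` tibble (`cultivar`, `cluster`) with
#'   attributes `k`, `method`, and the underlying [stats::kmeans] fit.
#' @export
kmeans_cluster <- function(scaled, k, seed = 1, n_init = 25) {
  scaled <- as.matrix(scaled)
  if (k > nrow(scaled)) abort("`k` cannot exceed the number of cultivars.")
  if (k == nrow(scaled)) {
    # every point its own centroid; Lloyd accepts k = n, Hartigan-Wong
    # does not
    fit <- kmeans(scaled, centers = scaled, iter.max = 2,
                  algorithm = "Lloyd")
  } else {
    fit <- withr::with_seed(derive_seed(seed, 8L), {
      kmeans(scaled, centers = k, nstart = n_init, iter.max = 100)
    })
  }
  new_growth_clusters(rownames(scaled), fit$cluster, k, "kmeans", fit)
}

#' Ward hierarchical clustering of cultivars
#'
#' Agglomerative clustering with Euclidean distance and ward.D2 linkage
#' (merges minimise the increase in within-cluster variance on squared
#' distances), cut at `k` groups.
#'
#' @inheritParams kmeans_cluster
#' @return A `growth_clusters` tibble; the dendrogram is kept in the
#'   `fit` attribute.
#' @export
hierarchical_cluster <- function(scaled, k) {
  scaled <- as.matrix(scaled)
  if (k > nrow(scaled)) abort("`k` cannot exceed the number of cultivars.")
  hc <- hclust(dist(scaled), method = "ward.D2")
  new_growth_clusters(rownames(scaled), cutree(hc, k = k), k, "hierarchical", hc)
}

#' Rank clusters into performance labels
#'
#' Relabels k = 3 clusters `high` / `medium` / `low` by the descending mean
#' of row-summed scaled traits; ties go to the cluster with the heavier
#' mean tuber weight. Other k produce ordered labels `rank1`, `rank2`, ...
#'
#' @param clusters A `growth_clusters` object.
#' @param scaled The scaled trait matrix used for clustering.
#' @param traits Optional raw traits (for the tuber-weight tie-break);
#'   must contain `cultivar` and `tuber_weight`.
#' @return A `growth_clusters` tibble with performance labels.
#' @export
rank_clusters <- function(clusters, scaled, traits = NULL) {
  scaled <- as.matrix(scaled)
  idx <- match(clusters$cultivar, rownames(scaled))
  score <- rowSums(scaled)[idx]
  per <- tapply(score, clusters$cluster, mean)
  tie <- rep(0, length(per))
  if (!is.null(traits) && "tuber_weight" %in% names(traits)) {
    tw <- setNames(traits$tuber_weight, traits$cultivar)[clusters$cultivar]
    tie <- tapply(tw, clusters$cluster, mean)[names(per)]
    tie[is.na(tie)] <- 0
  }
  ord <- order(-per, -tie)
  k <- attr(clusters, "k")
  labels <- if (k == 3) c("high", "medium", "low") else paste0("rank", seq_len(k))
  map <- setNames(labels, names(per)[ord])
  new_growth_clusters(clusters$cultivar, unname(map[clusters$cluster]),
                      k, attr(clusters, "method"), attr(clusters, "fit"))
}

#' Analysis of similarity (ANOSIM)
#'
#' Permutation test of between- versus within-group ranked distances,
#' R = (mean between-group rank - mean within-group rank) / (N(N-1)/4).
#' Backed by [vegan::anosim]; the p-value uses the (count + 1) /
#' (n_perm + 1) estimator.
#'
#' @param dist A distance matrix (square matrix, `dist`, or data produced
#'   by [scale_traits()], in which case Euclidean distances are taken).
#' @param labels Group label per object (>= 2 groups, each of size >= 2).
#' @param n_perm Number of permutations (default 999).
#' @param seed Integer seed.
#' @return Tibble with `R`, `p`, `n_perm`.
#' @export
anosim_test <- function(dist, labels, n_perm = 999, seed = 1) {
  if (is.matrix(dist) && nrow(dist) != ncol(dist)) dist <- stats::dist(dist)
  if (!inherits(dist, "dist")) dist <- stats::as.dist(assert_square_dist(dist))
  labels <- as.factor(labels)
  if (nlevels(labels) < 2 || any(table(labels) < 2)) {
    abort("ANOSIM needs >= 2 groups with >= 2 members each.")
  }
  fit <- withr::with_seed(derive_seed(seed, 9L), {
    vegan::anosim(dist, labels, permutations = n_perm)
  })
  tibble(R = unname(fit$statistic), p = fit$signif, n_perm = n_perm)
}

#' Growth clustering workflow
#'
#' Scales traits, selects k, runs both k-means and Ward clustering, ranks
#' the clusters into performance labels, and tests group separation with
#' ANOSIM on Euclidean trait distances.
#'
#' @inheritParams scale_traits
#' @inheritParams select_k
#' @param k Optional fixed k; when `NULL` it is selected by `criterion`.
#' @param n_perm ANOSIM permutations.
#' @return List with `k`, `selection`, `kmeans`, `hierarchical` (both
#'   ranked `growth_clusters`), `agreement` (label cross-table) and
#'   `anosim` tibble.
#' @export
cluster_growth <- function(traits, k = NULL, k_max = 10,
                           criterion = "wss", n_perm = 999, seed = 1) {
  scaled <- scale_traits(traits)
  sel <- NULL
  if (is.null(k)) {
    sel <- select_k(scaled, k_max = min(k_max, nrow(scaled) - 1),
                    criterion = criterion, seed = seed)
    k <- sel$k
  }
  km <- rank_clusters(kmeans_cluster(scaled, k, seed = seed), scaled, traits)
  hc <- rank_clusters(hierarchical_cluster(scaled, k), scaled, traits)
  an <- anosim_test(dist(scaled), km$cluster, n_perm = n_perm, seed = seed)
  list(k = k, selection = sel, kmeans = km, hierarchical = hc,
       agreement = table(kmeans = km$cluster, hierarchical = hc$cluster),
       anosim = an)
}
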