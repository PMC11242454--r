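test_that("trait scaling gives exact z-scores and rejects constant traits", {
  tr <- tibble::tibble(cultivar = c("a", "b", "c"),
                       x = c(1, 2, 3), y = c(10, 30, 20))
  sc <- scale_traits(tr)
  expect_equal(unname(sc[, "x"]), c(-1, 0, 1))
  expect_true(all(abs(colMeans(sc)) < 1e-12))
  expect_true(all(abs(apply(sc, 2, sd) - 1) < 1e-12))

  expect_error(scale_traits(tibble::tibble(cultivar = c("a", "b"),
                                           x = c(1, 2), flat = c(5, 5))),
               "flat")
})

test_that("k selection finds three separated blobs and degrades gracefully", {
  centers <- rbind(c(0, 0), c(10, 0), c(0, 10))
  hits_wss <- 0
  hits_sil <- 0
  for (s in 1:10) {
    x <- rand_blob_data(12, centers, sd = 1, seed = s)
    hits_wss <- hits_wss + (select_k(x, k_max = 8, "wss", seed = s)$k == 3)
    hits_sil <- hits_sil +
      (select_k(x, k_max = 8, "silhouette", seed = s)$k == 3)
  }
  expect_gte(hits_wss, 9)
  expect_gte(hits_sil, 9)

  # a single blob has no structure: silhouette warns and stays low
  x1 <- rand_blob_data(30, rbind(c(0, 0)), sd = 1, seed = 1)
  expect_warning(sel <- select_k(x1, k_max = 6, "silhouette", seed = 1),
                 "[Ww]eak")
  expect_lt(max(sel$curve$silhouette), 0.4)

  expect_error(select_k(rand_blob_data(5, rbind(c(0, 0)), 1, 1), k_max = 1),
               "k_max")
})

test_that("k-means attains zero within-SS at k = n and is deterministic", {
  x <- rand_blob_data(4, rbind(c(0, 0), c(5, 5)), sd = 0.5, seed = 2)
  rownames(x) <- paste0("cv", 1:8)
  fit_n <- kmeans_cluster(x, k = 8, seed = 1)
  expect_equal(attr(fit_n, "fit")$tot.withinss, 0, tolerance = 1e-12)

  one <- kmeans_cluster(x, k = 1, seed = 1)
  expect_equal(length(unique(one$cluster)), 1)

  expect_identical(kmeans_cluster(x, 2, seed = 5)$cluster,
                   kmeans_cluster(x, 2, seed = 5)$cluster)
  expect_error(kmeans_cluster(x, 9, seed = 1), "exceed")
})

test_that("k-means and Ward clustering both recover separated blobs exactly", {
  centers <- rbind(c(0, 0, 0), c(8, 8, 0), c(0, 8, 8))
  truth <- rep(1:3, each = 10)
  for (s in 1:5) {
    x <- rand_blob_data(10, centers, sd = 0.6, seed = s)
    rownames(x) <- paste0("cv", seq_len(nrow(x)))
    km <- kmeans_cluster(x, 3, seed = s)
    hc <- hierarchical_cluster(x, 3)
    expect_equal(mclust::adjustedRandIndex(km$cluster, truth), 1, info = s)
    expect_equal(mclust::adjustedRandIndex(hc$cluster, truth), 1, info = s)
    expect_equal(mclust::adjustedRandIndex(km$cluster, hc$cluster), 1,
                 info = s)
  }
})

test_that("Ward merge heights match the Lance-Williams recursion on 4 points", {
  # colinear points make merge order hand-checkable
  x <- matrix(c(0, 1, 4, 9), 4, 1,
              dimnames = list(paste0("p", 1:4), "x"))
  hc <- hierarchical_cluster(x, 2)
  fit <- attr(hc, "fit")

  # brute-force ward.D2: merge the pair minimising the ward.D2 distance,
  # updating with the Lance-Williams formula on squared distances
  d2 <- as.matrix(dist(x))^2
  sizes <- rep(1, 4)
  active <- as.list(1:4)
  heights <- numeric(0)
  dmat <- d2
  while (length(active) > 1) {
    n_act <- length(active)
    best <- c(NA, NA)
    best_v <- Inf
    for (i in seq_len(n_act - 1)) {
      for (j in seq(i + 1, n_act)) {
        if (dmat[i, j] < best_v) {
          best_v <- dmat[i, j]
          best <- c(i, j)
        }
      }
    }
    heights <- c(heights, sqrt(best_v))
    i <- best[1]; j <- best[2]
    ni <- sizes[i]; nj <- sizes[j]
    new_row <- vapply(seq_len(n_act), function(k) {
      if (k %in% best) return(NA_real_)
      nk <- sizes[k]
      ((ni + nk) * dmat[i, k] + (nj + nk) * dmat[j, k] -
         nk * best_v) / (ni + nj + nk)
    }, numeric(1))
    keep <- setdiff(seq_len(n_act), best)
    dmat <- rbind(cbind(dmat[keep, keep, drop = FALSE], new_row[keep]),
                  c(new_row[keep], 0))
    sizes <- c(sizes[keep], ni + nj)
    active <- c(active[keep], list(unlist(active[best])))
  }
  expect_equal(unname(fit$height), heights, tolerance = 1e-10)
  expect_true(all(diff(fit$height) >= -1e-12))  # monotone merges

  two <- hierarchical_cluster(x[1:2, , drop = FALSE], 2)
  expect_equal(sort(table(two$cluster)), sort(c(`1` = 1L, `2` = 1L)),
               ignore_attr = TRUE)
})

test_that("cluster ranking orders by performance with a tuber tie-break", {
  sc <- rbind(h1 = c(2, 2), h2 = c(2.2, 2), m1 = c(0, 0), m2 = c(0, 0.1),
              l1 = c(-2, -2), l2 = c(-2, -2.1))
  cl <- rhizocomm:::new_growth_clusters(rownames(sc), c(1, 1, 2, 2, 3, 3), 3, "kmeans")
  ranked <- rank_clusters(cl, sc)
  expect_equal(ranked$cluster, c("high", "high", "medium", "medium",
                                 "low", "low"))

  # permuting input cluster ids leaves performance labels unchanged
  cl2 <- rhizocomm:::new_growth_clusters(rownames(sc), c(3, 3, 1, 1, 2, 2), 3, "kmeans")
  expect_equal(rank_clusters(cl2, sc)$cluster, ranked$cluster)

  # exact tie on summed z-scores resolved by heavier mean tuber weight
  sc_tie <- rbind(a1 = c(1, -1), a2 = c(1, -1), b1 = c(-1, 1), b2 = c(-1, 1),
                  c1 = c(5, 5), c2 = c(5, 5))
  traits <- tibble::tibble(cultivar = rownames(sc_tie),
                           tuber_weight = c(90, 90, 10, 10, 50, 50))
  cl3 <- rhizocomm:::new_growth_clusters(rownames(sc_tie), c(1, 1, 2, 2, 3, 3), 3, "km")
  r3 <- rank_clusters(cl3, sc_tie, traits)
  expect_equal(r3$cluster[1:2], c("medium", "medium"))  # heavier tubers
  expect_equal(r3$cluster[3:4], c("low", "low"))
  expect_equal(r3$cluster[5:6], c("high", "high"))
})

test_that("ANOSIM equals 1 under complete rank separation and matches
           exhaustive enumeration on tiny inputs", {
  # two tight pairs far apart: all between-group distances exceed all
  # within-group distances
  x <- rbind(c(0, 0), c(0.1, 0), c(10, 10), c(10.1, 10))
  lab <- c("a", "a", "b", "b")
  res <- anosim_test(dist(x), lab, n_perm = 199, seed = 1)
  expect_equal(res$R, 1)
  expect_true(res$p > 0 && res$p <= 1)

  # R statistic agrees with the hand formula
  expect_equal(res$R, oracle_anosim_r(dist(x), lab), tolerance = 1e-12)

  # exhaustive check over every labelling of 4 points
  d <- dist(rbind(c(0, 0), c(1, 2), c(3, 1), c(5, 5)))
  labs <- c("a", "a", "b", "b")
  perms <- unique(combinat_perms(labs))
  for (p in perms) {
    expect_equal(anosim_test(d, p, n_perm = 99, seed = 2)$R,
                 oracle_anosim_r(d, p), tolerance = 1e-12)
  }
  expect_error(anosim_test(d, c("a", "b", "b", "b")), "2 members")
})

test_that("the growth workflow recovers planted clusters end to end", {
  traits <- simulate_growth_traits(noise_sd = 0.15, seed = 3)
  res <- cluster_growth(traits, n_perm = 199, seed = 3)
  expect_equal(res$k, 3)
  expect_equal(
    mclust::adjustedRandIndex(res$kmeans$cluster, traits$true_cluster), 1)
  expect_equal(
    mclust::adjustedRandIndex(res$kmeans$cluster, res$hierarchical$cluster), 1)
  expect_gt(res$anosim$R, 0.5)
  expect_lt(res$anosim$p, 0.05)
})
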