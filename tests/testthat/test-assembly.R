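test_that("patristic distances follow single paths and the path-sum oracle", {
  tree <- ape::read.tree(text = "(A:0.3,B:0.7);")
  d <- cophenetic_distances(tree)
  expect_equal(d["A", "B"], 1.0)
  expect_equal(d, t(d))
  expect_true(all(diag(d) == 0))

  tr5 <- simulate_phylogeny(5, seed = 11)
  o <- oracle_cophenetic(tr5)
  expect_equal(cophenetic_distances(tr5)[rownames(o), colnames(o)], o,
               tolerance = 1e-10)
})

test_that("betaMNTD matches hand expansion and is symmetric", {
  d <- matrix(c(0, 1, 3,
                1, 0, 2,
                3, 2, 0), 3, 3,
              dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  # identical communities: every nearest-taxon distance is zero
  p <- c(x = 0.5, y = 0.5, z = 0)
  expect_equal(beta_mntd(p, p, d), 0)

  # single-taxon communities: the only path
  expect_equal(beta_mntd(c(x = 1, y = 0, z = 0), c(x = 0, y = 1, z = 0),
                         matrix(c(0, 2, 2, 0), 2, 2,
                                dimnames = list(c("x", "y"), c("x", "y")))),
               2)

  # worked 3-taxon case, expanded by hand:
  # A = (0.5, 0.5, 0), B = (0, 0.5, 0.5)
  # from A: x -> nearest of {y,z} = d(x,y) = 1; y -> y = 0
  # from B: y -> y = 0; z -> nearest of {x,y} = d(z,y) = 2
  # 0.5 * (0.5*1 + 0.5*0 + 0.5*0 + 0.5*2) = 0.75
  pa <- c(x = 0.5, y = 0.5, z = 0)
  pb <- c(x = 0, y = 0.5, z = 0.5)
  expect_equal(beta_mntd(pa, pb, d), 0.75)
  expect_equal(beta_mntd(pb, pa, d), beta_mntd(pa, pb, d))

  expect_error(beta_mntd(c(x = 0, y = 0, z = 0), pb, d), "Empty")
})

test_that("the all-pairs engine agrees with the scalar reference and oracle", {
  tr <- simulate_phylogeny(12, seed = 21)
  d <- cophenetic_distances(tr)
  withr::with_seed(21, {
    m <- matrix(rpois(5 * 12, 2), 5, 12,
                dimnames = list(paste0("S", 1:5), tr$tip.label))
  })
  m[m == 0 | col(m) > 8] <- 0  # sparsify
  m[, 1] <- pmax(m[, 1], 1)    # keep all samples non-empty
  bm <- beta_mntd_all(make_ft(m), tr)
  for (a in 1:4) {
    for (b in seq(a + 1, 5)) {
      expect_equal(bm[a, b], beta_mntd(m[a, ], m[b, ], d), tolerance = 1e-10)
      expect_equal(bm[a, b], oracle_bmntd(m[a, ], m[b, ], d),
                   tolerance = 1e-10)
    }
  }
})

test_that("betaMNTD agrees with picante's comdistnt cross-check", {
  tr <- simulate_phylogeny(15, seed = 31)
  withr::with_seed(31, {
    m <- matrix(rpois(4 * 15, 3), 4, 15,
                dimnames = list(paste0("S", 1:4), tr$tip.label))
  })
  m[1, ] <- pmax(m[1, ], 1)
  got <- beta_mntd_all(make_ft(m), tr)
  ref <- as.matrix(picante::comdistnt(m, cophenetic_distances(tr),
                                      abundance.weighted = TRUE))
  expect_equal(got[rownames(ref), colnames(ref)], ref, tolerance = 1e-8)
})

test_that("betaNTI flags degenerate nulls and is invariant to branch scaling", {
  # star phylogeny: shuffles cannot change any distance
  star <- ape::read.tree(text = "(A:1,B:1,C:1,D:1,E:1);")
  withr::with_seed(2, {
    m <- matrix(rpois(3 * 5, 4) + 1, 3, 5,
                dimnames = list(paste0("S", 1:3), star$tip.label))
  })
  bn <- beta_nti(make_ft(m), star, n_null = 100, seed = 1)
  expect_true(all(bn$degenerate[upper.tri(bn$degenerate)]))
  expect_true(all(is.na(bn$bnti[upper.tri(bn$bnti)])))

  # scaling all branch lengths by 10 leaves the z-score unchanged
  tr <- simulate_phylogeny(20, seed = 41)
  withr::with_seed(41, {
    m2 <- matrix(rpois(6 * 20, 2), 6, 20,
                 dimnames = list(paste0("S", 1:6), tr$tip.label))
  })
  m2[, 1] <- pmax(m2[, 1], 1)
  tr10 <- tr
  tr10$edge.length <- tr$edge.length * 10
  b1 <- beta_nti(make_ft(m2), tr, n_null = 200, seed = 7)
  b2 <- beta_nti(make_ft(m2), tr10, n_null = 200, seed = 7)
  expect_equal(b1$bnti, b2$bnti, tolerance = 1e-6)
  expect_equal(b1$bnti, t(b1$bnti))

  expect_error(beta_nti(make_ft(m2), tr, n_null = 50), "100")
})

test_that("RCbray is bounded and hits its tails on planted structure", {
  # identical high-richness pair inside a heterogeneous pool
  withr::with_seed(5, {
    pool <- matrix(rpois(8 * 40, 2), 8, 40)
  })
  pool[1, ] <- pool[2, ] <- rpois(40, 3) + 1
  rownames(pool) <- paste0("S", 1:8)
  colnames(pool) <- paste0("t", 1:40)
  pool[rowSums(pool) == 0, 1] <- 1
  rc <- raup_crick_bray(make_ft(pool), n_null = 200, seed = 3)
  expect_true(all(rc >= -1 & rc <= 1))
  expect_lt(rc["S1", "S2"], -0.95)

  # samples from disjoint taxon pools are less similar than null
  withr::with_seed(6, {
    ab <- matrix(0, 6, 40, dimnames = list(paste0("S", 1:6),
                                           paste0("t", 1:40)))
    for (s in 1:3) ab[s, 1:20] <- rpois(20, 4) + 1
    for (s in 4:6) ab[s, 21:40] <- rpois(20, 4) + 1
  })
  rc2 <- raup_crick_bray(make_ft(ab), n_null = 200, seed = 4)
  expect_gt(rc2["S1", "S4"], 0.95)
  expect_gt(min(rc2[1:3, 4:6]), 0.95)

  # invariant to taxon relabeling
  perm <- sample(ncol(ab))
  ab_perm <- ab[, perm]
  rc3 <- raup_crick_bray(make_ft(ab_perm), n_null = 200, seed = 4)
  expect_equal(rc2, rc3, tolerance = 1e-12)

  empty <- make_ft(rbind(S1 = c(1, 2), S2 = c(0, 0)))
  expect_error(raup_crick_bray(empty, n_null = 100), "richness")
})

test_that("process classification applies the exact thresholds", {
  expect_equal(classify_process(2.5, 0.0), "heterogeneous_selection")
  expect_equal(classify_process(-2.5, 0.0), "homogeneous_selection")
  expect_equal(classify_process(0.5, 0.97), "dispersal_limitation")
  expect_equal(classify_process(0.1, -0.97), "homogenizing_dispersal")
  expect_equal(classify_process(0.0, 0.0), "undominated")

  # boundary values belong to the stochastic / undominated side
  expect_equal(classify_process(2, 0), "undominated")
  expect_equal(classify_process(-2, 0), "undominated")
  expect_equal(classify_process(0, 0.95), "undominated")
  expect_equal(classify_process(0, -0.95), "undominated")

  expect_true(is.na(classify_process(NA, 0.5)))
  expect_error(classify_process(NaN, 0), "NaN")
})

test_that("assembly fractions sum to one and respect pair grouping", {
  pw <- tibble::tibble(
    group = rep(c("g1", "g2"), c(4, 3)),
    process = c(rep("homogeneous_selection", 4),
                "undominated", "undominated", NA)
  )
  fr <- summarize_fractions(pw)
  g1 <- fr[fr$group == "g1", ]
  expect_equal(sum(g1$fraction), 1)
  expect_equal(g1$fraction[g1$process == "homogeneous_selection"], 1)
  g2 <- fr[fr$group == "g2", ]
  expect_equal(sum(g2$fraction), 1)
  expect_equal(unique(g2$n_unclassifiable), 1)

  # within-group analysis only classifies within-group pairs
  ds <- simulate_dataset(n_cultivars = 4, n_replicates = 2, n_taxa = 30,
                         depth = 400, seed = 2)
  res <- assembly_analysis(
    ds$table, ds$tree,
    groups = tibble::tibble(sample_id = ds$metadata$sample_id,
                            group = ds$metadata$growth_cluster),
    pairs = "within", n_null = 100, seed = 1)
  expect_true(all(res$group != "between"))
  res_all <- assembly_analysis(ds$table, ds$tree, pairs = "all",
                               n_null = 100, seed = 1)
  expect_equal(nrow(res_all), choose(8, 2))
})
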