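# Synthetic-data generators: phylogenies, phylogenetically conserved niche
# optima, community tables under controllable assembly regimes, growth traits
# with planted cluster structure, and clade-based taxonomies.
#
# The generative model is a niche-filtering multinomial sampler: each taxon
# carries a Brownian-motion trait optimum evolved on the phylogeny, each
# sample an environmental value, and sampling weights are the metacommunity
# abundance damped by a Gaussian filter exp(-(optimum - env)^2 / (2 sd^2)).
# This is the minimal model under which the phylogenetic null behind betaNTI
# is informative: selection concentrates communities on related taxa.

#' Simulate a pure-birth phylogeny
#'
#' Generates a rooted binary tree with `n_taxa` tips under a pure-birth
#' (Yule) process and relabels the tips `ASV0001`, `ASV0002`, ...
#'
#' @param n_taxa Number of tips (>= 2).
#' @param seed Integer seed; identical seeds give identical trees.
#' @return An [ape::phylo] object with positive branch lengths.
#' @export
#' @examples
#' tr <- simulate_phylogeny(10, seed = 1)
simulate_phylogeny <- function(n_taxa, seed = 1) {
  if (!is.numeric(n_taxa) || n_taxa < 2) {
    abort("`n_taxa` must be an integer >= 2.")
  }
  n_taxa <- as.integer(n_taxa)
  tree <- withr::with_seed(derive_seed(seed, 1L), {
    ape::rphylo(n_taxa, birth = 1, death = 0)
  })
  tree$tip.label <- sprintf("ASV%04d", seq_len(n_taxa))
  tree
}

#' Evolve niche optima along a phylogeny by Brownian motion
#'
#' Walks from the root to every tip adding independent Gaussian increments
#' with variance `bm_sd^2 * branch_length`, so closely related taxa end up
#' with similar optima (phylogenetic signal). With `bm_sd = 0` all tips
#' inherit the root value of 0. With `rate_decay > 0` the rate declines
#' exponentially with time from the root (an early-burst model): niche
#' divergence concentrates in deep splits, giving strongly conserved
#' optima within clades — the regime-recovery experiments rely on this.
#'
#' @param tree An [ape::phylo] phylogeny with branch lengths.
#' @param bm_sd Brownian-motion rate (standard deviation per unit branch
#'   length), >= 0.
#' @param seed Integer seed.
#' @param standardize If `TRUE`, centre and scale the tip optima to mean 0
#'   and sd 1 so that selection widths are expressed in optimum-sd units.
#' @param rate_decay Exponential decay of the Brownian rate with node
#'   depth (0 = constant rate, i.e. plain Brownian motion).
#' @return Named numeric vector of one optimum per tip.
#' @export
simulate_trait_optima <- function(tree, bm_sd = 1, seed = 1,
                                  standardize = FALSE, rate_decay = 0) {
  if (!inherits(tree, "phylo")) abort("`tree` must be a `phylo` object.")
  if (!is.numeric(bm_sd) || bm_sd < 0) abort("`bm_sd` must be >= 0.")
  if (!is.numeric(rate_decay) || rate_decay < 0) {
    abort("`rate_decay` must be >= 0.")
  }
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  tr <- ape::reorder.phylo(tree, "cladewise")  # root-to-tip edge order
  depth <- numeric(n_node)
  for (i in seq_len(nrow(tr$edge))) {
    depth[tr$edge[i, 2]] <- depth[tr$edge[i, 1]] + tr$edge.length[i]
  }
  # per-edge trait variance: bm_sd^2 * integral of exp(-rate_decay * t)
  # over the edge's time span (reduces to the branch length at decay 0)
  edge_var <- vapply(seq_len(nrow(tr$edge)), function(i) {
    t0 <- depth[tr$edge[i, 1]]
    t1 <- depth[tr$edge[i, 2]]
    if (rate_decay > 0) {
      (exp(-rate_decay * t0) - exp(-rate_decay * t1)) / rate_decay
    } else {
      t1 - t0
    }
  }, numeric(1))
  val <- numeric(n_node)
  withr::with_seed(derive_seed(seed, 2L), {
    steps <- rnorm(nrow(tr$edge), mean = 0,
                   sd = bm_sd * sqrt(pmax(edge_var, 0)))
    for (i in seq_len(nrow(tr$edge))) {
      val[tr$edge[i, 2]] <- val[tr$edge[i, 1]] + steps[i]
    }
  })
  opt <- val[seq_len(n_tip)]
  names(opt) <- tr$tip.label
  if (standardize) {
    s <- sd(opt)
    opt <- if (s > 0) (opt - mean(opt)) / s else opt - mean(opt)
  }
  opt[tree$tip.label]
}

#' Describe a community assembly regime
#'
#' Bundles the parameters of the generative model for one of the five
#' assembly processes the null-model classifier distinguishes.
#'
#' @param name One of `"neutral"`, `"homogeneous_selection"`,
#'   `"heterogeneous_selection"`, `"homogenizing_dispersal"`,
#'   `"dispersal_limitation"`.
#' @param selection_sd Width of the Gaussian environmental filter, in the
#'   units of the trait optima (> 0). Small values mean strong selection.
#' @param env_values Optional environmental value(s): one per sample
#'   (recycled) for selection regimes. Defaults are derived from the optima
#'   at simulation time: the median for homogeneous selection, an even grid
#'   across the 5%-95% optimum quantiles for heterogeneous selection.
#' @param dispersal_mix Fraction in \[0, 1\] of each sample's reads drawn
#'   from a common dispersal pool (homogenizing dispersal only).
#' @param pool_overlap Fraction in \[0, 1\] of taxa shared between group
#'   pools (dispersal limitation only; 0 = fully disjoint pools).
#' @param group_size Samples per isolated pool under dispersal limitation.
#' @return An `assembly_regime` object (a validated list).
#' @export
assembly_regime <- function(name = c("neutral", "homogeneous_selection",
                                     "heterogeneous_selection",
                                     "homogenizing_dispersal",
                                     "dispersal_limitation"),
                            selection_sd = 0.05, env_values = NULL,
                            dispersal_mix = 0.95, pool_overlap = 0,
                            group_size = 4) {
  name <- match.arg(name)
  if (!is.numeric(selection_sd) || selection_sd <= 0) {
    abort("`selection_sd` must be > 0.")
  }
  if (dispersal_mix < 0 || dispersal_mix > 1) abort("`dispersal_mix` must be in [0, 1].")
  if (pool_overlap < 0 || pool_overlap > 1) abort("`pool_overlap` must be in [0, 1].")
  structure(
    list(name = name, selection_sd = selection_sd, env_values = env_values,
         dispersal_mix = dispersal_mix, pool_overlap = pool_overlap,
         group_size = as.integer(group_size)),
    class = "assembly_regime"
  )
}

#' @export
print.assembly_regime <- function(x, ...) {
  cat("<assembly_regime>", x$name, "\n")
  cat("  selection_sd:", x$selection_sd,
      " dispersal_mix:", x$dispersal_mix,
      " pool_overlap:", x$pool_overlap, "\n")
  invisible(x)
}

#' Simulate a community feature table under an assembly regime
#'
#' Draws one multinomial community per sample at the requested sequencing
#' depth. Metacommunity abundances come from a lognormal(0, 1) rank-abundance
#' curve; per-sample occupancy subsets emulate dispersal/drift; the Gaussian
#' niche filter on `optima` emulates selection. See [assembly_regime()] for
#' the per-regime mechanics.
#'
#' @param tree Phylogeny whose tips define the taxon universe.
#' @param optima Named optimum per tip (see [simulate_trait_optima()]).
#' @param regime An [assembly_regime()].
#' @param n_samples Number of samples (>= 2).
#' @param depth Reads per sample (>= 1).
#' @param seed Integer seed.
#' @param groups Optional character vector of group labels per sample;
#'   under dispersal limitation each group receives its own taxon pool,
#'   and under selection regimes `env_values` may be given per group level.
#' @return A list with `table` (feature-table tibble of counts), `metadata`
#'   (tibble: `sample_id`, `group`, `env`, `regime`).
#' @export
simulate_community <- function(tree, optima, regime, n_samples = 30,
                               depth = 5000, seed = 1, groups = NULL) {
  if (!inherits(regime, "assembly_regime")) {
    abort("`regime` must be created with assembly_regime().")
  }
  if (!is.numeric(depth) || depth < 1) abort("`depth` must be >= 1.")
  if (!is.numeric(n_samples) || n_samples < 2) abort("`n_samples` must be >= 2.")
  n_samples <- as.integer(n_samples)
  depth <- as.integer(depth)
  taxa <- tree$tip.label
  S <- length(taxa)
  optima <- optima[taxa]
  if (anyNA(optima)) abort("`optima` must cover every tree tip.")

  sample_ids <- sprintf("S%03d", seq_len(n_samples))
  if (!is.null(groups)) {
    groups <- rep_len(as.character(groups), n_samples)
  }

  # Stage 1: metacommunity structure shared by all regimes.
  meta <- withr::with_seed(derive_seed(seed, 3L), {
    list(m = rlnorm(S, 0, 1), occ = runif(S, 0.35, 0.95))
  })
  m <- meta$m

  env <- rep(NA_real_, n_samples)
  counts <- withr::with_seed(derive_seed(seed, 4L), {
    W <- matrix(0, n_samples, S)
    backbone <- NULL
    own_depth <- depth

    if (regime$name == "neutral") {
      avail <- matrix(runif(n_samples * S) < rep(meta$occ, each = n_samples),
                      n_samples, S)
      W <- avail * rep(m, each = n_samples)
      if (is.null(groups)) groups <- rep("G1", n_samples)
    } else if (regime$name %in% c("homogeneous_selection",
                                  "heterogeneous_selection")) {
      env_def <- if (regime$name == "homogeneous_selection") {
        rep(median(optima), n_samples)
      } else {
        seq(quantile(optima, 0.05), quantile(optima, 0.95),
            length.out = n_samples)
      }
      if (!is.null(regime$env_values)) {
        ev <- regime$env_values
        env <- if (!is.null(groups) && !is.null(names(ev))) {
          unname(ev[groups])
        } else {
          rep_len(ev, n_samples)
        }
      } else {
        env <- env_def
      }
      filt <- exp(-outer(env, optima, "-")^2 / (2 * regime$selection_sd^2))
      # occupancy subsets: each sample sees its own draw of the
      # metacommunity, so selected communities overlap in clades rather
      # than in identical taxon sets
      avail <- matrix(runif(n_samples * S) < rep(meta$occ, each = n_samples),
                      n_samples, S)
      W <- filt * avail * rep(m, each = n_samples)
      # Guard against an empty niche: fall back to the closest taxon.
      for (s in seq_len(n_samples)) {
        if (sum(W[s, ]) <= 0) W[s, which.min(abs(optima - env[s]))] <- 1
      }
      if (is.null(groups)) groups <- rep("G1", n_samples)
    } else if (regime$name == "dispersal_limitation") {
      if (is.null(groups)) {
        n_groups <- ceiling(n_samples / regime$group_size)
        groups <- sprintf("G%02d", rep(seq_len(n_groups),
                                       each = regime$group_size)[seq_len(n_samples)])
      }
      glev <- unique(groups)
      shared_n <- round(regime$pool_overlap * S)
      shared <- if (shared_n > 0) sample.int(S, shared_n) else integer(0)
      rest <- setdiff(sample.int(S, S), shared)  # shuffled remainder
      pools <- split(rest, rep_len(seq_along(glev), length(rest)))
      names(pools) <- glev
      for (s in seq_len(n_samples)) {
        pool <- c(pools[[groups[s]]], shared)
        W[s, pool] <- m[pool]
      }
    } else if (regime$name == "homogenizing_dispersal") {
      # Mass dispersal: a common backbone of reads literally shared by all
      # samples, plus sample-specific drift reads from occupancy subsets.
      # The backbone is drawn from a restricted common pool so that samples
      # do not trivially contain the whole taxon universe.
      n_shared <- round(regime$dispersal_mix * depth)
      own_depth <- depth - n_shared
      common_pool <- runif(S) < 0.6
      if (!any(common_pool)) common_pool[which.max(m)] <- TRUE
      backbone <- as.vector(rmultinom(1, n_shared, m * common_pool))
      avail <- matrix(runif(n_samples * S) < rep(meta$occ, each = n_samples),
                      n_samples, S)
      W <- avail * rep(m, each = n_samples)
      if (is.null(groups)) groups <- rep("G1", n_samples)
    }

    x <- matrix(0L, n_samples, S, dimnames = list(sample_ids, taxa))
    for (s in seq_len(n_samples)) {
      w <- W[s, ]
      if (sum(w) <= 0) w <- m
      drawn <- if (own_depth > 0) as.vector(rmultinom(1, own_depth, w)) else 0L
      x[s, ] <- drawn + if (is.null(backbone)) 0L else backbone
    }
    x
  })

  list(
    table = ft_tibble(counts),
    metadata = tibble(sample_id = sample_ids, group = groups, env = env,
                      regime = regime$name)
  )
}

#' Default growth-trait cluster means
#'
#' Greenhouse-scale potato growth parameters (shoot fresh/dry weight in g,
#' leaf count, total tuber weight in g, tuber number) for high-, medium- and
#' low-performing cultivar clusters.
#'
#' @return A 3 x 5 numeric matrix with named rows and columns.
#' @export
default_cluster_means <- function() {
  matrix(
    c(120, 18, 60, 90, 12,
      80, 12, 45, 60, 8,
      45, 7, 30, 30, 5),
    nrow = 3, byrow = TRUE,
    dimnames = list(
      c("high", "medium", "low"),
      c("shoot_fresh_weight", "shoot_dry_weight", "leaf_count",
        "tuber_weight", "tuber_number")
    )
  )
}

#' Simulate cultivar growth traits with planted clusters
#'
#' Assigns cultivars to `n_clusters` latent performance groups of nearly
#' equal size and draws each trait around its cluster mean. Noise is scaled
#' per trait by the between-cluster spread of that trait, so `noise_sd` is
#' the within-cluster sd expressed in units of between-cluster sd.
#'
#' @param n_cultivars Number of cultivars (default 51, the study design).
#' @param n_clusters Number of planted clusters (<= `n_cultivars`).
#' @param cluster_means Matrix of `n_clusters` rows x traits; defaults to
#'   [default_cluster_means()] (requires `n_clusters = 3`).
#' @param noise_sd Within-cluster noise, in between-cluster-sd units.
#' @param seed Integer seed.
#' @return Tibble with `cultivar`, one column per trait, and the planted
#'   `true_cluster` label.
#' @export
simulate_growth_traits <- function(n_cultivars = 51, n_clusters = 3,
                                   cluster_means = NULL, noise_sd = 0.15,
                                   seed = 1) {
  if (n_clusters > n_cultivars) abort("`n_clusters` cannot exceed `n_cultivars`.")
  if (is.null(cluster_means)) {
    if (n_clusters != 3) abort("Supply `cluster_means` when `n_clusters` != 3.")
    cluster_means <- default_cluster_means()
  }
  cluster_means <- as.matrix(cluster_means)
  if (nrow(cluster_means) != n_clusters) {
    abort("`cluster_means` must have `n_clusters` rows.")
  }
  if (is.null(rownames(cluster_means))) {
    rownames(cluster_means) <- paste0("C", seq_len(n_clusters))
  }
  trait_names <- colnames(cluster_means) %||%
    paste0("trait_", seq_len(ncol(cluster_means)))
  scale_t <- apply(cluster_means, 2, sd)
  scale_t[scale_t == 0 | is.na(scale_t)] <- 1

  withr::with_seed(derive_seed(seed, 5L), {
    labels <- sample(rep_len(seq_len(n_clusters), n_cultivars))
    noise <- matrix(rnorm(n_cultivars * length(trait_names)),
                    n_cultivars, length(trait_names))
    vals <- cluster_means[labels, , drop = FALSE] +
      noise * rep(noise_sd * scale_t, each = n_cultivars)
    if (noise_sd > 0) vals <- pmax(vals, 0)
    out <- dplyr::bind_cols(
      tibble(cultivar = sprintf("CV%02d", seq_len(n_cultivars))),
      as_tibble(`colnames<-`(vals, trait_names), .name_repair = "minimal"),
      tibble(true_cluster = rownames(cluster_means)[labels])
    )
    out
  })
}

#' Simulate a ranked taxonomy from tree clades
#'
#' Cuts the cophenetic dendrogram of the phylogeny into nested clades to
#' produce a consistent domain-to-genus lineage per taxon. A fraction of
#' taxa is left unclassified at the genus (and occasionally family) rank,
#' recorded as `NA`, mirroring real amplicon taxonomies.
#'
#' @param tree Phylogeny.
#' @param n_genera Number of genus-level clades.
#' @param p_unclassified Probability a taxon lacks a genus label.
#' @param seed Integer seed.
#' @return Tibble: `taxon_id`, `domain`, `phylum`, `class`, `order`,
#'   `family`, `genus` (missing ranks are `NA`).
#' @export
simulate_taxonomy <- function(tree, n_genera = 25, p_unclassified = 0.15,
                              seed = 1) {
  n_tip <- length(tree$tip.label)
  n_genera <- min(n_genera, n_tip)
  hc <- hclust(stats::as.dist(ape::cophenetic.phylo(tree)), method = "average")
  ranks <- list(
    phylum = max(2L, min(3L, n_tip)),
    class  = max(2L, min(6L, n_tip)),
    order  = max(2L, min(round(n_genera / 3), n_tip)),
    family = max(2L, min(round(n_genera / 2), n_tip)),
    genus  = n_genera
  )
  cuts <- lapply(ranks, function(k) cutree(hc, k = k))
  lineage <- tibble(
    taxon_id = tree$tip.label,
    domain = "Bacteria",
    phylum = sprintf("Phylum_%02d", cuts$phylum[tree$tip.label]),
    class = sprintf("Class_%02d", cuts$class[tree$tip.label]),
    order = sprintf("Order_%02d", cuts$order[tree$tip.label]),
    family = sprintf("Family_%02d", cuts$family[tree$tip.label]),
    genus = sprintf("Genus_%02d", cuts$genus[tree$tip.label])
  )
  withr::with_seed(derive_seed(seed, 6L), {
    u <- runif(n_tip)
    lineage$genus[u < p_unclassified] <- NA_character_
    lineage$family[u < p_unclassified / 3] <- NA_character_
  })
  lineage
}

#' Simulate a complete study-shaped dataset
#'
#' Builds a phylogeny, niche optima, taxonomy, cultivar growth traits with
#' planted performance clusters, and a community table of
#' `n_cultivars * n_replicates` rhizosphere samples. Under selection
#' regimes each growth cluster receives its own environmental value
#' (emulating cluster-specific root-exudate environments); under dispersal
#' limitation pools are per growth cluster.
#'
#' @param n_cultivars,n_replicates Study design (defaults 10 x 3; the full
#'   emulation of the 51 x 3 design is obtained with `n_cultivars = 51`).
#' @param n_taxa,depth Community dimensions.
#' @param regime An [assembly_regime()]; default homogeneous selection.
#' @param bm_sd Brownian rate for niche optima.
#' @param n_genera Genus-level clades in the taxonomy.
#' @param seed Integer seed.
#' @return A list: `table`, `tree`, `taxonomy`, `metadata`, `traits`,
#'   `true_labels`.
#' @export
simulate_dataset <- function(n_cultivars = 10, n_replicates = 3,
                             n_taxa = 150, depth = 5000,
                             regime = assembly_regime("homogeneous_selection"),
                             bm_sd = 1, n_genera = 25, seed = 1,
                             rate_decay = 2) {
  tree <- simulate_phylogeny(n_taxa, seed = seed)
  optima <- simulate_trait_optima(tree, bm_sd = bm_sd, seed = seed,
                                  standardize = TRUE,
                                  rate_decay = rate_decay)
  taxonomy <- simulate_taxonomy(tree, n_genera = n_genera, seed = seed)
  traits <- simulate_growth_traits(n_cultivars = n_cultivars, seed = seed)

  cultivars <- rep(traits$cultivar, each = n_replicates)
  clusters <- rep(traits$true_cluster, each = n_replicates)
  n_samples <- length(cultivars)

  reg <- regime
  if (reg$name %in% c("homogeneous_selection", "heterogeneous_selection") &&
      is.null(reg$env_values)) {
    lev <- unique(clusters)
    reg$env_values <- setNames(
      quantile(optima, seq(0.2, 0.8, length.out = length(lev)), names = FALSE),
      lev
    )
  }
  sim <- simulate_community(tree, optima, reg, n_samples = n_samples,
                            depth = depth, seed = seed, groups = clusters)

  metadata <- tibble(
    sample_id = sim$metadata$sample_id,
    cultivar = cultivars,
    replicate = rep(seq_len(n_replicates), times = n_cultivars),
    growth_cluster = clusters,
    env = sim$metadata$env
  )
  list(
    table = sim$table,
    tree = tree,
    taxonomy = taxonomy,
    metadata = metadata,
    traits = traits,
    true_labels = tibble(sample_id = metadata$sample_id,
                         cluster = clusters, regime = reg$name)
  )
}
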