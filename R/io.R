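# File formats, configuration and the end-to-end pipeline. Samples are rows
# in every table on disk; identifiers are opaque whitespace-free strings.

#' Read a feature table from TSV
#'
#' Expects a header row, a `sample_id` first column and one numeric column
#' per taxon.
#'
#' @param path Path to a tab-separated file.
#' @return Feature-table tibble.
#' @export
read_feature_table <- function(path) {
  raw <- readr::read_tsv(path, show_col_types = FALSE)
  probs <- readr::problems(raw)
  if (nrow(probs) > 0) {
    abort(paste0("Parse problems in ", path, " (first at line ",
                 probs$row[1], "): ", probs$expected[1]))
  }
  names(raw)[1] <- "sample_id"
  raw$sample_id <- as.character(raw$sample_id)
  if (anyDuplicated(raw$sample_id)) {
    abort(paste0("Duplicate sample ids in ", path, " at line(s) ",
                 paste(which(duplicated(raw$sample_id)) + 1, collapse = ", ")))
  }
  vals <- as.matrix(raw[-1])
  if (!is.numeric(vals)) abort(paste0("Non-numeric abundance column in ", path))
  bad <- which(vals < 0, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    abort(sprintf("Negative value at line %d, taxon `%s` in %s",
                  bad[1, 1] + 1, colnames(vals)[bad[1, 2]], path))
  }
  raw
}

#' Write a feature table to TSV
#'
#' @param table Feature-table tibble or matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path) {
  tbl <- if (is.matrix(table)) ft_tibble(table) else table
  readr::write_tsv(tbl, path)
  invisible(path)
}

#' Read a rooted Newick tree
#'
#' @param path Path to a Newick file; branch lengths are required (they
#'   drive UniFrac and betaMNTD).
#' @return An [ape::phylo] object.
#' @export
read_tree <- function(path) {
  tree <- tryCatch(ape::read.tree(path),
                   error = function(e) abort(paste0("Unparseable Newick: ",
                                                    conditionMessage(e))))
  if (is.null(tree)) abort(paste0("Unparseable Newick file: ", path))
  if (is.null(tree$edge.length) || anyNA(tree$edge.length)) {
    abort("Tree has missing branch lengths; lengths are required.")
  }
  tree
}

#' Write a tree to Newick
#' @param tree `phylo` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tree <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Write a square distance matrix as TSV (ids in header and first column)
#' @param dist Distance matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_distance_matrix <- function(dist, path) {
  d <- assert_square_dist(dist)
  out <- dplyr::bind_cols(tibble(sample_id = rownames(d)),
                          as_tibble(d, .name_repair = "minimal"))
  readr::write_tsv(out, path)
  invisible(path)
}

#' Read a square distance matrix written by [write_distance_matrix()]
#' @param path Input path.
#' @return Symmetric matrix with dimnames.
#' @export
read_distance_matrix <- function(path) {
  raw <- readr::read_tsv(path, show_col_types = FALSE)
  d <- as.matrix(raw[-1])
  rownames(d) <- as.character(raw[[1]])
  assert_square_dist(d)
}

#' Write the edge list of an association network as TSV
#' @param network An `assoc_network`.
#' @param path Output path.
#' @param kept_only Write only retained edges (default TRUE).
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(network, path, kept_only = TRUE) {
  ed <- network$edges
  if (kept_only) ed <- ed[ed$keep, , drop = FALSE]
  mod <- network$modules$membership
  ed$module_from <- unname(mod[ed$from])
  ed$module_to <- unname(mod[ed$to])
  readr::write_tsv(ed, path)
  invisible(path)
}

#' Write an association network as GraphML with node attributes
#' @param network An `assoc_network`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(network, path) {
  g <- network$graph
  nd <- network$nodes
  idx <- match(igraph::V(g)$name, nd$node)
  igraph::V(g)$module <- nd$module[idx]
  igraph::V(g)$hub <- nd$hub[idx]
  igraph::V(g)$mean_rel_abundance <- nd$mean_rel_abundance[idx]
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Write a simulated dataset to a directory
#'
#' Emits feature table, Newick tree, taxonomy, metadata and traits TSVs
#' plus a JSON manifest recording the generator parameters.
#'
#' @param dataset Result of [simulate_dataset()].
#' @param dir Output directory (created if needed).
#' @param params Optional list recorded in the manifest.
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir, params = list()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_feature_table(dataset$table, file.path(dir, "feature_table.tsv"))
  write_tree(dataset$tree, file.path(dir, "tree.nwk"))
  readr::write_tsv(dataset$taxonomy, file.path(dir, "taxonomy.tsv"))
  readr::write_tsv(dataset$metadata, file.path(dir, "metadata.tsv"))
  readr::write_tsv(dataset$traits, file.path(dir, "traits.tsv"))
  readr::write_tsv(dataset$true_labels, file.path(dir, "true_labels.tsv"))
  jsonlite::write_json(params, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}

pipeline_defaults <- function() {
  list(
    seed = 1,
    out_dir = NULL,
    input_dir = NULL,
    simulate = NULL,          # list of simulate_dataset() arguments, or NULL
    group_col = "growth_cluster",
    min_reps = 2,
    prevalence_min = 0.80,
    abundance_min = 1e-4,
    k = NULL,
    k_max = 10,
    criterion = "wss",
    n_perm = 999,
    n_null = 1000,
    pairs = "within",
    r_min = 0.3,
    alpha = 1e-4,
    lfdr_max = 0.2,
    hub_quantile = 0.95
  )
}

#' Validated pipeline configuration
#'
#' All defaults equal the workflow's reference values (999 PERMANOVA
#' permutations, 1000 null-model iterations, 0.3/alpha/0.2 network
#' sparsification, 80%/0.01% core rule, two-of-three replicate filter).
#' Unknown keys are rejected before anything runs.
#'
#' @param ... Overrides of the defaults; see [run_pipeline()].
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(...) {
  cfg <- pipeline_defaults()
  ov <- list(...)
  unknown <- setdiff(names(ov), names(cfg))
  if (length(unknown) > 0) {
    abort(paste0("Unknown config key(s): ", paste(unknown, collapse = ", ")))
  }
  cfg[names(ov)] <- ov
  if (is.null(cfg$out_dir)) abort("`out_dir` is required.")
  if (is.null(cfg$input_dir) && is.null(cfg$simulate)) {
    abort("Provide `input_dir` or `simulate` parameters.")
  }
  structure(cfg, class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Executes, in order: (optional) simulation, growth clustering,
#' preprocessing (singletons, two-of-three replicate filter, TSS, core
#' microbiome by growth cluster), diversity (alpha metrics, weighted
#' UniFrac, PCoA, PERMANOVA, pairwise Wilcoxon on alpha metrics),
#' assembly (betaNTI + RCbray + process fractions) and per-group
#' co-occurrence networks. Each stage writes into its own subdirectory of
#' `out_dir` and never mutates its inputs; a manifest with parameters,
#' seed and per-file checksums makes runs reproducible.
#'
#' @param config A [pipeline_config()].
#' @return A list of in-memory stage results (invisibly), with the
#'   manifest path in `$manifest`.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config")) {
    abort("`config` must be created with pipeline_config().")
  }
  cfg <- config
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  stage_dir <- function(name) {
    d <- file.path(cfg$out_dir, name)
    dir.create(d, showWarnings = FALSE)
    d
  }
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("Pipeline stage `%s` failed: %s", name,
                    conditionMessage(e)))
    })
  }

  # inputs
  if (!is.null(cfg$simulate)) {
    ds <- run_stage("simulate", {
      args <- cfg$simulate
      args$seed <- args$seed %||% cfg$seed
      do.call(simulate_dataset, args)
    })
    write_dataset(ds, stage_dir("00_input"),
                  params = c(cfg$simulate, list(seed = cfg$seed)))
  } else {
    ds <- run_stage("read_input", {
      d <- cfg$input_dir
      list(
        table = read_feature_table(file.path(d, "feature_table.tsv")),
        tree = read_tree(file.path(d, "tree.nwk")),
        taxonomy = readr::read_tsv(file.path(d, "taxonomy.tsv"),
                                   show_col_types = FALSE),
        metadata = readr::read_tsv(file.path(d, "metadata.tsv"),
                                   show_col_types = FALSE),
        traits = readr::read_tsv(file.path(d, "traits.tsv"),
                                 show_col_types = FALSE)
      )
    })
  }

  # growth clustering (provides the group labels for every later stage)
  growth <- run_stage("growth_clustering", {
    cluster_growth(ds$traits, k = cfg$k, k_max = cfg$k_max,
                   criterion = cfg$criterion, n_perm = cfg$n_perm,
                   seed = cfg$seed)
  })
  d_growth <- stage_dir("01_growth")
  readr::write_tsv(growth$kmeans, file.path(d_growth, "clusters_kmeans.tsv"))
  readr::write_tsv(growth$hierarchical,
                   file.path(d_growth, "clusters_hierarchical.tsv"))
  jsonlite::write_json(
    list(k = growth$k, anosim = as.list(growth$anosim),
         curve = if (!is.null(growth$selection)) growth$selection$curve),
    file.path(d_growth, "growth_report.json"),
    auto_unbox = TRUE, pretty = TRUE, digits = NA, dataframe = "columns"
  )

  cl_map <- setNames(growth$kmeans$cluster, growth$kmeans$cultivar)
  metadata <- dplyr::mutate(
    ds$metadata,
    growth_cluster = unname(cl_map[as.character(.data$cultivar)])
  )
  groups <- setNames(metadata[[cfg$group_col]], metadata$sample_id)

  # preprocessing
  prep <- run_stage("preprocess", {
    rel <- preprocess_table(ds$table, metadata, min_reps = cfg$min_reps)
    core <- core_microbiome(rel, tibble(sample_id = metadata$sample_id,
                                        group = unname(groups)),
                            prevalence_min = cfg$prevalence_min,
                            abundance_min = cfg$abundance_min)
    list(rel = rel, counts = attr(rel, "counts"), core = core)
  })
  d_prep <- stage_dir("02_preprocess")
  write_feature_table(prep$counts, file.path(d_prep, "filtered_counts.tsv"))
  write_feature_table(prep$rel, file.path(d_prep, "relative_abundance.tsv"))
  readr::write_tsv(
    tidyr::unnest(dplyr::select(prep$core, "region", "taxa"), "taxa"),
    file.path(d_prep, "core_taxa.tsv")
  )
  jsonlite::write_json(
    dplyr::select(prep$core, -"taxa"),
    file.path(d_prep, "core_partition.json"),
    auto_unbox = TRUE, pretty = TRUE, digits = NA, dataframe = "rows"
  )

  # diversity
  div <- run_stage("diversity", {
    alpha <- alpha_diversity(prep$counts)
    wu <- weighted_unifrac(prep$rel, ds$tree)
    ord <- pcoa_ordination(wu)
    perm <- permanova_test(wu, metadata,
                           factors = intersect(c("cultivar", "growth_cluster"),
                                               names(metadata)),
                           n_perm = cfg$n_perm, seed = cfg$seed)
    wil <- pairwise_wilcoxon_fdr(alpha[c("sample_id", "richness", "shannon",
                                         "simpson_dominance")],
                                 tibble(sample_id = metadata$sample_id,
                                        group = unname(groups)))
    list(alpha = alpha, unifrac = wu, ordination = ord, permanova = perm,
         wilcoxon = wil)
  })
  d_div <- stage_dir("03_diversity")
  readr::write_tsv(div$alpha, file.path(d_div, "alpha_diversity.tsv"))
  write_distance_matrix(div$unifrac, file.path(d_div, "weighted_unifrac.tsv"))
  readr::write_tsv(div$ordination$coordinates,
                   file.path(d_div, "pcoa_coordinates.tsv"))
  readr::write_tsv(div$permanova, file.path(d_div, "permanova.tsv"))
  readr::write_tsv(div$wilcoxon, file.path(d_div, "wilcoxon_alpha.tsv"))

  # assembly
  asm <- run_stage("assembly", {
    pw <- assembly_analysis(prep$counts, ds$tree,
                            groups = tibble(sample_id = metadata$sample_id,
                                            group = unname(groups)),
                            pairs = cfg$pairs, n_null = cfg$n_null,
                            seed = cfg$seed)
    list(pairwise = pw, fractions = summarize_fractions(pw))
  })
  d_asm <- stage_dir("04_assembly")
  readr::write_tsv(asm$pairwise, file.path(d_asm, "pairwise_assembly.tsv"))
  jsonlite::write_json(asm$fractions, file.path(d_asm, "fractions.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       dataframe = "rows")

  # networks
  net <- run_stage("networks", {
    compare_networks(prep$counts,
                     tibble(sample_id = metadata$sample_id,
                            group = unname(groups)),
                     taxonomy = ds$taxonomy, r_min = cfg$r_min,
                     alpha = cfg$alpha, lfdr_max = cfg$lfdr_max,
                     hub_quantile = cfg$hub_quantile)
  })
  d_net <- stage_dir("05_networks")
  for (gr in names(net$networks)) {
    write_edge_list(net$networks[[gr]],
                    file.path(d_net, paste0("edges_", gr, ".tsv")))
    write_graphml(net$networks[[gr]],
                  file.path(d_net, paste0("network_", gr, ".graphml")))
  }
  readr::write_tsv(net$properties, file.path(d_net, "properties.tsv"))
  jsonlite::write_json(
    list(core_hubs = net$core_hubs, group_hubs = net$group_hubs),
    file.path(d_net, "hubs.json"), auto_unbox = TRUE, pretty = TRUE
  )

  files <- list.files(cfg$out_dir, recursive = TRUE, full.names = TRUE)
  files <- files[basename(files) != "manifest.json"]
  manifest <- list(
    package_version = as.character(utils::packageVersion("rhizocomm")),
    seed = cfg$seed,
    parameters = unclass(cfg)[setdiff(names(cfg), c("out_dir", "input_dir"))],
    checksums = as.list(tools::md5sum(files))
  )
  manifest_path <- file.path(cfg$out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)

  invisible(list(growth = growth, preprocess = prep, diversity = div,
                 assembly = asm, networks = net, manifest = manifest_path))
}
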