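# Post-denoising filters and normalization, applied in the fixed order
# singletons -> replicate prevalence -> TSS, plus the core-microbiome
# partition. All filters are idempotent and never touch the sample set.

#' Remove singleton taxa
#'
#' Drops every taxon whose total count across all samples is exactly 1.
#'
#' @param table Feature table of counts (samples in rows).
#' @return Filtered feature table (tibble).
#' @export
remove_singletons <- function(table) {
  mat <- ft_matrix(table)
  assert_counts(mat, "singleton removal")
  keep <- colSums(mat) != 1
  ft_tibble(mat[, keep, drop = FALSE])
}

#' Replicate prevalence filter
#'
#' Keeps a taxon if there is at least one cultivar in which it is present
#' (count > 0) in at least `min_reps` of that cultivar's replicates. The
#' rule is existential over cultivars: a taxon reproducibly detected in any
#' single cultivar is retained globally.
#'
#' @param table Feature table of counts.
#' @param metadata Data frame with `sample_id` and `cultivar` columns
#'   covering every sample of `table`.
#' @param min_reps Minimum replicates a taxon must appear in (default 2,
#'   the two-of-three rule).
#' @return Filtered feature table (tibble).
#' @export
replicate_prevalence_filter <- function(table, metadata, min_reps = 2) {
  mat <- ft_matrix(table)
  if (!all(c("sample_id", "cultivar") %in% names(metadata))) {
    abort("`metadata` needs `sample_id` and `cultivar` columns.")
  }
  idx <- match(rownames(mat), metadata$sample_id)
  if (anyNA(idx)) {
    abort(paste0("Samples missing from metadata: ",
                 paste(rownames(mat)[is.na(idx)], collapse = ", ")))
  }
  cultivar <- metadata$cultivar[idx]
  pres <- mat > 0
  # replicates-per-cultivar presence count, taxa x cultivars
  per_cv <- rowsum(pres + 0, group = cultivar)
  keep <- apply(per_cv >= min_reps, 2, any)
  ft_tibble(mat[, keep, drop = FALSE])
}

#' Total-sum scaling
#'
#' Converts counts to within-sample relative abundances by dividing each
#' sample row by its library size.
#'
#' @param table Feature table of counts; every sample must have at least
#'   one read.
#' @return Relative-abundance feature table (rows sum to 1).
#' @export
tss_normalize <- function(table) {
  mat <- ft_matrix(table)
  rs <- rowSums(mat)
  if (any(rs == 0)) {
    abort(paste0("Zero-sum sample(s): ",
                 paste(rownames(mat)[rs == 0], collapse = ", ")))
  }
  ft_tibble(mat / rs)
}

#' Core-microbiome partition
#'
#' Within each group, a taxon qualifies as core when its relative abundance
#' exceeds `abundance_min` (strictly) in at least `prevalence_min` of the
#' group's samples. Qualifying taxa are partitioned into Venn regions (the
#' exact combination of groups in which they qualify), and each region is
#' annotated with the proportion of reads its taxa carry, averaged over all
#' samples of the compared groups.
#'
#' @param table Relative-abundance feature table (see [tss_normalize()]).
#' @param groups Data frame with `sample_id` and `group` columns, or a
#'   vector of group labels named by sample id.
#' @param prevalence_min Minimum within-group prevalence (default 0.80).
#' @param abundance_min Relative-abundance floor, strict comparison
#'   (default 1e-4, i.e. 0.01%).
#' @return A `core_partition` object: tibble with `region`, `n_taxa`,
#'   `read_proportion` and a `taxa` list-column; the full qualifying set is
#'   kept in attribute `"core_taxa"`.
#' @export
core_microbiome <- function(table, groups, prevalence_min = 0.80,
                            abundance_min = 1e-4) {
  mat <- ft_matrix(table)
  if (!looks_relative(mat)) {
    abort("`table` must hold relative abundances; run tss_normalize() first.")
  }
  if (is.data.frame(groups)) {
    groups <- setNames(as.character(groups$group), groups$sample_id)
  }
  g <- groups[rownames(mat)]
  if (anyNA(g)) abort("Every sample needs a group label.")
  lev <- unique(unname(g))
  if (any(table(g) == 0)) abort("Empty group.")

  qualifies <- vapply(lev, function(gr) {
    sub <- mat[g == gr, , drop = FALSE]
    colMeans(sub > abundance_min) >= prevalence_min
  }, logical(ncol(mat)))
  colnames(qualifies) <- lev

  any_core <- rowSums(qualifies) > 0  # rows are taxa here
  region_of <- apply(qualifies, 1, function(q) paste(lev[q], collapse = "&"))
  core_taxa <- colnames(mat)[any_core]
  region_of <- region_of[any_core]

  mean_ab <- colMeans(mat)  # averaged over all samples in the compared groups
  regions <- sort(unique(region_of))
  out <- purrr::map_dfr(regions, function(r) {
    taxa <- core_taxa[region_of == r]
    tibble(region = r, n_taxa = length(taxa),
           read_proportion = sum(mean_ab[taxa]), taxa = list(taxa))
  })
  structure(out, class = c("core_partition", class(out)),
            core_taxa = core_taxa, groups = lev)
}

#' Run the full preprocessing chain
#'
#' Applies singleton removal, the replicate prevalence filter and TSS in
#' the fixed order of the workflow.
#'
#' @inheritParams replicate_prevalence_filter
#' @return Relative-abundance feature table (tibble). The intermediate
#'   count table (after both filters, before TSS) is kept in attribute
#'   `"counts"` because the Raup-Crick null operates on counts.
#' @export
preprocess_table <- function(table, metadata, min_reps = 2) {
  counts <- remove_singletons(table)
  counts <- replicate_prevalence_filter(counts, metadata, min_reps = min_reps)
  rel <- tss_normalize(counts)
  attr(rel, "counts") <- counts
  rel
}
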