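# Internal helpers shared across modules.
#
# A feature table is a data frame whose first column, `sample_id`, holds
# unique sample identifiers and whose remaining columns are numeric taxon
# abundances (counts or relative abundances). Samples are always rows.

#' Convert a feature table to an abundance matrix
#'
#' @param table A feature table: data frame with a `sample_id` first column
#'   and one numeric column per taxon, or an already-formed numeric matrix
#'   with sample row names.
#' @return Numeric matrix, samples in rows (named), taxa in columns (named).
#' @keywords internal
#' @noRd
ft_matrix <- function(table) {
  if (is.matrix(table)) {
    if (is.null(rownames(table))) {
      rownames(table) <- paste0("S", seq_len(nrow(table)))
    }
    storage.mode(table) <- "double"
    return(table)
  }
  if (!is.data.frame(table)) {
    abort("`table` must be a data frame or a numeric matrix.")
  }
  id_col <- if ("sample_id" %in% names(table)) "sample_id" else names(table)[1]
  ids <- as.character(table[[id_col]])
  if (anyDuplicated(ids)) {
    abort("Duplicate sample ids in feature table.")
  }
  mat <- as.matrix(table[setdiff(names(table), id_col)])
  if (!is.numeric(mat)) abort("Feature table abundance columns must be numeric.")
  if (any(is.na(mat))) abort("Feature table contains missing values.")
  if (any(mat < 0)) abort("Feature table contains negative abundances.")
  rownames(mat) <- ids
  mat
}

#' @noRd
ft_tibble <- function(mat) {
  dplyr::bind_cols(
    tibble(sample_id = rownames(mat)),
    as_tibble(mat, .name_repair = "minimal")
  )
}

# Heuristic used by count-only filters: a table already carries relative
# abundances when every non-empty sample row sums to 1.
#' @noRd
looks_relative <- function(mat) {
  rs <- rowSums(mat)
  nz <- rs > 0
  any(nz) && all(abs(rs[nz] - 1) < 1e-6)
}

#' @noRd
assert_counts <- function(mat, what = "this operation") {
  if (looks_relative(mat)) {
    abort(paste0(
      "Feature table appears to hold relative abundances; ",
      what, " requires counts."
    ))
  }
  invisible(mat)
}

#' @noRd
assert_square_dist <- function(d, arg = "dist") {
  d <- as.matrix(d)
  if (nrow(d) != ncol(d)) abort(sprintf("`%s` must be square.", arg))
  if (max(abs(d - t(d))) > 1e-8) abort(sprintf("`%s` must be symmetric.", arg))
  d
}

# Single documented seed-splitting rule: every stage that needs its own RNG
# stream derives a 32-bit sub-seed from the user seed and a stage index.
#' @noRd
derive_seed <- function(seed, stage) {
  as.integer((as.numeric(seed) * 48271 + 7919 * stage) %% 2147483647L)
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a
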