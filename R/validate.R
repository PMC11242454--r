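# Self-validation experiments: null calibration of betaNTI on neutral
# communities and recovery of the five assembly regimes by the classifier.
# These are the package's internal ground-truth checks; the conditions are
# fixed here so tests, scripts and documentation all run the same
# experiment.

#' betaNTI null calibration on neutral communities
#'
#' Simulates a neutral-regime community table (no selection, no dispersal
#' structure), runs the betaNTI null model, and reports the fraction of
#' sample pairs with |betaNTI| > 2. On well-calibrated nulls this
#' false-selection fraction stays near the nominal two-sided z rate.
#'
#' @param seed Integer seed.
#' @param n_samples,n_taxa,depth Community dimensions (defaults 30 x 150
#'   at depth 5000, the desk-scale emulation).
#' @param n_null Null shuffles (default 500).
#' @return Tibble with `seed`, `n_pairs`, `frac_significant`.
#' @export
bnti_null_fraction <- function(seed, n_samples = 30, n_taxa = 150,
                               depth = 5000, n_null = 500) {
  tree <- simulate_phylogeny(n_taxa, seed = seed)
  optima <- simulate_trait_optima(tree, seed = seed, standardize = TRUE)
  sim <- simulate_community(tree, optima, assembly_regime("neutral"),
                            n_samples = n_samples, depth = depth,
                            seed = seed)
  bn <- beta_nti(sim$table, tree, n_null = n_null, seed = seed)
  v <- bn$bnti[upper.tri(bn$bnti)]
  tibble(seed = seed, n_pairs = sum(!is.na(v)),
         frac_significant = mean(abs(v) > 2, na.rm = TRUE))
}

#' Regime-recovery experiment
#'
#' Simulates one community table under a named assembly regime at strong
#' parameter settings, runs the full pairwise classification, and reports
#' the modal process. The recovery conditions use a 500-taxon phylogeny
#' with early-burst niche optima (`rate_decay = 2`) so that selection
#' regimes produce the phylogenetically conserved communities the betaNTI
#' null is designed to detect, and a narrow selection filter
#' (`selection_sd = 0.05` on optima of sd 1).
#'
#' @param regime_name One of the five regime names, see
#'   [assembly_regime()].
#' @param seed Integer seed.
#' @param n_samples,n_taxa,depth Community dimensions (defaults 10 x 500
#'   at depth 5000).
#' @param n_null Null iterations for betaNTI and RCbray (default 199).
#' @param selection_sd,rate_decay Strength settings for the selection
#'   regimes.
#' @return Tibble with `regime`, `seed`, `modal_process`, `modal_fraction`
#'   and the expected process label under that regime.
#' @export
recover_regime <- function(regime_name, seed, n_samples = 10, n_taxa = 500,
                           depth = 5000, n_null = 199, selection_sd = 0.05,
                           rate_decay = 2) {
  tree <- simulate_phylogeny(n_taxa, seed = seed)
  optima <- simulate_trait_optima(tree, seed = seed, standardize = TRUE,
                                  rate_decay = rate_decay)
  reg <- assembly_regime(regime_name, selection_sd = selection_sd)
  sim <- simulate_community(tree, optima, reg, n_samples = n_samples,
                            depth = depth, seed = seed)
  res <- assembly_analysis(sim$table, tree, pairs = "all", n_null = n_null,
                           seed = seed)
  cl <- res$process[!is.na(res$process)]
  tab <- sort(table(cl), decreasing = TRUE)
  expected <- c(
    neutral = "undominated",
    homogeneous_selection = "homogeneous_selection",
    heterogeneous_selection = "heterogeneous_selection",
    dispersal_limitation = "dispersal_limitation",
    homogenizing_dispersal = "homogenizing_dispersal"
  )[[regime_name]]
  tibble(
    regime = regime_name, seed = seed,
    modal_process = names(tab)[1],
    modal_fraction = as.numeric(tab)[1] / length(cl),
    expected_process = expected,
    recovered = names(tab)[1] == expected
  )
}
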