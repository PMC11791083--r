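# One-call wrapper for a single bait-vs-control contrast.

#' Run one bait-vs-control differential enrichment contrast
#'
#' Applies the per-contrast steps in their canonical order: pairwise
#' valid-value filtering, restriction to the contrast's samples,
#' per-replicate down-shifted imputation, and the S0-moderated Welch
#' test with permutation FDR.
#'
#' @param m a normalized, min-valid-filtered [intensity_matrix]
#'   containing the contrast's samples
#' @param design an [experiment_design]
#' @param bait,control condition labels
#' @param k minimum valid values in the bait condition (default 3)
#' @param width,downshift imputation parameters (defaults 0.3, 1.8)
#' @param impute_seed seed for the imputation draws
#' @param ... further arguments to [permutation_fdr()] (`s0`,
#'   `fdr_threshold`, `n_permutations`, `seed`, ...)
#' @return a `differential_result`
#' @export
run_contrast <- function(m, design, bait, control, k = 3L,
                         width = 0.3, downshift = 1.8,
                         impute_seed = NULL, ...) {
  mp <- filter_pairwise_valid(m, design, bait, control, k = k)
  keep <- names(design$condition_of)[design$condition_of %in%
                                       c(bait, control)]
  mp <- intensity_matrix(unclass(mp)[, intersect(colnames(mp), keep),
                                     drop = FALSE])
  imp <- impute_downshifted(mp, width = width, downshift = downshift,
                            seed = impute_seed)
  permutation_fdr(imp$matrix, design, bait, control, ...)
}
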