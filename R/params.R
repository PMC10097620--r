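#' Tuning constants of the analysis pipeline
#'
#' Bundles every threshold and constant the downstream stages use, with the
#' defaults of the original Perseus-style workflow: downshift imputation with
#' `width` 0.3 and `downshift` 1.8 (both expressed as multiples of the
#' per-column observed standard deviation), an artificial within-group
#' variance `s0` of 0.1 log2 units with a permutation FDR target of 0.1 over
#' 250 randomisations, a linear fold-change gate of 1.5 with
#' Benjamini-Hochberg alpha 0.05, at least 3 valid values required in at
#' least one condition group, and discard when more than 2 values are
#' missing in every condition.
#'
#' @param width Imputation spread as a multiple of the observed column sd
#'   (unitless, > 0).
#' @param downshift Imputation left shift as a multiple of the observed
#'   column sd (unitless, >= 0).
#' @param s0 Artificial within-group variance term added to the denominator
#'   of the modified test statistic (log2 units, >= 0).
#' @param target_fdr Target false discovery rate for the permutation cutoff
#'   curve, in (0, 1).
#' @param n_randomisations Number of random group relabelings for the
#'   permutation FDR (>= 1).
#' @param fold_change Linear-scale fold-change threshold (> 1); significance
#'   requires a log2 difference above `log2(fold_change)`.
#' @param alpha Adjusted-p threshold for the BH branch, in (0, 1).
#' @param min_valid Minimum observed values required in at least one
#'   condition group (>= 1).
#' @param max_missing_per_condition A protein is discarded when every
#'   condition has strictly more missing values than this (>= 0).
#' @param seed Master seed; stage-local seeds are derived from it.
#' @return A list of class `analysis_params`.
#' @export
analysis_params <- function(width = 0.3, downshift = 1.8, s0 = 0.1,
                            target_fdr = 0.1, n_randomisations = 250L,
                            fold_change = 1.5, alpha = 0.05,
                            min_valid = 3L, max_missing_per_condition = 2L,
                            seed = 1L) {
  stopifnot(width > 0, downshift >= 0, s0 >= 0,
            target_fdr > 0, target_fdr < 1,
            n_randomisations >= 1,
            fold_change > 1,
            alpha > 0, alpha < 1,
            min_valid >= 1, max_missing_per_condition >= 0,
            is.numeric(seed), length(seed) == 1, is.finite(seed))
  structure(list(width = width, downshift = downshift, s0 = s0,
                 target_fdr = target_fdr,
                 n_randomisations = as.integer(n_randomisations),
                 fold_change = fold_change, alpha = alpha,
                 min_valid = as.integer(min_valid),
                 max_missing_per_condition = as.integer(max_missing_per_condition),
                 seed = as.integer(seed)),
            class = "analysis_params")
}

#' @export
print.analysis_params <- function(x, ...) {
  cat("Analysis parameters:\n")
  for (nm in names(x)) cat(sprintf("  %-26s %s\n", nm, format(x[[nm]])))
  invisible(x)
}
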