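#' Parameters of the ensemble-of-gene-sets scorer
#'
#' Bundles every tunable of the pipeline in one validated list. Defaults are
#' the framework's reference settings: high-expresser cutoff z > 1.5, at
#' least 50 driver cells per subpopulation, Wilcoxon DE with
#' `logfc_threshold = 0.25` and Bonferroni-adjusted p <= 0.05, log
#' normalization to 10,000 counts per cell, 100 confident cells per stratum
#' and three-fold cross-validation.
#'
#' @param z_high z-score cutoff defining high expressers of a driver gene
#'   (strict inequality); default 1.5.
#' @param min_cells minimum number of high-expresser cells for a driver to
#'   yield a gene-set pair; default 50.
#' @param logfc_threshold minimum |log2 fold change| (on de-logged means)
#'   for a gene to be tested in the Wilcoxon DE; default 0.25.
#' @param adj_p_max maximum Bonferroni-adjusted p-value retained; default 0.05.
#' @param scale_factor library-size scaling for log normalization; default 1e4.
#' @param n_confident number of cells per confident stratum (lowest-score
#'   p21-/p16- and highest-score p21+ or p16+); default 100.
#' @param k_folds folds for cross-validation; default 3.
#' @param rng_seed integer seed used by every stochastic step; default 1.
#' @param coverage_min minimum fraction of a pair's genes that must be present
#'   in a dataset for the pair to be scored there; default 0.3.
#' @param lowsasp_quantile quantile of the per-cell SASP-detection fraction
#'   below (or at) which a cell is a lowSASP candidate; default 0.25.
#' @param n_bins expression bins for bin-matched control gene sampling
#'   (module and proliferation scores); default 24.
#' @param n_ctrl_per_gene control genes sampled per signature gene; default 100.
#' @param threshold_weighting `"counts"` (expected false positives plus false
#'   negatives weighted by observed group sizes) or `"equal"` (equal priors)
#'   for the Gaussian decision threshold; default `"counts"`.
#' @return an object of class `egs_params`.
#' @export
#' @examples
#' p <- egs_params(min_cells = 25)
#' p$z_high
egs_params <- function(z_high = 1.5,
                       min_cells = 50L,
                       logfc_threshold = 0.25,
                       adj_p_max = 0.05,
                       scale_factor = 1e4,
                       n_confident = 100L,
                       k_folds = 3L,
                       rng_seed = 1L,
                       coverage_min = 0.3,
                       lowsasp_quantile = 0.25,
                       n_bins = 24L,
                       n_ctrl_per_gene = 100L,
                       threshold_weighting = c("counts", "equal")) {
  threshold_weighting <- match.arg(threshold_weighting)
  p <- list(z_high = z_high, min_cells = as.integer(min_cells),
            logfc_threshold = logfc_threshold, adj_p_max = adj_p_max,
            scale_factor = scale_factor, n_confident = as.integer(n_confident),
            k_folds = as.integer(k_folds), rng_seed = as.integer(rng_seed),
            coverage_min = coverage_min, lowsasp_quantile = lowsasp_quantile,
            n_bins = as.integer(n_bins),
            n_ctrl_per_gene = as.integer(n_ctrl_per_gene),
            threshold_weighting = threshold_weighting)
  validate_egs_params(p)
  structure(p, class = "egs_params")
}

validate_egs_params <- function(p) {
  if (!(p$z_high > 0)) stop_contract("z_high must be > 0 (got %g)", p$z_high)
  if (p$min_cells < 2) stop_contract("min_cells must be >= 2 (got %d)", p$min_cells)
  if (!(p$adj_p_max > 0 && p$adj_p_max <= 1))
    stop_contract("adj_p_max must lie in (0, 1] (got %g)", p$adj_p_max)
  if (p$scale_factor <= 0) stop_contract("scale_factor must be positive")
  if (p$k_folds < 2) stop_contract("k_folds must be >= 2")
  if (p$coverage_min < 0 || p$coverage_min > 1)
    stop_contract("coverage_min must lie in [0, 1]")
  invisible(p)
}

#' @export
print.egs_params <- function(x, ...) {
  cat("egs_params:\n")
  for (nm in names(x)) cat(sprintf("  %-19s %s\n", nm, format(x[[nm]])))
  invisible(x)
}
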