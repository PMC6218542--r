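#' Pipeline run configuration
#'
#' Bundles every tunable parameter of the discovery pipeline with the
#' defaults used throughout: the 25% per-group missingness filter, the
#' downshift imputation distribution (width 0.3, shift 1.8 sample standard
#' deviations), 250 label permutations for the false discovery rate, 10,000
#' permutations for the cross-fluid and targeted tests, the 0.6 correlation
#' pruning threshold, a 5-protein classification panel, repeated (n = 50)
#' 5-fold cross-validation, the SVM cost grid 2^-2 ... 2^12 with fixed
#' radial-basis sigma 0.0333, the random-forest mtry grid 2:5, recursive
#' feature elimination under repeated (n = 5) 10-fold cross-validation over
#' subset sizes 1:25, 30, 40, ..., 100 with a 5% simplification tolerance,
#' and exhaustive best-subset regression up to 7 predictors.
#'
#' @param seed Integer global seed; all stochastic stages derive substreams
#'   from it via [substream_seed()].
#' @param filter_max_missing_frac Proteins missing in more than this
#'   fraction of samples in *both* contrast groups are removed.
#' @param impute_width Imputation width as a multiple of the sample
#'   standard deviation.
#' @param impute_shift Downshift in sample standard deviation units.
#' @param fdr_permutations Label permutations for the permutation FDR.
#' @param crossfluid_permutations Permutations for the cross-fluid
#'   correlation test.
#' @param corr_prune_threshold Absolute Pearson correlation above which one
#'   of a protein pair is pruned.
#' @param panel_size Number of proteins in the classification panel.
#' @param cv_folds,cv_repeats Outer cross-validation geometry for model
#'   comparison.
#' @param tune_folds Inner folds used to tune SVM cost / forest mtry within
#'   each training split.
#' @param svm_cost_grid Cost grid for the support vector machine.
#' @param svm_sigma Fixed radial-basis kernel scale.
#' @param rf_mtry_grid Candidate numbers of predictors sampled per split.
#' @param rf_ntree Trees per random forest.
#' @param rfe_folds,rfe_repeats Resampling geometry for recursive feature
#'   elimination.
#' @param rfe_subset_sizes Candidate panel sizes evaluated by RFE.
#' @param rfe_tolerance Fractional AUC loss tolerated when simplifying the
#'   RFE model.
#' @param subset_max_k Largest subset size in best-subset regression.
#' @param targeted_permutations Permutations for the targeted median test.
#' @return A list of class `promark_config`.
#' @export
run_config <- function(seed = 1L,
                       filter_max_missing_frac = 0.25,
                       impute_width = 0.3,
                       impute_shift = 1.8,
                       fdr_permutations = 250L,
                       crossfluid_permutations = 10000L,
                       corr_prune_threshold = 0.6,
                       panel_size = 5L,
                       cv_folds = 5L,
                       cv_repeats = 50L,
                       tune_folds = 5L,
                       svm_cost_grid = 2^seq(-2, 12),
                       svm_sigma = 0.0333,
                       rf_mtry_grid = 2:5,
                       rf_ntree = 250L,
                       rfe_folds = 10L,
                       rfe_repeats = 5L,
                       rfe_subset_sizes = c(1:25, seq(30, 100, by = 10)),
                       rfe_tolerance = 0.05,
                       subset_max_k = 7L,
                       targeted_permutations = 10000L) {
  cfg <- list(
    seed = as.integer(seed),
    filter_max_missing_frac = filter_max_missing_frac,
    impute_width = impute_width,
    impute_shift = impute_shift,
    fdr_permutations = as.integer(fdr_permutations),
    crossfluid_permutations = as.integer(crossfluid_permutations),
    corr_prune_threshold = corr_prune_threshold,
    panel_size = as.integer(panel_size),
    cv_folds = as.integer(cv_folds),
    cv_repeats = as.integer(cv_repeats),
    tune_folds = as.integer(tune_folds),
    svm_cost_grid = svm_cost_grid,
    svm_sigma = svm_sigma,
    rf_mtry_grid = as.integer(rf_mtry_grid),
    rf_ntree = as.integer(rf_ntree),
    rfe_folds = as.integer(rfe_folds),
    rfe_repeats = as.integer(rfe_repeats),
    rfe_subset_sizes = as.integer(sort(unique(rfe_subset_sizes))),
    rfe_tolerance = rfe_tolerance,
    subset_max_k = as.integer(subset_max_k),
    targeted_permutations = as.integer(targeted_permutations)
  )
  counts <- c("fdr_permutations", "crossfluid_permutations", "panel_size",
              "cv_folds", "cv_repeats", "tune_folds", "rf_ntree",
              "rfe_folds", "rfe_repeats", "subset_max_k",
              "targeted_permutations")
  for (nm in counts) {
    if (cfg[[nm]] < 1L) stop("'", nm, "' must be a positive count")
  }
  for (nm in c("filter_max_missing_frac", "rfe_tolerance")) {
    if (cfg[[nm]] < 0 || cfg[[nm]] >= 1)
      stop("'", nm, "' must lie in [0, 1)")
  }
  if (cfg$corr_prune_threshold <= 0 || cfg$corr_prune_threshold >= 1)
    stop("'corr_prune_threshold' must lie in (0, 1)")
  if (length(cfg$svm_cost_grid) == 0L || length(cfg$rf_mtry_grid) == 0L ||
      length(cfg$rfe_subset_sizes) == 0L)
    stop("tuning grids must be non-empty")
  if (cfg$svm_sigma <= 0) stop("'svm_sigma' must be positive")
  structure(cfg, class = "promark_config")
}

#' @export
print.promark_config <- function(x, ...) {
  cat("promark run configuration (seed ", x$seed, ")\n", sep = "")
  cat("  missingness filter : >", x$filter_max_missing_frac,
      "missing in both groups\n")
  cat("  imputation         : width", x$impute_width, ", shift",
      x$impute_shift, "sd\n")
  cat("  permutations       : FDR", x$fdr_permutations, "| cross-fluid",
      x$crossfluid_permutations, "| targeted", x$targeted_permutations, "\n")
  cat("  classification     :", x$cv_repeats, "x", x$cv_folds,
      "-fold CV, panel", x$panel_size, "\n")
  cat("  RFE                :", x$rfe_repeats, "x", x$rfe_folds,
      "-fold over", length(x$rfe_subset_sizes), "sizes\n")
  invisible(x)
}

config_hash <- function(cfg) {
  # stable short fingerprint of the flattened configuration for provenance
  flat <- paste(names(cfg), vapply(cfg, function(v)
    paste(format(v, digits = 15), collapse = ","), ""), collapse = ";")
  codes <- utf8ToInt(flat)
  h <- 0
  for (k in codes) h <- (h * 131 + k) %% 2147483647
  sprintf("%08x", as.integer(h))
}
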