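#' Log2 transform a raw-scale abundance matrix
#'
#' @param x An `abundance_matrix` with `scale_tag = "raw"`; every unmasked
#'   value must be strictly positive (zeros are masked at read time).
#' @return The matrix on the log2 scale; the mask is unchanged.
#' @export
log2_transform <- function(x) {
  stopifnot(inherits(x, "abundance_matrix"))
  if (x$scale_tag != "raw")
    stop("matrix is already on the ", x$scale_tag, " scale")
  bad <- which(!x$missing_mask & x$values <= 0, arr.ind = TRUE)
  if (nrow(bad))
    stop("unmasked non-positive value at protein '",
         x$protein_ids[bad[1, 1]], "', sample '",
         x$sample_ids[bad[1, 2]],
         "' (zeros must be masked as missing at read time)")
  v <- log2(x$values)
  abundance_matrix(v, x$protein_ids, x$sample_ids, x$missing_mask, "log2")
}

#' Filter proteins by per-group missingness
#'
#' A protein is removed only when its fraction of missing cells exceeds
#' `max_frac` in *both* contrast groups; a protein well observed in either
#' group alone is retained. Retained proteins keep their input order.
#'
#' @param x An `abundance_matrix`.
#' @param meta A `sample_table` covering the matrix columns.
#' @param contrast Character vector of the two group labels tested.
#' @param max_frac Maximum tolerated missing fraction (default 0.25).
#' @return A list with elements `matrix` (filtered `abundance_matrix`) and
#'   `report` (a `preprocess_report`).
#' @export
filter_by_missingness <- function(x, meta, contrast = c("ALS", "healthy"),
                                  max_frac = 0.25) {
  stopifnot(inherits(x, "abundance_matrix"), length(contrast) == 2L)
  meta <- align_samples(x, meta)
  in1 <- meta$group == contrast[1]
  in2 <- meta$group == contrast[2]
  if (!any(in1) || !any(in2))
    stop("contrast group with zero samples: ",
         contrast[c(!any(in1), !any(in2))][1])
  f1 <- rowMeans(x$missing_mask[, in1, drop = FALSE])
  f2 <- rowMeans(x$missing_mask[, in2, drop = FALSE])
  drop <- f1 > max_frac & f2 > max_frac
  keep <- which(!drop)
  out <- subset_abundance(x, proteins = keep)
  report <- structure(list(
    n_proteins_in = length(x$protein_ids),
    n_removed_by_missingness = sum(drop),
    removed_ids = x$protein_ids[drop],
    n_cells_imputed = 0L,
    sample_params = NULL), class = "preprocess_report")
  list(matrix = out, report = report)
}

#' Impute missing values by per-sample downshifted normal draws
#'
#' Reproduces the left-censored (missing-not-at-random) imputation used by
#' Perseus-style label-free workflows: each missing cell in sample *j* is
#' replaced by a draw from
#' `Normal(mean_j - shift * sd_j, (width * sd_j)^2)`, where `mean_j` and
#' `sd_j` are the mean and standard deviation of the *observed* log2
#' values of that sample. The downshift models the fact that undetected
#' proteins sit below the detection limit.
#'
#' @param x An `abundance_matrix` on the log2 scale.
#' @param width Width of the imputation distribution as a multiple of the
#'   sample standard deviation (default 0.3).
#' @param shift Downshift in sample standard deviation units (default 1.8).
#' @param seed Integer seed; the operation is a pure function of
#'   `(x, width, shift, seed)`.
#' @return A list with elements `matrix` (fully observed) and `report`.
#' @export
impute_downshift <- function(x, width = 0.3, shift = 1.8, seed = 1L) {
  stopifnot(inherits(x, "abundance_matrix"))
  if (x$scale_tag != "log2")
    stop("downshift imputation requires log2-scale values")
  nobs <- colSums(!x$missing_mask)
  if (any(nobs < 3L))
    stop("sample(s) with fewer than 3 observed values: ",
         paste(x$sample_ids[nobs < 3L], collapse = ", "))
  mu <- colMeans(x$values, na.rm = TRUE)
  sd_j <- apply(x$values, 2, stats::sd, na.rm = TRUE)
  vals <- x$values
  n_imp <- 0L
  with_seed(seed, {
    for (j in seq_along(x$sample_ids)) {
      idx <- which(x$missing_mask[, j])
      if (length(idx) == 0L) next
      vals[idx, j] <- stats::rnorm(length(idx),
                                   mean = mu[j] - shift * sd_j[j],
                                   sd = width * sd_j[j])
      n_imp <- n_imp + length(idx)
    }
  })
  report <- structure(list(
    n_proteins_in = length(x$protein_ids),
    n_removed_by_missingness = 0L,
    removed_ids = character(),
    n_cells_imputed = n_imp,
    sample_params = data.frame(sample_id = x$sample_ids,
                               mean = mu, sd = sd_j,
                               n_imputed = colSums(x$missing_mask),
                               row.names = NULL)),
    class = "preprocess_report")
  out <- abundance_matrix(vals, x$protein_ids, x$sample_ids,
                          matrix(FALSE, nrow(vals), ncol(vals)), "log2")
  list(matrix = out, report = report)
}

#' @export
print.preprocess_report <- function(x, ...) {
  cat("preprocess report: ", x$n_proteins_in, " proteins in, ",
      x$n_removed_by_missingness, " removed by missingness, ",
      x$n_cells_imputed, " cells imputed\n", sep = "")
  invisible(x)
}

#' Run the full preprocessing chain on a raw matrix
#'
#' Log2 transform (if raw), missingness filter, then downshift imputation,
#' using the parameters in `cfg`. Sample means and standard deviations for
#' imputation are computed after filtering.
#'
#' @param x An `abundance_matrix` (raw or log2 scale).
#' @param meta A `sample_table`.
#' @param contrast Two group labels for the missingness filter.
#' @param cfg A [run_config()].
#' @param seed Seed for the imputation draws; defaults to an imputation
#'   substream of `cfg$seed`.
#' @return A list with `matrix` (imputed log2 matrix), `filtered` (the
#'   pre-imputation filtered matrix, mask intact — the empirical-background
#'   substrate), and `report`.
#' @export
preprocess <- function(x, meta, contrast = c("ALS", "healthy"),
                       cfg = run_config(),
                       seed = substream_seed(cfg$seed, "impute")) {
  if (x$scale_tag == "raw") x <- log2_transform(x)
  flt <- filter_by_missingness(x, meta, contrast,
                               cfg$filter_max_missing_frac)
  imp <- impute_downshift(flt$matrix, cfg$impute_width, cfg$impute_shift,
                          seed)
  rep <- imp$report
  rep$n_proteins_in <- flt$report$n_proteins_in
  rep$n_removed_by_missingness <- flt$report$n_removed_by_missingness
  rep$removed_ids <- flt$report$removed_ids
  list(matrix = imp$matrix, filtered = flt$matrix, report = rep)
}
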