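#' Normalize a targeted peptide response to its SIL internal standard
#'
#' The stable-isotope-labeled (heavy) analogue of each peptide is spiked
#' at a fixed level before digestion, so the light/heavy area ratio
#' cancels sample preparation and instrument-response variation.
#'
#' @param light_area,heavy_area Integrated peak areas (same length).
#' @return The dimensionless normalized response `light / heavy`.
#' @export
normalize_to_sil <- function(light_area, heavy_area) {
  stopifnot(length(light_area) == length(heavy_area))
  if (any(heavy_area <= 0))
    stop("non-positive heavy (SIL) area at row(s): ",
         paste(which(heavy_area <= 0), collapse = ", "))
  if (any(light_area < 0)) stop("negative light area")
  light_area / heavy_area
}

#' Two-group permutation test on the median normalized response
#'
#' Distribution-free comparison for targeted peptide responses whose
#' distributions deviate from normality. The statistic is the absolute
#' difference of group medians; its null distribution is generated by
#' uniform random re-assignments of the pooled values to the original
#' group sizes. The default p estimator adds one to numerator and
#' denominator so a finite Monte Carlo run never reports exactly zero;
#' `estimator = "raw"` gives the plain exceedance proportion.
#'
#' @param g1,g2 Numeric response vectors, each of length >= 3.
#' @param n_perm Number of permutations (default 10000).
#' @param seed Integer seed.
#' @param estimator `"add_one"` (default) or `"raw"`.
#' @return A list of class `perm_median_result` with `median_diff`
#'   (signed, group 1 minus group 2), `stat` (absolute), `p`, `n_perm`,
#'   `n_exceed`.
#' @export
median_permutation_test <- function(g1, g2, n_perm = 10000L, seed = 1L,
                                    estimator = c("add_one", "raw")) {
  estimator <- match.arg(estimator)
  g1 <- as.numeric(g1); g2 <- as.numeric(g2)
  if (length(g1) < 3L || length(g2) < 3L)
    stop("each group needs at least 3 values")
  pooled <- c(g1, g2)
  n1 <- length(g1)
  obs_signed <- stats::median(g1) - stats::median(g2)
  obs <- abs(obs_signed)
  if (stats::sd(pooled) == 0) {
    return(structure(list(median_diff = 0, stat = 0, p = 1,
                          n_perm = as.integer(n_perm), n_exceed = n_perm),
                     class = "perm_median_result"))
  }
  # permute the sorted pool and always sample the smaller group: the
  # Monte Carlo draw is then identical under relabeling of the groups
  pool_sorted <- sort(pooled)
  m <- min(n1, length(g2))
  null_stat <- with_seed(seed, {
    vapply(seq_len(n_perm), function(b) {
      idx <- sample.int(length(pool_sorted), m)
      abs(stats::median(pool_sorted[idx]) -
            stats::median(pool_sorted[-idx]))
    }, numeric(1))
  })
  n_exceed <- sum(null_stat >= obs)
  p <- if (estimator == "add_one") (1 + n_exceed) / (1 + n_perm)
       else n_exceed / n_perm
  structure(list(median_diff = obs_signed, stat = obs, p = p,
                 n_perm = as.integer(n_perm),
                 n_exceed = as.integer(n_exceed)),
            class = "perm_median_result")
}

#' @export
print.perm_median_result <- function(x, ...) {
  cat("median permutation test: diff = ", format(x$median_diff, digits = 3),
      ", p = ", format(x$p, digits = 3), " (", x$n_exceed, "/", x$n_perm,
      " exceed)\n", sep = "")
  invisible(x)
}

#' Validate a targeted-peptide report table
#'
#' @param report A data.frame with columns `sample_id`, `group`,
#'   `peptide_id`, `light_area`, `heavy_area`.
#' @param drop_zero_heavy Drop (with a warning naming them) rows whose
#'   heavy area is non-positive instead of erroring.
#' @return The validated report with a `response` column appended.
#' @export
targeted_report <- function(report, drop_zero_heavy = TRUE) {
  need <- c("sample_id", "group", "peptide_id", "light_area", "heavy_area")
  miss <- setdiff(need, names(report))
  if (length(miss)) stop("report missing column(s): ",
                         paste(miss, collapse = ", "))
  key <- paste(report$sample_id, report$peptide_id)
  if (anyDuplicated(key))
    stop("duplicate (sample, peptide) row(s): ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  bad <- which(report$heavy_area <= 0)
  if (length(bad)) {
    msg <- paste(report$sample_id[bad], report$peptide_id[bad],
                 collapse = "; ")
    if (!drop_zero_heavy) stop("non-positive heavy area: ", msg)
    warning("dropping ", length(bad),
            " row(s) with non-positive heavy area: ", msg)
    report <- report[-bad, , drop = FALSE]
  }
  report$response <- normalize_to_sil(report$light_area, report$heavy_area)
  report
}

#' Read a flat targeted peptide area export
#'
#' Accepts a tab-separated table in the shape of a peptide-area report
#' (one row per sample x peptide with light and heavy integrated areas).
#'
#' @param path Path to the TSV file.
#' @return A validated report (see [targeted_report()]).
#' @export
read_targeted_report <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  targeted_report(utils::read.table(path, header = TRUE, sep = "\t",
                                    stringsAsFactors = FALSE))
}

#' Run the targeted panel analysis across group contrasts
#'
#' SIL-normalizes the report and applies the median permutation test to
#' every requested pairwise group contrast of every peptide, with a
#' deterministic seed substream per (peptide, contrast).
#'
#' @param report A targeted report data.frame (validated internally).
#' @param contrasts A list of 2-vectors of group labels, or strings like
#'   `"ALS:healthy"`.
#' @param n_perm Permutations per test (default 10000).
#' @param seed Integer seed.
#' @param estimator Passed to [median_permutation_test()].
#' @return A data.frame with one row per (peptide, contrast): group
#'   medians and sizes, signed median difference, and permutation p.
#' @export
run_targeted_panel <- function(report,
                               contrasts = list(c("ALS", "healthy"),
                                                c("ALS", "disease_control")),
                               n_perm = 10000L, seed = 1L,
                               estimator = "add_one") {
  report <- targeted_report(report)
  if (is.character(contrasts)) contrasts <- as.list(contrasts)
  contrasts <- lapply(contrasts, function(ct) {
    if (length(ct) == 1L) strsplit(ct, ":", fixed = TRUE)[[1]] else ct
  })
  groups <- unique(report$group)
  for (ct in contrasts) {
    bad <- setdiff(ct, groups)
    if (length(bad)) stop("unknown group in contrast: ",
                          paste(bad, collapse = ", "))
  }
  rows <- list()
  for (pep in unique(report$peptide_id)) {
    sub <- report[report$peptide_id == pep, ]
    for (ct in contrasts) {
      r1 <- sub$response[sub$group == ct[1]]
      r2 <- sub$response[sub$group == ct[2]]
      if (length(r1) < 3L || length(r2) < 3L)
        stop("contrast ", ct[1], " vs ", ct[2], " for peptide ", pep,
             " has a group with fewer than 3 samples")
      res <- median_permutation_test(
        r1, r2, n_perm,
        substream_seed(seed, paste0("targeted:", pep, ":", ct[1], ":", ct[2])),
        estimator)
      rows[[length(rows) + 1L]] <- data.frame(
        peptide_id = pep, group1 = ct[1], group2 = ct[2],
        n1 = length(r1), n2 = length(r2),
        median1 = stats::median(r1), median2 = stats::median(r2),
        median_diff = res$median_diff, p = res$p,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
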