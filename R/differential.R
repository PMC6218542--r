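#' Two-group pooled-variance t-test
#'
#' Student's t with pooled variance and `n1 + n2 - 2` degrees of freedom,
#' two-sided. The effect estimate is `mean(x) - mean(y)` (log2 fold change
#' when inputs are log2 abundances, case minus control). Welch's unequal
#' variance form is available via `var_equal = FALSE`.
#'
#' Degenerate inputs: when both groups have zero variance and equal means
#' the result is `t = 0, p = 1`; zero variance with unequal means yields
#' an infinite t and a `p = 0` sentinel with a warning.
#'
#' @param x,y Numeric vectors (each of length >= 2) of the two groups.
#' @param var_equal Pooled (`TRUE`, default) or Welch (`FALSE`) variance.
#' @return A list with `mean_diff`, `t_stat`, `p`, `df`.
#' @export
#' @examples
#' ttest_two_group(c(1, 2, 3), c(4, 5, 6))
ttest_two_group <- function(x, y, var_equal = TRUE) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) < 2L || length(y) < 2L)
    stop("each group needs at least 2 values")
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop("non-finite values in input")
  n1 <- length(x); n2 <- length(y)
  d <- mean(x) - mean(y)
  v1 <- stats::var(x); v2 <- stats::var(y)
  if (v1 == 0 && v2 == 0) {
    if (d == 0) return(list(mean_diff = 0, t_stat = 0, p = 1,
                            df = n1 + n2 - 2))
    warning("both groups have zero variance with unequal means; p = 0 sentinel")
    return(list(mean_diff = d, t_stat = sign(d) * Inf, p = 0,
                df = n1 + n2 - 2))
  }
  if (var_equal) {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  t <- d / se
  list(mean_diff = d, t_stat = t,
       p = 2 * stats::pt(-abs(t), df), df = df)
}

# Row-wise pooled t statistics for a proteins x samples value matrix.
# Returns list(mean_diff, t, p); zero-variance rows follow the
# ttest_two_group degenerate conventions without warnings.
row_t_stats <- function(vals, idx1, idx2, var_equal = TRUE) {
  n1 <- length(idx1); n2 <- length(idx2)
  x1 <- vals[, idx1, drop = FALSE]
  x2 <- vals[, idx2, drop = FALSE]
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  ss1 <- rowSums((x1 - m1)^2)
  ss2 <- rowSums((x2 - m2)^2)
  d <- m1 - m2
  if (var_equal) {
    sp2 <- (ss1 + ss2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- rep.int(n1 + n2 - 2, length(d))
  } else {
    v1 <- ss1 / (n1 - 1); v2 <- ss2 / (n2 - 1)
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  t <- d / se
  zero <- se == 0
  t[zero & d == 0] <- 0
  t[zero & d != 0] <- sign(d[zero & d != 0]) * Inf
  p <- 2 * stats::pt(-abs(t), df)
  p[zero & d == 0] <- 1
  p[zero & d != 0] <- 0
  list(mean_diff = d, t = t, p = p)
}

#' Per-protein differential abundance table
#'
#' Applies the two-group pooled t-test to every protein of a fully imputed
#' log2 matrix. Rows are in input protein order.
#'
#' @param x A fully imputed `abundance_matrix` (log2 scale, no mask).
#' @param meta A `sample_table`.
#' @param contrast Two group labels; the effect is
#'   `mean(contrast[1]) - mean(contrast[2])`.
#' @param var_equal Pooled (default) or Welch t.
#' @return A `data.frame` with columns `protein_id`, `mean_diff`,
#'   `t_stat`, `p`, `direction` (sign of `mean_diff`).
#' @export
differential_table <- function(x, meta, contrast = c("ALS", "healthy"),
                               var_equal = TRUE) {
  stopifnot(inherits(x, "abundance_matrix"), length(contrast) == 2L)
  if (any(x$missing_mask))
    stop("matrix must be fully imputed before differential testing")
  meta <- align_samples(x, meta)
  idx1 <- which(meta$group == contrast[1])
  idx2 <- which(meta$group == contrast[2])
  if (length(idx1) < 2L || length(idx2) < 2L)
    stop("contrast group absent or has fewer than 2 samples: ",
         contrast[c(length(idx1) < 2L, length(idx2) < 2L)][1])
  st <- row_t_stats(x$values, idx1, idx2, var_equal)
  data.frame(protein_id = x$protein_ids,
             mean_diff = st$mean_diff,
             t_stat = st$t,
             p = st$p,
             direction = sign(st$mean_diff),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Permutation-based false discovery rate
#'
#' Label-permutation FDR in the SAM style: for each of `n_perm` random
#' reassignments of group labels the absolute t statistics of all proteins
#' are recomputed; for protein *i* with observed statistic `|t_i|`, the
#' expected false-positive count is the average over permutations of the
#' number of permuted statistics at least `|t_i|`, the raw q is that count
#' divided by the observed number of proteins at least `|t_i|`, and the
#' final q is monotonized step-down (cumulative minimum from the largest
#' `|t|`) and clipped to `[0, 1]`. No fudge (s0) term is added.
#'
#' Permutations are drawn uniformly with replacement from all label
#' assignments, excluding the observed labeling. With `null_stat =
#' "median"` the median permuted exceedance count replaces the mean.
#'
#' @param x A fully imputed `abundance_matrix`.
#' @param meta A `sample_table`.
#' @param contrast Two group labels.
#' @param n_perm Number of permutations (default 250; minimum 10).
#' @param seed Integer seed.
#' @param null_stat `"mean"` (default) or `"median"` exceedance summary.
#' @param var_equal Pooled (default) or Welch t.
#' @return The [differential_table()] data.frame with extra columns `q`
#'   (permutation FDR) and `perm_p` (per-protein permutation p-value with
#'   the add-one correction).
#' @export
permutation_fdr <- function(x, meta, contrast = c("ALS", "healthy"),
                            n_perm = 250L, seed = 1L,
                            null_stat = c("mean", "median"),
                            var_equal = TRUE) {
  null_stat <- match.arg(null_stat)
  if (n_perm < 10L) stop("n_perm < 10 gives a meaningless FDR estimate")
  tab <- differential_table(x, meta, contrast, var_equal)
  meta <- align_samples(x, meta)
  idx1 <- which(meta$group == contrast[1])
  idx2 <- which(meta$group == contrast[2])
  both <- c(idx1, idx2)
  n1 <- length(idx1)
  P <- nrow(tab)
  obs_abs <- abs(tab$t_stat)

  perm_abs <- matrix(0, nrow = P, ncol = n_perm)
  with_seed(seed, {
    for (b in seq_len(n_perm)) {
      repeat {
        pi1 <- sort(sample(both, n1))
        if (!identical(pi1, sort(idx1))) break
      }
      pi2 <- setdiff(both, pi1)
      perm_abs[, b] <- abs(row_t_stats(x$values, pi1, pi2, var_equal)$t)
    }
  })

  # counts of permuted |t| >= each observed |t|, via one sorted pool
  pool <- sort(as.vector(perm_abs))
  total_ge <- length(pool) - findInterval(obs_abs, pool, left.open = TRUE)
  if (null_stat == "mean") {
    fp <- total_ge / n_perm
  } else {
    fp <- apply(perm_abs, 2, function(col) {
      sc <- sort(col)
      length(sc) - findInterval(obs_abs, sc, left.open = TRUE)
    })
    fp <- apply(fp, 1, stats::median)
  }
  sorted_obs <- sort(obs_abs)
  n_ge_obs <- P - findInterval(obs_abs, sorted_obs, left.open = TRUE)
  q_raw <- fp / n_ge_obs

  # q(i) = min of the raw FDR estimate over thresholds protein i passes
  # (|t| thresholds <= |t_i|): suffix minimum along decreasing |t|, which
  # makes q monotone non-decreasing as significance falls
  ord <- order(obs_abs, decreasing = TRUE)
  q <- numeric(P)
  q[ord] <- rev(cummin(rev(q_raw[ord])))
  q <- pmin(pmax(q, 0), 1)

  # per-protein permutation p with the add-one correction
  ge_own <- rowSums(perm_abs >= obs_abs)
  tab$q <- q
  tab$perm_p <- (1 + ge_own) / (1 + n_perm)
  tab
}

#' Cross-fluid permutation correlation test
#'
#' Tests whether a protein's abundance in one fluid tracks its abundance
#' in the matched fluid of the same individuals. Two statistics are
#' returned: the two-sided p-value that the simple-regression slope
#' differs from zero, and a permutation p-value built from the Pearson
#' correlations between the original first-fluid vector and `n_perm`
#' random permutations of the second-fluid vector. Following the
#' verbatim counting rule, `n_exceed` counts signed permuted correlations
#' greater than `|r_obs|`, and `perm_p = 2 * n_exceed / n_perm`, capped at
#' 1; `counting = "absolute"` counts `|r_perm| > |r_obs|` instead.
#'
#' @param csf_vec,plasma_vec Numeric abundance vectors aligned on the same
#'   individuals, length >= 4, neither constant.
#' @param n_perm Number of permutations (default 10000).
#' @param seed Integer seed.
#' @param counting `"signed"` (default, one-sided count doubled) or
#'   `"absolute"`.
#' @return A list of class `perm_corr_result` with `pearson_r`, `slope_p`,
#'   `perm_p`, `n_perm`, `n_exceed`, and `reported` — the printable p,
#'   `"< 2/n_perm"` when no permutation exceeds.
#' @export
cross_fluid_test <- function(csf_vec, plasma_vec, n_perm = 10000L,
                             seed = 1L, counting = c("signed", "absolute")) {
  counting <- match.arg(counting)
  x <- as.numeric(csf_vec); y <- as.numeric(plasma_vec)
  n <- length(x)
  if (length(y) != n) stop("fluid vectors must be aligned (equal length)")
  if (n < 4L) stop("need at least 4 matched individuals")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant vector: correlation undefined")
  fit <- summary(stats::lm(y ~ x))
  slope_p <- fit$coefficients[2, 4]

  xc <- x - mean(x)
  yc <- y - mean(y)
  denom <- sqrt(sum(xc^2) * sum(yc^2))
  # same arithmetic as the permuted correlations, so an identity
  # permutation ties exactly instead of at floating-point noise
  r_obs <- sum(xc * yc) / denom
  r_perm <- numeric(n_perm)
  with_seed(seed, {
    for (b in seq_len(n_perm))
      r_perm[b] <- sum(xc * yc[sample.int(n)]) / denom
  })
  n_exceed <- if (counting == "signed") sum(r_perm > abs(r_obs))
              else sum(abs(r_perm) > abs(r_obs))
  perm_p <- min(1, 2 * n_exceed / n_perm)
  reported <- if (n_exceed == 0L)
    paste0("< ", format(2 / n_perm)) else format(perm_p)
  structure(list(pearson_r = r_obs, slope_p = slope_p, perm_p = perm_p,
                 n_perm = as.integer(n_perm),
                 n_exceed = as.integer(n_exceed), reported = reported),
            class = "perm_corr_result")
}

#' @export
print.perm_corr_result <- function(x, ...) {
  cat("cross-fluid correlation: r = ", format(x$pearson_r, digits = 3),
      ", slope p = ", format(x$slope_p, digits = 3),
      ", permutation p ", x$reported, " (", x$n_exceed, "/", x$n_perm,
      " exceed)\n", sep = "")
  invisible(x)
}

#' Cross-fluid tests for a set of proteins present in both fluids
#'
#' Runs [cross_fluid_test()] for each protein of the intersection of the
#' two matrices, pairing columns through the metadata's individuals (both
#' matrices must share sample identifiers). Pairs with a missing value in
#' either fluid are dropped (observed-only pairing).
#'
#' @param csf,plasma `abundance_matrix` objects sharing sample ids.
#' @param proteins Protein ids to test; default the full intersection.
#' @param n_perm,seed,counting Passed to [cross_fluid_test()]; the seed is
#'   substreamed per protein.
#' @return A data.frame, one row per testable protein.
#' @export
cross_fluid_table <- function(csf, plasma, proteins = NULL,
                              n_perm = 10000L, seed = 1L,
                              counting = "signed") {
  shared_s <- intersect(csf$sample_ids, plasma$sample_ids)
  if (length(shared_s) < 4L) stop("fewer than 4 shared individuals")
  if (is.null(proteins))
    proteins <- intersect(csf$protein_ids, plasma$protein_ids)
  rows <- lapply(proteins, function(pid) {
    cx <- csf$values[pid, shared_s]
    px <- plasma$values[pid, shared_s]
    ok <- !(csf$missing_mask[pid, shared_s] |
              plasma$missing_mask[pid, shared_s])
    if (sum(ok) < 4L || stats::sd(cx[ok]) == 0 || stats::sd(px[ok]) == 0)
      return(NULL)
    res <- cross_fluid_test(cx[ok], px[ok], n_perm,
                            substream_seed(seed, paste0("xf:", pid)),
                            counting)
    data.frame(protein_id = pid, n_pairs = sum(ok),
               pearson_r = res$pearson_r, slope_p = res$slope_p,
               perm_p = res$perm_p, n_exceed = res$n_exceed,
               reported = res$reported, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
}
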