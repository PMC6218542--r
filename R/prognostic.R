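#' Exhaustive best-subset linear regression
#'
#' For every size k in 1..max_k, fits all C(P, k) least-squares models of
#' the response on k predictor columns (plus intercept) and records the
#' subset with minimal residual sum of squares, together with adjusted
#' R-squared, Mallows Cp, and BIC:
#' \itemize{
#'   \item `Cp = RSS_k / sigma2 - n + 2(k+1)`, with `sigma2` the residual
#'     mean square of the full P-predictor model;
#'   \item `BIC = n log(RSS_k / n) + (k+1) log(n)` (Gaussian
#'     profile-likelihood scale, constants dropped);
#'   \item `adj R2 = 1 - (RSS_k / (n-k-1)) / (TSS / (n-1))`.
#' }
#'
#' @param X Numeric samples x predictors matrix with column names.
#' @param y Numeric response (e.g. ALS-FRS scores); rows with missing y
#'   must be dropped beforehand.
#' @param max_k Largest subset size (default 7).
#' @return A data.frame of class `subset_search`: one row per k with
#'   columns `k`, `subset` (comma-joined ids), `rss`, `adj_r2`, `cp`,
#'   `bic`, plus attributes `n`, `sigma2_full`, `tss`.
#' @export
best_subset <- function(X, y, max_k = 7L) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  stopifnot(nrow(X) == length(y), !anyNA(y), !anyNA(X))
  n <- nrow(X); P <- ncol(X)
  if (P > 20L)
    stop("refusing exhaustive search over ", P,
         " predictors; prune correlated features first")
  max_k <- min(max_k, P)
  if (n <= max_k + 1L) stop("need n > max_k + 1 samples")
  ids <- colnames(X)
  if (is.null(ids)) ids <- paste0("X", seq_len(P))
  tss <- sum((y - mean(y))^2)
  rss_of <- function(cols) {
    fit <- stats::lm.fit(cbind(1, X[, cols, drop = FALSE]), y)
    sum(fit$residuals^2)
  }
  sigma2_full <- rss_of(seq_len(P)) / (n - P - 1)
  rows <- vector("list", max_k)
  for (k in seq_len(max_k)) {
    combos <- utils::combn(P, k)
    rss <- apply(combos, 2, rss_of)
    best <- which.min(rss)
    cols <- combos[, best]
    rk <- rss[best]
    rows[[k]] <- data.frame(
      k = k,
      subset = paste(ids[cols], collapse = ","),
      rss = rk,
      adj_r2 = 1 - (rk / (n - k - 1)) / (tss / (n - 1)),
      cp = rk / sigma2_full - n + 2 * (k + 1),
      bic = n * log(rk / n) + (k + 1) * log(n),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  attr(out, "n") <- n
  attr(out, "sigma2_full") <- sigma2_full
  attr(out, "tss") <- tss
  class(out) <- c("subset_search", "data.frame")
  out
}

#' Ordinary least squares fit with regression diagnostics
#'
#' Fits the response on the chosen predictor subset with an intercept and
#' reports the coefficient table, multiple and adjusted R-squared, the
#' overall F test, residuals, and a Shapiro-Wilk residual-normality
#' p-value plus the data for density and QQ diagnostic plots.
#'
#' @param X Numeric samples x predictors matrix (the chosen subset).
#' @param y Numeric response.
#' @return A list of class `ols_report`.
#' @export
fit_ols <- function(X, y) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  stopifnot(nrow(X) == length(y))
  n <- nrow(X); k <- ncol(X)
  if (n <= k + 1L) stop("need n > k + 1 samples")
  design <- cbind(`(Intercept)` = 1, X)
  qd <- qr(design)
  if (qd$rank < ncol(design)) {
    bad <- colnames(design)[setdiff(seq_len(ncol(design)),
                                    qd$pivot[seq_len(qd$rank)])]
    stop("rank-deficient design; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  df <- data.frame(.y = y, X, check.names = FALSE)
  fit <- stats::lm(.y ~ ., data = df)
  sm <- summary(fit)
  fstat <- sm$fstatistic
  f_p <- stats::pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE)
  res <- stats::residuals(fit)
  sw <- if (n >= 3 && n <= 5000) stats::shapiro.test(res)$p.value
        else NA_real_
  structure(list(
    coefficients = sm$coefficients,
    r_squared = sm$r.squared,
    adj_r_squared = sm$adj.r.squared,
    f_stat = unname(fstat[1]), f_df = unname(fstat[2:3]), f_p = unname(f_p),
    residuals = res, fitted = stats::fitted(fit),
    shapiro_p = sw, fit = fit), class = "ols_report")
}

#' @export
print.ols_report <- function(x, ...) {
  cat("OLS fit: R2 = ", sprintf("%.3f", x$r_squared),
      " (adj ", sprintf("%.3f", x$adj_r_squared), "), F(",
      x$f_df[1], ",", x$f_df[2], ") = ", sprintf("%.2f", x$f_stat),
      ", p = ", format(x$f_p, digits = 2),
      "; residual normality p = ", format(x$shapiro_p, digits = 2),
      "\n", sep = "")
  stats::printCoefmat(x$coefficients)
  invisible(x)
}

#' Choose the prognostic model size from a subset search
#'
#' Default policy `"elbow_capped"`: the smallest k whose BIC lies within
#' 2 of the minimum BIC (the conventional "indistinguishable support"
#' band), additionally capped at `n / 10` predictors to guard against
#' overspecification at small n. An explicit `k` reproduces a manual
#' choice.
#'
#' @param search A [best_subset()] result.
#' @param policy `"elbow_capped"` or `"min_bic"`.
#' @param k Optional explicit size override.
#' @return The chosen size (integer).
#' @export
choose_model_size <- function(search, policy = c("elbow_capped", "min_bic"),
                              k = NULL) {
  policy <- match.arg(policy)
  stopifnot(nrow(search) > 0L)
  if (!is.null(k)) {
    if (!k %in% search$k) stop("no size-", k, " model in the search")
    return(as.integer(k))
  }
  if (policy == "min_bic") return(search$k[which.min(search$bic)])
  n <- attr(search, "n")
  cap <- max(1L, floor(n / 10))
  cand <- search[search$k <= cap, , drop = FALSE]
  if (nrow(cand) == 0L) cand <- search[1, , drop = FALSE]
  ok <- cand$bic <= min(cand$bic) + 2
  as.integer(min(cand$k[ok]))
}

#' Best-subset prognostic regression of a functional score
#'
#' Convenience wrapper chaining the correlation pruning of the candidate
#' predictors, an optional cap to the most significant predictors, the
#' exhaustive subset search, model-size choice, and the final OLS fit.
#'
#' @param x An imputed `abundance_matrix`.
#' @param meta A `sample_table` with an `alsfrs` column; samples with a
#'   missing score are dropped.
#' @param candidates Candidate protein ids (e.g. the q < 0.05 set).
#' @param cfg A [run_config()].
#' @param max_predictors Cap on the predictor pool after pruning; the
#'   most significant (by `diff_p`, if given) are kept.
#' @param diff_p Optional named p-value vector used for the cap.
#' @param k Optional explicit model size.
#' @return A list of class `prognostic_report` with `search`,
#'   `chosen_k`, `model` (an `ols_report`), `predictors`, `pruned`.
#' @export
prognostic_regression <- function(x, meta, candidates, cfg = run_config(),
                                  max_predictors = 16L, diff_p = NULL,
                                  k = NULL) {
  stopifnot(inherits(x, "abundance_matrix"))
  meta <- align_samples(x, meta)
  if (!"alsfrs" %in% names(meta)) stop("metadata lacks an alsfrs column")
  keep_s <- which(!is.na(meta$alsfrs))
  if (length(keep_s) < 10L) stop("too few scored samples")
  sub <- subset_abundance(x, proteins = candidates, samples = keep_s)
  pr <- prune_correlated(sub, cfg$corr_prune_threshold)
  pool <- pr$retained
  if (length(pool) > max_predictors) {
    if (!is.null(diff_p)) {
      pool <- pool[order(diff_p[pool])][seq_len(max_predictors)]
    } else {
      pool <- pool[seq_len(max_predictors)]
    }
  }
  X <- t(sub$values[pool, , drop = FALSE])
  y <- meta$alsfrs[keep_s]
  search <- best_subset(X, y, cfg$subset_max_k)
  chosen_k <- choose_model_size(search, k = k)
  chosen_ids <- strsplit(search$subset[search$k == chosen_k], ",")[[1]]
  model <- fit_ols(X[, chosen_ids, drop = FALSE], y)
  structure(list(search = search, chosen_k = chosen_k,
                 predictors = chosen_ids, model = model,
                 pruned = pr, pool = pool, n = length(keep_s)),
            class = "prognostic_report")
}

#' @export
print.prognostic_report <- function(x, ...) {
  cat("prognostic best-subset regression over ", length(x$pool),
      " predictors (n = ", x$n, "): chosen k = ", x$chosen_k,
      " [", paste(x$predictors, collapse = ", "), "]\n", sep = "")
  print(x$model)
  invisible(x)
}
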