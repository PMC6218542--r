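#' Correlation-based pruning of redundant proteins
#'
#' Iteratively removes one protein of the most-correlated offending pair:
#' while any pair of retained proteins has `|Pearson r|` above the
#' threshold, the pair with the largest `|r|` is located and the member
#' with the *larger* mean absolute correlation against all currently
#' retained proteins is removed (the protein with the lowest average
#' correlation among the others is retained; ties remove the protein
#' later in input order).
#'
#' @param x An imputed `abundance_matrix` (proteins in rows), or a
#'   numeric proteins x samples matrix with rownames.
#' @param threshold Pruning threshold on `|r|` (default 0.6).
#' @param use_abs Compare `|r|` (default); `FALSE` prunes on signed r
#'   exceeding the threshold, leaving anticorrelated pairs untouched.
#' @return A list with `retained` (protein ids, input order) and `trace`
#'   (data.frame of removal steps: removed id, partner id, their r, the
#'   mean absolute correlations that decided the removal).
#' @export
prune_correlated <- function(x, threshold = 0.6, use_abs = TRUE) {
  vals <- if (inherits(x, "abundance_matrix")) {
    if (any(x$missing_mask)) stop("matrix must be imputed before pruning")
    x$values
  } else as.matrix(x)
  ids <- rownames(vals)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(vals)))
  if (nrow(vals) < 2L)
    return(list(retained = ids, trace = empty_prune_trace()))
  cm <- suppressWarnings(stats::cor(t(vals)))
  cm[is.na(cm)] <- 0
  eff <- if (use_abs) abs(cm) else cm
  diag(eff) <- 0
  alive <- rep(TRUE, nrow(vals))
  steps <- list()
  repeat {
    sub <- eff
    sub[!alive, ] <- 0; sub[, !alive] <- 0
    mx <- max(sub)
    if (mx <= threshold) break
    hit <- which(sub == mx, arr.ind = TRUE)[1, ]
    i <- hit[[1]]; j <- hit[[2]]
    mean_i <- mean(abs(cm[i, alive & seq_len(ncol(cm)) != i]))
    mean_j <- mean(abs(cm[j, alive & seq_len(ncol(cm)) != j]))
    drop <- if (mean_i > mean_j) i
            else if (mean_j > mean_i) j
            else max(i, j)  # tie: remove the later protein in input order
    alive[drop] <- FALSE
    steps[[length(steps) + 1L]] <- data.frame(
      removed = ids[drop], partner = ids[if (drop == i) j else i],
      r = cm[i, j], mean_abs_r_removed = if (drop == i) mean_i else mean_j,
      mean_abs_r_kept = if (drop == i) mean_j else mean_i,
      stringsAsFactors = FALSE)
  }
  trace <- if (length(steps)) do.call(rbind, steps) else empty_prune_trace()
  list(retained = ids[alive], trace = trace)
}

empty_prune_trace <- function() {
  data.frame(removed = character(), partner = character(), r = numeric(),
             mean_abs_r_removed = numeric(), mean_abs_r_kept = numeric(),
             stringsAsFactors = FALSE)
}

#' Select the classification panel from the differential table
#'
#' Applies the unsupervised selection rule: among the correlation-pruned
#' proteins whose permutation FDR is below `q_max`, take the `k` with the
#' smallest p-values, ordered by p ascending.
#'
#' @param diff A [permutation_fdr()] table (needs `protein_id`, `p`, `q`).
#' @param retained Protein ids surviving [prune_correlated()].
#' @param q_max FDR cutoff (default 0.05).
#' @param k Panel size (default 5).
#' @return A list of class `feature_panel` with `panel` (ids in rank
#'   order), `p`, `q`, and `n_qualifying`. Fewer than `k` qualifying
#'   proteins return all of them with a warning; zero return an empty
#'   panel with a warning (the classifier stage refuses an empty panel).
#' @export
select_panel <- function(diff, retained, q_max = 0.05, k = 5L) {
  miss <- setdiff(retained, diff$protein_id)
  if (length(miss)) stop("differential table does not cover: ",
                         paste(miss, collapse = ", "))
  sub <- diff[diff$protein_id %in% retained & diff$q < q_max, ]
  sub <- sub[order(sub$p), ]
  if (nrow(sub) == 0L)
    warning("no proteins pass q < ", q_max, " after pruning; empty panel")
  else if (nrow(sub) < k)
    warning("only ", nrow(sub), " proteins qualify for a panel of ", k)
  top <- utils::head(sub, k)
  structure(list(panel = top$protein_id, p = top$p, q = top$q,
                 n_qualifying = nrow(sub)), class = "feature_panel")
}

#' @export
print.feature_panel <- function(x, ...) {
  cat("feature panel (", length(x$panel), " of ", x$n_qualifying,
      " qualifying):\n", sep = "")
  if (length(x$panel))
    print(data.frame(protein_id = x$panel, p = x$p, q = x$q))
  invisible(x)
}

# Feature importance on a fitted training split: absolute standardized
# coefficients for linear models (the split is already centered/scaled),
# impurity importance for the forest.
rank_features <- function(kind, Xtr, ytr, params) {
  yf <- factor(ifelse(ytr, "case", "ctrl"), levels = c("ctrl", "case"))
  imp <- switch(kind,
    lda = {
      fit <- MASS::lda(Xtr, grouping = yf)
      abs(fit$scaling[, 1])
    },
    glm_logit = {
      df <- as.data.frame(Xtr); df$.y <- ytr
      fit <- suppressWarnings(stats::glm(.y ~ ., data = df,
                                         family = stats::binomial()))
      co <- stats::coef(fit)[-1]
      co[is.na(co)] <- 0
      stats::setNames(abs(co), colnames(Xtr))
    },
    svm_linear = {
      fit <- kernlab::ksvm(as.matrix(Xtr), yf,
                           kernel = kernlab::vanilladot(),
                           C = params$C %||% 1, scaled = FALSE)
      w <- crossprod(kernlab::coef(fit)[[1]],
                     as.matrix(Xtr)[kernlab::SVindex(fit), , drop = FALSE])
      stats::setNames(abs(as.numeric(w)), colnames(Xtr))
    },
    rf = {
      fit <- randomForest::randomForest(
        Xtr, yf, ntree = params$ntree %||% 250L, importance = FALSE)
      imp <- randomForest::importance(fit, type = 2)[, 1]
      imp
    },
    stop("no importance measure for model kind: ", kind))
  imp[colnames(Xtr)]
}

#' Recursive feature elimination under repeated cross-validation
#'
#' Supervised backward selection: over `repeats x folds` stratified outer
#' resamples, the model is fit on the training 90% with all features and
#' its importance measure ranks them; every candidate subset size is then
#' refit on the top-ranked features of the training split and scored on
#' the untouched held-out fold by AUC. The profile aggregates the
#' resample AUCs per size; the chosen size maximizes the mean AUC.
#'
#' @param x An imputed `abundance_matrix` (apply [prune_correlated()]
#'   first; redundant features dilute the rankings).
#' @param meta A `sample_table`.
#' @param model Model kind: `"rf"` (default), `"lda"`, `"glm_logit"`, or
#'   `"svm_linear"`.
#' @param contrast Two group labels; first is the positive class.
#' @param sizes Candidate subset sizes; sizes exceeding the feature count
#'   are dropped with a warning.
#' @param folds,repeats Resampling geometry (default 10-fold, 5 repeats).
#' @param cfg A [run_config()] (supplies `rf_ntree` and the tolerance).
#' @param seed Integer seed.
#' @return A list of class `rfe_profile`: `sizes`, `mean_auc`, `resample_auc`
#'   (matrix resamples x sizes), `rankings` (feature ids by rank, one
#'   column per resample), `final_ranking` (features by mean rank across
#'   resamples), `chosen_size`, and `simplified_size` (smallest size
#'   within `cfg$rfe_tolerance` of the best mean AUC).
#' @export
rfe <- function(x, meta, model = "rf", contrast = c("ALS", "healthy"),
                sizes = NULL, folds = NULL, repeats = NULL,
                cfg = run_config(), seed = cfg$seed) {
  stopifnot(inherits(x, "abundance_matrix"))
  if (any(x$missing_mask)) stop("matrix must be fully imputed")
  sizes <- if (is.null(sizes)) cfg$rfe_subset_sizes else as.integer(sizes)
  folds <- folds %||% cfg$rfe_folds
  repeats <- repeats %||% cfg$rfe_repeats
  meta <- align_samples(x, meta)
  keep <- meta$group %in% contrast
  X <- t(x$values[, keep, drop = FALSE])
  y <- meta$group[keep] == contrast[1]
  P <- ncol(X)
  if (any(sizes > P)) {
    warning("dropping subset size(s) above the feature count: ",
            paste(sizes[sizes > P], collapse = ", "))
    sizes <- sizes[sizes <= P]
  }
  sizes <- sort(unique(sizes))
  if (length(sizes) == 0L) stop("no evaluable subset sizes")
  params <- list(ntree = cfg$rf_ntree)

  n_res <- repeats * folds
  auc_mat <- matrix(NA_real_, n_res, length(sizes),
                    dimnames = list(NULL, sizes))
  rankings <- matrix(NA_character_, P, n_res)
  schedule <- with_seed(substream_seed(seed, "rfe_folds"), {
    lapply(seq_len(repeats), function(r) stratified_folds(y, folds))
  })
  res <- 0L
  for (r in seq_len(repeats)) {
    fold_of <- schedule[[r]]
    for (f in seq_len(folds)) {
      res <- res + 1L
      te <- fold_of == f
      Xtr <- X[!te, , drop = FALSE]; Xte <- X[te, , drop = FALSE]
      ctr <- colMeans(Xtr); scl <- apply(Xtr, 2, stats::sd)
      scl[scl == 0] <- 1
      Xtr <- scale(Xtr, ctr, scl); Xte <- scale(Xte, ctr, scl)
      imp <- with_seed(substream_seed(seed, sprintf("rfe_rank:%d", res)),
                       rank_features(model, Xtr, y[!te], params))
      ord <- order(imp, decreasing = TRUE)
      rankings[, res] <- colnames(Xtr)[ord]
      for (si in seq_along(sizes)) {
        top <- ord[seq_len(sizes[si])]
        sc <- with_seed(substream_seed(seed, sprintf("rfe_fit:%d:%d", res, si)),
                        fit_score(model, Xtr[, top, drop = FALSE], y[!te],
                                  Xte[, top, drop = FALSE], params))
        m <- binary_metrics(sc, y[te])
        auc_mat[res, si] <- m$auc
      }
    }
  }
  mean_auc <- colMeans(auc_mat, na.rm = TRUE)
  chosen <- sizes[which.max(mean_auc)]
  mean_rank <- rowMeans(apply(rankings, 2, function(col)
    match(rankings[, 1], col)))
  final_ranking <- rankings[, 1][order(mean_rank)]
  out <- list(sizes = sizes, mean_auc = unname(mean_auc),
              resample_auc = auc_mat, rankings = rankings,
              final_ranking = final_ranking, chosen_size = chosen,
              model = model, folds = folds, repeats = repeats)
  out$simplified_size <- simplify_within_tolerance(out, cfg$rfe_tolerance)
  class(out) <- "rfe_profile"
  out
}

#' @export
print.rfe_profile <- function(x, ...) {
  cat("RFE profile (", x$model, ", ", x$repeats, " x ", x$folds,
      "-fold): best mean AUC ", sprintf("%.3f", max(x$mean_auc)),
      " at size ", x$chosen_size, "; simplified size ",
      x$simplified_size, "\n", sep = "")
  invisible(x)
}

#' Simplify an RFE model within an AUC tolerance
#'
#' Returns the smallest subset size whose mean AUC is at least
#' `(1 - tol)` times the best mean AUC — trading a bounded performance
#' loss for a smaller targeted panel.
#'
#' @param profile An [rfe()] profile (or any list with `sizes` and
#'   `mean_auc`).
#' @param tol Fractional tolerance (default 0.05).
#' @return The selected size.
#' @export
simplify_within_tolerance <- function(profile, tol = 0.05) {
  stopifnot(length(profile$sizes) > 0L,
            length(profile$sizes) == length(profile$mean_auc))
  best <- max(profile$mean_auc)
  ok <- profile$mean_auc >= (1 - tol) * best
  min(profile$sizes[ok])
}
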