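#' Binary classification metrics at a fixed threshold
#'
#' Computes the standard metric set for a two-class problem with cases
#' (ALS) as the positive class: accuracy, sensitivity `TP/(TP+FN)`,
#' specificity `TN/(TN+FP)`, Cohen's kappa, the Youden index
#' (sensitivity + specificity - 1), and the area under the ROC curve as
#' the Mann-Whitney concordance probability with ties counted 1/2.
#'
#' @param scores Numeric case scores (probabilities or decision values);
#'   higher means more case-like.
#' @param truth Logical vector (`TRUE` = case) or factor/character equal
#'   to `positive`.
#' @param threshold Classification threshold on `scores` (default 0.5,
#'   appropriate for probability scores).
#' @param positive Positive class label used when `truth` is not logical.
#' @return A list with `accuracy`, `sensitivity`, `specificity`, `auc`,
#'   `kappa`, `youden`. `auc` is `NA` when only one class is present.
#' @export
binary_metrics <- function(scores, truth, threshold = 0.5,
                           positive = "ALS") {
  if (!is.logical(truth)) truth <- truth == positive
  stopifnot(length(scores) == length(truth), all(is.finite(scores)))
  pred <- scores > threshold
  tp <- sum(pred & truth); tn <- sum(!pred & !truth)
  fp <- sum(pred & !truth); fn <- sum(!pred & truth)
  n <- length(truth)
  acc <- (tp + tn) / n
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  p_yes <- ((tp + fp) / n) * ((tp + fn) / n)
  p_no <- ((tn + fn) / n) * ((tn + fp) / n)
  pe <- p_yes + p_no
  kappa <- if (pe < 1) (acc - pe) / (1 - pe) else 0
  n_pos <- sum(truth); n_neg <- n - n_pos
  auc <- if (n_pos > 0 && n_neg > 0) {
    r <- rank(scores)  # midranks give the tie-1/2 convention
    (sum(r[truth]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  } else NA_real_
  list(accuracy = acc, sensitivity = sens, specificity = spec,
       auc = auc, kappa = kappa,
       youden = if (is.na(sens) || is.na(spec)) NA_real_ else sens + spec - 1)
}

# ---- internal model fitting -------------------------------------------

# y: logical (TRUE = case). Returns case scores for Xte on a scale where
# larger = more case-like; probabilities where the model provides them,
# decision values for the SVM (AUC is rank-based, and the 0 decision
# boundary maps to the 0.5 probability threshold via `shift`).
fit_score <- function(kind, Xtr, ytr, Xte, params = list()) {
  yf <- factor(ifelse(ytr, "case", "ctrl"), levels = c("ctrl", "case"))
  switch(kind,
    lda = {
      fit <- MASS::lda(Xtr, grouping = yf)
      as.numeric(stats::predict(fit, Xte)$posterior[, "case"])
    },
    glm_logit = {
      df <- as.data.frame(Xtr); df$.y <- ytr
      fit <- suppressWarnings(stats::glm(.y ~ ., data = df,
                                         family = stats::binomial()))
      as.numeric(suppressWarnings(
        stats::predict(fit, newdata = as.data.frame(Xte),
                       type = "response")))
    },
    svm_rbf = ,
    svm_linear = {
      kern <- if (kind == "svm_rbf")
        kernlab::rbfdot(sigma = params$sigma %||% 0.0333)
      else kernlab::vanilladot()
      fit <- kernlab::ksvm(as.matrix(Xtr), yf, kernel = kern,
                           C = params$C %||% 1, scaled = FALSE,
                           prob.model = FALSE)
      dec_tr <- as.numeric(kernlab::predict(fit, as.matrix(Xtr),
                                            type = "decision"))
      flip <- if (mean(dec_tr[ytr]) < mean(dec_tr[!ytr])) -1 else 1
      dec <- flip * as.numeric(kernlab::predict(fit, as.matrix(Xte),
                                                type = "decision"))
      # map the 0 decision boundary onto the 0.5 class threshold
      stats::plogis(dec)
    },
    rf = {
      fit <- randomForest::randomForest(
        Xtr, yf,
        ntree = params$ntree %||% 250L,
        mtry = params$mtry %||% max(1L, floor(sqrt(ncol(Xtr)))))
      as.numeric(stats::predict(fit, Xte, type = "prob")[, "case"])
    },
    stop("unknown model kind: ", kind))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Stratified fold labels for a logical class vector.
stratified_folds <- function(y, k) {
  f <- integer(length(y))
  for (cl in c(TRUE, FALSE)) {
    idx <- which(y == cl)
    if (length(idx) < k) stop("need at least ", k, " samples per class")
    f[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  f
}

# Inner-resampling grid tuning on the training split only; returns the
# params list for fit_score. Grid point with the best mean inner accuracy
# wins; ties go to the first (smallest) grid value.
tune_params <- function(kind, Xtr, ytr, cfg, seed) {
  grid <- switch(kind,
    svm_rbf = lapply(cfg$svm_cost_grid,
                     function(C) list(C = C, sigma = cfg$svm_sigma)),
    rf = {
      g <- cfg$rf_mtry_grid[cfg$rf_mtry_grid <= ncol(Xtr)]
      if (length(g) == 0L) g <- max(1L, floor(sqrt(ncol(Xtr))))
      lapply(g, function(m) list(mtry = m, ntree = cfg$rf_ntree))
    },
    return(list()))
  if (length(grid) == 1L) return(grid[[1L]])
  kf <- min(cfg$tune_folds, min(sum(ytr), sum(!ytr)))
  acc <- with_seed(seed, {
    folds <- stratified_folds(ytr, kf)
    vapply(grid, function(par) {
      hits <- 0L
      for (f in seq_len(kf)) {
        te <- folds == f
        sc <- fit_score(kind, Xtr[!te, , drop = FALSE], ytr[!te],
                        Xtr[te, , drop = FALSE], par)
        hits <- hits + sum((sc > 0.5) == ytr[te])
      }
      hits / length(ytr)
    }, numeric(1))
  })
  grid[[which.max(acc)]]
}

#' Repeated stratified cross-validated model comparison
#'
#' Evaluates a set of classifiers on an identical schedule of repeated
#' stratified k-fold resamples, so the per-resample metrics are paired
#' across models. Within every training split the features are centered
#' and scaled (parameters estimated on the training split only and
#' applied to its test split) and tunable models (SVM cost, forest mtry)
#' pick their grid point by nested inner-fold resampling of the training
#' split; the test fold is never touched before evaluation.
#'
#' @param x An imputed `abundance_matrix` restricted to the panel proteins.
#' @param meta A `sample_table`.
#' @param specs Character vector of model kinds among `"lda"`,
#'   `"glm_logit"`, `"svm_rbf"`, `"svm_linear"`, `"rf"`.
#' @param contrast Two group labels; the first is the positive class.
#' @param cfg A [run_config()] supplying the tuning grids.
#' @param folds,repeats Outer cross-validation geometry.
#' @param seed Integer seed controlling the fold schedule and tuning.
#' @return A `data.frame` of class `resample_table`: one row per
#'   (model, repeat, fold) with the [binary_metrics()] columns. The fold
#'   schedule is attached as attribute `fold_schedule` and its checksum
#'   (identical across models by construction) as `fold_checksum`.
#' @export
repeated_cv <- function(x, meta, specs = c("lda", "glm_logit",
                                           "svm_rbf", "rf"),
                        contrast = c("ALS", "healthy"),
                        cfg = run_config(), folds = cfg$cv_folds,
                        repeats = cfg$cv_repeats, seed = cfg$seed) {
  stopifnot(inherits(x, "abundance_matrix"))
  if (any(x$missing_mask)) stop("matrix must be fully imputed")
  meta <- align_samples(x, meta)
  keep <- meta$group %in% contrast
  X <- t(x$values[, keep, drop = FALSE])
  y <- meta$group[keep] == contrast[1]
  if (min(sum(y), sum(!y)) < folds)
    stop("need at least ", folds, " samples per class")

  schedule <- with_seed(substream_seed(seed, "cv_folds"), {
    lapply(seq_len(repeats), function(r) stratified_folds(y, folds))
  })

  rows <- vector("list", length(specs) * repeats * folds)
  i <- 0L
  for (r in seq_len(repeats)) {
    fold_of <- schedule[[r]]
    for (f in seq_len(folds)) {
      te <- fold_of == f
      Xtr <- X[!te, , drop = FALSE]; Xte <- X[te, , drop = FALSE]
      ctr <- colMeans(Xtr); scl <- apply(Xtr, 2, stats::sd)
      scl[scl == 0] <- 1
      Xtr <- scale(Xtr, ctr, scl); Xte <- scale(Xte, ctr, scl)
      for (kind in specs) {
        par <- tune_params(kind, Xtr, y[!te], cfg,
                           substream_seed(seed,
                                          sprintf("tune:%s:%d:%d", kind, r, f)))
        sc <- with_seed(substream_seed(seed,
                                       sprintf("fit:%s:%d:%d", kind, r, f)),
                        fit_score(kind, Xtr, y[!te], Xte, par))
        m <- binary_metrics(sc, y[te])
        i <- i + 1L
        rows[[i]] <- data.frame(model = kind, rep = r, fold = f,
                                accuracy = m$accuracy,
                                sensitivity = m$sensitivity,
                                specificity = m$specificity,
                                auc = m$auc, kappa = m$kappa,
                                youden = m$youden,
                                stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "fold_schedule") <- schedule
  attr(out, "fold_checksum") <- vapply(schedule, function(s)
    sum(s * seq_along(s)), numeric(1))
  attr(out, "n_auc_undefined") <- sum(is.na(out$auc))
  class(out) <- c("resample_table", "data.frame")
  out
}

#' Median and interquartile range of resampled metrics per model
#'
#' Quartiles use linear interpolation (R's default type 7).
#'
#' @param resamples A [repeated_cv()] table.
#' @return A data.frame with one row per (model, metric).
#' @export
summarize_resamples <- function(resamples) {
  metrics <- c("accuracy", "sensitivity", "specificity", "auc",
               "kappa", "youden")
  rows <- list()
  for (m in unique(resamples$model)) {
    sub <- resamples[resamples$model == m, ]
    for (met in metrics) {
      v <- sub[[met]]
      v <- v[!is.na(v)]
      q <- stats::quantile(v, c(0.25, 0.5, 0.75), type = 7)
      rows[[length(rows) + 1L]] <- data.frame(
        model = m, metric = met, median = q[[2]],
        q25 = q[[1]], q75 = q[[3]], n = length(v),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Paired comparison of models over shared resamples
#'
#' Because every model is trained and tested on the identical resample
#' schedule, per-resample metric differences are paired; each ordered
#' model pair is compared with a two-sided paired Student t-test
#' (`df = n_pairs - 1`). Resamples where the metric is undefined for
#' either model are dropped pairwise.
#'
#' @param resamples A [repeated_cv()] table.
#' @param metric Metric column name, e.g. `"auc"`.
#' @return A data.frame with one row per ordered model pair: `mean_diff`
#'   (first minus second), `t`, `p`, `n_pairs`. Antisymmetric in the pair
#'   order. All-zero differences report `t = 0, p = 1`.
#' @export
compare_models <- function(resamples, metric = "auc") {
  stopifnot(metric %in% names(resamples))
  models <- unique(resamples$model)
  key <- function(d) paste(d$rep, d$fold, sep = ":")
  rows <- list()
  for (a in models) for (b in models) {
    if (a == b) next
    da <- resamples[resamples$model == a, ]
    db <- resamples[resamples$model == b, ]
    db <- db[match(key(da), key(db)), ]
    stopifnot(!anyNA(db$model))  # pairing integrity
    diff <- da[[metric]] - db[[metric]]
    diff <- diff[!is.na(diff)]
    n <- length(diff)
    if (n < 2L || stats::sd(diff) == 0) {
      t <- 0; p <- 1
      if (n >= 1L && mean(diff) != 0) {
        t <- sign(mean(diff)) * Inf; p <- 0
      }
    } else {
      t <- mean(diff) / (stats::sd(diff) / sqrt(n))
      p <- 2 * stats::pt(-abs(t), n - 1)
    }
    rows[[length(rows) + 1L]] <- data.frame(
      model_a = a, model_b = b, metric = metric,
      mean_diff = if (n) mean(diff) else 0, t = t, p = p, n_pairs = n,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
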