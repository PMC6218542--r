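test_that("binary metrics match hand counts and the tie convention", {
  m <- binary_metrics(c(0.9, 0.8, 0.2, 0.1), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(unlist(m[c("accuracy", "sensitivity", "specificity",
                          "auc", "kappa", "youden")]),
               c(accuracy = 1, sensitivity = 1, specificity = 1,
                 auc = 1, kappa = 1, youden = 1))

  # 2 of 4 case-control pairs concordant
  m2 <- binary_metrics(c(0.9, 0.2, 0.3, 0.6), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(m2$auc, 0.5)

  # all scores tied: every pair counts 1/2
  m3 <- binary_metrics(rep(0.4, 6), rep(c(TRUE, FALSE), 3))
  expect_equal(m3$auc, 0.5)

  # one-class truth: AUC undefined
  m4 <- binary_metrics(c(0.2, 0.9), c(TRUE, TRUE))
  expect_true(is.na(m4$auc))
})

test_that("Mann-Whitney AUC agrees with pROC on random scores", {
  set.seed(10)
  truth <- rep(c(TRUE, FALSE), c(20, 25))
  scores <- rnorm(45) + truth
  ours <- binary_metrics(scores, truth)$auc
  ref <- as.numeric(pROC::auc(pROC::roc(
    response = truth, predictor = scores, levels = c(FALSE, TRUE),
    direction = "<", quiet = TRUE)))
  expect_equal(ours, ref, tolerance = 1e-12)
  # kappa cross-check against the confusion-matrix definition
  pred <- scores > 0.5
  tab <- table(factor(pred, c(FALSE, TRUE)), factor(truth, c(FALSE, TRUE)))
  po <- sum(diag(tab)) / sum(tab)
  pe <- sum(rowSums(tab) * colSums(tab)) / sum(tab)^2
  expect_equal(binary_metrics(scores, truth)$kappa, (po - pe) / (1 - pe),
               tolerance = 1e-12)
})

test_that("repeated CV emits paired resamples with exact geometry", {
  coh <- generate_cohort(cohort_design(n_cases = 15, n_controls = 15,
                                       n_proteins = 10, n_markers = 4,
                                       censor_midpoint_log2 = -Inf),
                         seed = 4)
  panel <- subset_abundance(coh$csf, proteins = coh$truth$marker_ids)
  cfg <- run_config(seed = 2, svm_cost_grid = 2^(0:2), rf_ntree = 60,
                    tune_folds = 3)
  rs <- repeated_cv(panel, coh$meta, specs = c("lda", "glm_logit", "rf"),
                    cfg = cfg, folds = 5, repeats = 3, seed = 9)
  expect_equal(nrow(rs), 3 * 5 * 3)
  expect_equal(unname(table(rs$model)), rep(15L, 3), ignore_attr = TRUE)
  # pairing: every model sees the identical (rep, fold) schedule
  for (m in unique(rs$model))
    expect_identical(rs[rs$model == m, c("rep", "fold")],
                     rs[rs$model == "lda", c("rep", "fold")],
                     ignore_attr = TRUE)
  expect_length(attr(rs, "fold_checksum"), 3L)
  # youden identity to machine precision
  expect_equal(rs$youden, rs$sensitivity + rs$specificity - 1,
               tolerance = 1e-15)
  # determinism
  rs2 <- repeated_cv(panel, coh$meta, specs = c("lda", "glm_logit", "rf"),
                     cfg = cfg, folds = 5, repeats = 3, seed = 9)
  expect_identical(rs$auc, rs2$auc)
})

test_that("perfectly separated panel gives median AUC 1 for every model", {
  set.seed(5)
  n <- 24
  vals <- rbind(sep1 = c(rnorm(n / 2, 5, 0.1), rnorm(n / 2, -5, 0.1)),
                sep2 = c(rnorm(n / 2, 3, 0.1), rnorm(n / 2, -3, 0.1)))
  m <- abundance_matrix(vals, c("sep1", "sep2"), sprintf("S%02d", 1:n),
                        matrix(FALSE, 2, n), "log2")
  meta <- toy_meta(n / 2, n / 2)
  cfg <- run_config(seed = 3, svm_cost_grid = c(1, 4), rf_ntree = 60,
                    tune_folds = 3)
  rs <- repeated_cv(m, meta, specs = c("lda", "glm_logit", "svm_rbf", "rf"),
                    cfg = cfg, folds = 4, repeats = 3, seed = 7)
  med <- summarize_resamples(rs)
  expect_true(all(med$median[med$metric == "auc"] == 1))
})

test_that("model comparison is paired, antisymmetric, and handles ties", {
  rs <- expand.grid(model = c("a", "b"), rep = 1:10, fold = 1:5,
                    stringsAsFactors = FALSE)
  set.seed(11)
  base <- rnorm(50, 0.8, 0.05)
  rs$auc <- ifelse(rs$model == "a", base[(rs$rep - 1) * 5 + rs$fold] + 0.01,
                   base[(rs$rep - 1) * 5 + rs$fold])
  cmp <- compare_models(rs, "auc")
  ab <- cmp[cmp$model_a == "a" & cmp$model_b == "b", ]
  ba <- cmp[cmp$model_a == "b" & cmp$model_b == "a", ]
  expect_equal(ab$mean_diff, 0.01, tolerance = 1e-12)
  expect_equal(ab$mean_diff, -ba$mean_diff)
  expect_equal(ab$p, 0)  # constant shift: paired t degenerate, p -> 0

  # identical copies: mean diff 0, p = 1
  rs$auc <- base[(rs$rep - 1) * 5 + rs$fold]
  cmp0 <- compare_models(rs, "auc")
  expect_true(all(cmp0$mean_diff == 0) && all(cmp0$p == 1))

  # noisy pair agrees with stats::t.test(paired = TRUE)
  rs$auc <- rnorm(100, 0.8, 0.05)
  cmp2 <- compare_models(rs, "auc")
  a <- rs$auc[rs$model == "a"][order(rs$rep[rs$model == "a"],
                                     rs$fold[rs$model == "a"])]
  b <- rs$auc[rs$model == "b"][order(rs$rep[rs$model == "b"],
                                     rs$fold[rs$model == "b"])]
  ref <- t.test(a, b, paired = TRUE)
  ab2 <- cmp2[cmp2$model_a == "a" & cmp2$model_b == "b", ]
  expect_equal(ab2$t, unname(ref$statistic), tolerance = 1e-9)
  expect_equal(ab2$p, ref$p.value, tolerance = 1e-9)
})
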