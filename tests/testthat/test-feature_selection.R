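test_that("pruning removes the member with the larger mean correlation", {
  target <- matrix(c(1, 0.9, 0.5,
                     0.9, 1, 0.1,
                     0.5, 0.1, 1), 3, 3,
                   dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  X <- make_corr_data(target, n = 30, seed = 2)
  expect_equal(cor(t(X)), target, tolerance = 1e-9, ignore_attr = TRUE)
  res <- prune_correlated(X, threshold = 0.6)
  # A's mean |r| (0.7) exceeds B's (0.5): A is removed, {B, C} retained
  expect_identical(res$retained, c("B", "C"))
  expect_identical(res$trace$removed, "A")

  # brute force over removal orders: {B, C} is the unique rule-consistent
  # endpoint (removing B instead leaves |r(A,C)| = 0.5 <= 0.6 but violates
  # the retention criterion); verify no retained pair exceeds the threshold
  cm <- cor(t(X))
  for (pair in combn(res$retained, 2, simplify = FALSE))
    expect_lte(abs(cm[pair[1], pair[2]]), 0.6)
})

test_that("pruning identity and total-collapse edge cases", {
  set.seed(4)
  X <- matrix(rnorm(5 * 40), 5, dimnames = list(paste0("P", 1:5), NULL))
  res <- prune_correlated(X, threshold = 0.99)
  expect_identical(res$retained, paste0("P", 1:5))
  expect_equal(nrow(res$trace), 0L)

  base <- rnorm(40)
  Xi <- rbind(A = base, B = base, C = base)
  resi <- prune_correlated(Xi, threshold = 0.6)
  expect_length(resi$retained, 1L)
})

test_that("pruned output never contains a pair above the threshold", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- 20
    X <- matrix(rnorm(15 * n), 15)
    X[2, ] <- X[1, ] + rnorm(n, 0, 0.3)
    X[3, ] <- X[1, ] + rnorm(n, 0, 0.4)
    X[10, ] <- -X[9, ] + rnorm(n, 0, 0.2)
    rownames(X) <- paste0("P", 1:15)
    res <- prune_correlated(X, threshold = 0.6)
    cm <- abs(cor(t(X[res$retained, ])))
    diag(cm) <- 0
    expect_lte(max(cm), 0.6)
  }
})

test_that("panel selection takes the k smallest p among q-passing proteins", {
  diff <- data.frame(protein_id = paste0("P", 1:10),
                     p = c(1e-6, 2e-6, 5e-4, 1e-3, 2e-3, 4e-3,
                           0.2, 0.4, 0.6, 0.9),
                     q = c(rep(0.01, 6), rep(0.5, 4)),
                     stringsAsFactors = FALSE)
  pan <- select_panel(diff, retained = diff$protein_id, q_max = 0.05, k = 5)
  expect_identical(pan$panel, paste0("P", 1:5))
  expect_equal(pan$n_qualifying, 6)

  expect_warning(p3 <- select_panel(diff, retained = paste0("P", c(1, 3, 5)),
                                    k = 5),
                 "only 3")
  expect_identical(p3$panel, paste0("P", c(1, 3, 5)))
  expect_warning(p0 <- select_panel(diff, retained = paste0("P", 7:10)),
                 "empty panel")
  expect_length(p0$panel, 0L)
  expect_error(select_panel(diff, retained = "P99"), "P99")
})

test_that("RFE profile structure, size guard, and determinism", {
  set.seed(6)
  coh <- generate_cohort(cohort_design(n_cases = 15, n_controls = 15,
                                       n_proteins = 12, n_markers = 3,
                                       censor_midpoint_log2 = -Inf),
                         seed = 8)
  cfg <- run_config(seed = 1, rf_ntree = 60)
  expect_warning(
    prof <- rfe(coh$csf, coh$meta, model = "rf",
                sizes = c(1, 2, 4, 8, 20), folds = 3, repeats = 2,
                cfg = cfg, seed = 5),
    "dropping subset size")
  expect_identical(prof$sizes, c(1L, 2L, 4L, 8L))
  expect_equal(dim(prof$resample_auc), c(6L, 4L))
  expect_true(all(prof$mean_auc >= 0 & prof$mean_auc <= 1))
  expect_equal(ncol(prof$rankings), 6L)
  expect_gte(prof$chosen_size, prof$simplified_size)

  prof2 <- suppressWarnings(
    rfe(coh$csf, coh$meta, model = "rf", sizes = c(1, 2, 4, 8, 20),
        folds = 3, repeats = 2, cfg = cfg, seed = 5))
  expect_identical(prof$resample_auc, prof2$resample_auc)
  expect_identical(prof$final_ranking, prof2$final_ranking)
})

test_that("tolerance simplification picks the smallest size within 5%", {
  prof <- list(sizes = c(5L, 12L, 18L), mean_auc = c(0.80, 0.86, 0.89))
  expect_equal(simplify_within_tolerance(prof, 0.05), 12L)
  flat <- list(sizes = c(3L, 7L, 9L), mean_auc = c(0.7, 0.7, 0.7))
  expect_equal(simplify_within_tolerance(flat, 0.05), 3L)
  expect_equal(simplify_within_tolerance(prof, 0), 18L)
  tie <- list(sizes = c(2L, 6L), mean_auc = c(0.9, 0.9))
  expect_equal(simplify_within_tolerance(tie, 0), 2L)
})
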