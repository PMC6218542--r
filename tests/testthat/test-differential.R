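test_that("pooled t-test matches the closed form and stats::t.test", {
  r <- ttest_two_group(c(1, 2, 3), c(4, 5, 6))
  # hand formula: sp = 1, t = -3 / (1 * sqrt(2/3))
  expect_equal(r$mean_diff, -3)
  expect_equal(r$t_stat, -3 / sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(r$t_stat, -3.674, tolerance = 1e-3)
  expect_equal(r$p, 0.0213, tolerance = 2e-3)
  expect_equal(r$df, 4)

  set.seed(1)
  x <- rnorm(9); y <- rnorm(12, 0.4)
  ours <- ttest_two_group(x, y)
  ref <- t.test(x, y, var.equal = TRUE)
  expect_equal(ours$t_stat, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(ours$p, ref$p.value, tolerance = 1e-12)
  refw <- t.test(x, y)
  oursw <- ttest_two_group(x, y, var_equal = FALSE)
  expect_equal(oursw$p, refw$p.value, tolerance = 1e-12)
})

test_that("t-test degenerate and affine properties", {
  r <- ttest_two_group(c(5, 6, 7), c(5, 6, 7))
  expect_equal(r$t_stat, 0)
  expect_equal(r$p, 1)
  expect_warning(rz <- ttest_two_group(c(2, 2), c(3, 3)), "zero variance")
  expect_equal(rz$p, 0)

  set.seed(2)
  x <- rnorm(5); y <- rnorm(5)
  a <- ttest_two_group(x, y)
  b <- ttest_two_group(10 * x, 10 * y)
  expect_equal(b$t_stat, a$t_stat, tolerance = 1e-12)
  expect_equal(b$p, a$p, tolerance = 1e-12)
  expect_equal(b$mean_diff, 10 * a$mean_diff, tolerance = 1e-12)
})

test_that("differential table is invariant under sample reordering", {
  m <- toy_matrix(P = 12, n1 = 5, n2 = 5, effect = 1.5, seed = 3)
  meta <- toy_meta(5, 5)
  tab <- differential_table(m, meta)
  perm <- sample(seq_len(10))
  m2 <- subset_abundance(m, samples = perm)
  tab2 <- differential_table(m2, meta)
  expect_equal(tab2$t_stat, tab$t_stat, tolerance = 1e-12)
  expect_identical(tab2$protein_id, tab$protein_id)
  expect_error(differential_table(m, meta, c("ALS", "disease_control")),
               "disease_control")
})

test_that("permutation FDR agrees with exhaustive label enumeration", {
  m <- toy_matrix(P = 8, n1 = 3, n2 = 3, effect = 3, seed = 21)
  meta <- toy_meta(3, 3)
  res <- permutation_fdr(m, meta, n_perm = 250, seed = 5)

  # independent oracle: enumerate all 10 distinct splits of 6 samples
  # into two groups of 3 and rebuild FP-hat / q by direct loops
  vals <- m$values
  splits <- combn(6, 3)
  splits <- splits[, splits[1, ] == 1, drop = FALSE]  # distinct partitions
  abs_t <- function(i1) {
    i2 <- setdiff(1:6, i1)
    apply(vals, 1, function(v) {
      sp <- sqrt(((2) * var(v[i1]) + 2 * var(v[i2])) / 4)
      abs((mean(v[i1]) - mean(v[i2])) / (sp * sqrt(2 / 3)))
    })
  }
  obs <- abs_t(1:3)
  null_mat <- sapply(seq_len(ncol(splits)), function(j) abs_t(splits[, j]))
  q_exact <- sapply(seq_along(obs), function(i) {
    fp <- mean(colSums(null_mat >= obs[i]))
    fp / sum(obs >= obs[i])
  })
  ord <- order(obs, decreasing = TRUE)
  q_exact[ord] <- rev(cummin(rev(q_exact[ord])))
  q_exact <- pmin(q_exact, 1)
  expect_lt(max(abs(res$q - q_exact)), 0.15)
  expect_gt(cor(res$q, q_exact), 0.9)
})

test_that("q is monotone in |t| and respects the permutation count guard", {
  m <- toy_matrix(P = 30, n1 = 5, n2 = 5, effect = 2, seed = 4)
  meta <- toy_meta(5, 5)
  res <- permutation_fdr(m, meta, n_perm = 60, seed = 2)
  ord <- order(abs(res$t_stat), decreasing = TRUE)
  expect_true(all(diff(res$q[ord]) >= -1e-12))
  expect_true(all(res$q >= 0 & res$q <= 1))
  expect_error(permutation_fdr(m, meta, n_perm = 5), "meaningless")
  # determinism
  res2 <- permutation_fdr(m, meta, n_perm = 60, seed = 2)
  expect_identical(res$q, res2$q)
})

test_that("cross-fluid test: perfect correlation reports below 2/n_perm", {
  set.seed(8)
  v <- rnorm(30)
  # lm warns about the (intentionally) perfect fit
  r <- suppressWarnings(cross_fluid_test(v, v, n_perm = 1000, seed = 1))
  expect_equal(r$pearson_r, 1)
  expect_match(r$reported, "^< ")
  expect_equal(r$n_exceed, 0L)
  expect_error(cross_fluid_test(rep(1, 10), rnorm(10)), "constant")
})

test_that("cross-fluid permutation p matches exhaustive enumeration at n=5", {
  set.seed(31)
  x <- rnorm(5); y <- x + rnorm(5, 0, 0.8)
  # oracle: all 120 permutations of y
  perms <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (rest in perms(v[-i])) out <- c(out, list(c(v[i], rest)))
    out
  }
  r_obs <- cor(x, y)
  r_all <- vapply(perms(y), function(py) cor(x, py), numeric(1))
  p_exact <- min(1, 2 * mean(r_all > abs(r_obs)))
  B <- 4000
  r <- cross_fluid_test(x, y, n_perm = B, seed = 12)
  se <- sqrt(p_exact / 2 * (1 - p_exact / 2) / B) * 2
  expect_lt(abs(r$perm_p - p_exact), 3 * se + 1e-9)
})

test_that("cross-fluid table pairs observed-only samples per protein", {
  coh <- generate_cohort(cohort_design(n_proteins = 40, n_markers = 0,
                                       n_crossfluid = 3, rho = 0.9),
                         seed = 6)
  tab <- cross_fluid_table(coh$csf, coh$plasma,
                           proteins = coh$truth$crossfluid_ids,
                           n_perm = 400, seed = 3)
  expect_true(all(tab$n_pairs <= 63))
  expect_true(all(tab$perm_p <= 0.2))  # rho = 0.9 in a third of samples
})
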