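test_that("cohort generation is deterministic and structurally sound", {
  d <- cohort_design(n_proteins = 60, n_markers = 6)
  a <- generate_cohort(d, seed = 11)
  b <- generate_cohort(d, seed = 11)
  expect_identical(a$csf$values, b$csf$values)
  expect_identical(a$plasma$missing_mask, b$plasma$missing_mask)
  expect_identical(a$meta$alsfrs, b$meta$alsfrs)
  c2 <- generate_cohort(d, seed = 12)
  expect_false(identical(a$csf$values, c2$csf$values))

  expect_equal(table(a$meta$group)[["ALS"]], 33)
  expect_equal(table(a$meta$group)[["healthy"]], 30)
  expect_length(a$truth$marker_ids, 6)
  expect_true(all(a$truth$score_ids %in% a$truth$marker_ids))
  frs <- a$meta$alsfrs[a$meta$group == "ALS"]
  expect_true(all(frs >= 0 & frs <= 48))
  expect_true(all(is.na(a$meta$alsfrs[a$meta$group == "healthy"])))
})

test_that("degenerate one-group design is generated but refused downstream", {
  d <- cohort_design(n_cases = 0, n_controls = 10, n_proteins = 20,
                     n_markers = 5, score_coeffs = c(0, 0, 0))
  coh <- generate_cohort(d, seed = 2)
  expect_identical(unique(coh$meta$group), "healthy")
  imp <- impute_downshift(coh$csf, seed = 1)$matrix
  expect_error(differential_table(imp, coh$meta), "ALS")
})

test_that("null design yields ~5% of proteins at p < 0.05", {
  d <- cohort_design(n_cases = 30, n_controls = 30, n_proteins = 500,
                     n_markers = 0, censor_midpoint_log2 = -Inf)
  coh <- generate_cohort(d, seed = 7)
  tab <- differential_table(coh$csf, coh$meta)
  frac <- mean(tab$p < 0.05)
  band <- binom_band(500, 0.05)
  expect_gte(frac, band[1])
  expect_lte(frac, band[2])
})

test_that("pre-censoring marker group difference matches the planted effect", {
  d <- cohort_design(n_proteins = 100, n_markers = 10, effect_log2 = 1)
  coh <- generate_cohort(d, seed = 13)
  pre <- coh$truth$pre_censor$csf
  is_case <- coh$meta$group == "ALS"
  diffs <- rowMeans(pre$values[coh$truth$marker_ids, is_case]) -
    rowMeans(pre$values[coh$truth$marker_ids, !is_case])
  # CLT tolerance: sd 0.5, n 33/30 => se ~ 0.126; 3.5 se margin per marker
  expect_true(all(abs(diffs - coh$truth$marker_effects) < 0.45))
})

test_that("censoring is value-dependent, monotone, and mask-only", {
  m <- toy_matrix(P = 200, n1 = 10, n2 = 10, seed = 9, sd = 3)
  cen <- apply_censoring(m, midpoint = quantile(m$values, 0.2),
                         steepness = 2, seed = 5)
  expect_identical(cen$values[!cen$missing_mask],
                   m$values[!cen$missing_mask])
  # missingness rate decreasing in value across deciles
  dec <- cut(m$values, quantile(m$values, seq(0, 1, 0.1)),
             include.lowest = TRUE, labels = FALSE)
  rate <- tapply(as.vector(cen$missing_mask), dec, mean)
  expect_lt(cor(seq_along(rate), rate, method = "spearman"), 0)

  flat <- apply_censoring(m, midpoint = 0, steepness = 0, seed = 5)
  expect_equal(mean(flat$missing_mask), 0.5, tolerance = 0.05)
  none <- apply_censoring(m, midpoint = -Inf, steepness = 1, seed = 5)
  expect_equal(sum(none$missing_mask), 0L)
})

test_that("score regression recovers coefficient signs and design R2", {
  d <- cohort_design(n_proteins = 50, n_markers = 5,
                     censor_midpoint_log2 = -Inf)
  coh <- generate_cohort(d, seed = 17)
  cases <- coh$meta$group == "ALS"
  X <- t(coh$csf$values[coh$truth$score_ids, cases])
  y <- coh$meta$alsfrs[cases]
  fit <- fit_ols(X, y)
  est <- fit$coefficients[-1, 1]
  expect_identical(sign(est), sign(coh$truth$score_coeffs),
                   ignore_attr = TRUE)
  implied <- {
    sig <- sum(coh$truth$score_coeffs^2) * d$within_sd_log2^2
    sig / (sig + d$score_noise_sd^2)
  }
  expect_lt(abs(fit$r_squared - implied), 0.15)
})

test_that("targeted generator: structure, determinism, degenerate group", {
  g <- generate_targeted(seed = 3)
  expect_equal(nrow(g$report), 4 * (11 + 15 + 12))
  expect_true(all(g$report$light_area > 0 & g$report$heavy_area > 0))
  g2 <- generate_targeted(seed = 3)
  expect_identical(g$report$light_area, g2$report$light_area)
  expect_warning(generate_targeted(c(ALS = 1, healthy = 5),
                                   peptide_effects = matrix(
                                     1, 1, 2, dimnames = list("p1",
                                       c("ALS", "healthy"))),
                                   seed = 1),
                 "single sample")
})
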