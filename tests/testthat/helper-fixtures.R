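# Shared fixture builders for the suite. Everything is generated in code;
# no binary fixtures are stored.

# A small fully observed log2-scale matrix with group structure.
toy_matrix <- function(P = 8, n1 = 3, n2 = 3, effect = 0, seed = 42,
                       sd = 1) {
  set.seed(seed)
  vals <- matrix(rnorm(P * (n1 + n2), 20, sd), P)
  if (effect != 0) vals[1:2, 1:n1] <- vals[1:2, 1:n1] + effect
  abundance_matrix(vals, sprintf("P%02d", 1:P),
                   sprintf("S%02d", 1:(n1 + n2)),
                   matrix(FALSE, P, n1 + n2), "log2")
}

toy_meta <- function(n1 = 3, n2 = 3, groups = c("ALS", "healthy")) {
  sample_table(data.frame(
    sample_id = sprintf("S%02d", 1:(n1 + n2)),
    group = rep(groups, c(n1, n2)),
    stringsAsFactors = FALSE))
}

# Rows of the result have *exactly* the requested sample correlation
# structure: whiten an arbitrary draw, then color with chol(target).
make_corr_data <- function(target, n = 24, seed = 7) {
  set.seed(seed)
  p <- nrow(target)
  Z <- matrix(rnorm(p * n), p)
  Z <- Z - rowMeans(Z)
  C0 <- tcrossprod(Z) / (n - 1)
  X <- t(chol(target)) %*% solve(t(chol(C0))) %*% Z
  rownames(X) <- rownames(target)
  X
}

# 99% binomial acceptance band for an empirical rejection rate.
binom_band <- function(n, p = 0.05, level = 0.99) {
  a <- (1 - level) / 2
  qbinom(c(a, 1 - a), n, p) / n
}

expect_in_band <- function(rate, n, p = 0.05) {
  band <- binom_band(n, p)
  expect_gte(rate, band[1])
  expect_lte(rate, band[2])
}
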