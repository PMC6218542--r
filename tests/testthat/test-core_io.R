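test_that("plain TSV reader masks blank and zero cells as missing", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("protein_id\tA\tB",
               "P1\t100\t200",
               "P2\t\t300",
               "P3\t400\t500"), f)
  m <- read_abundance_table(f, "plain_tsv")
  expect_equal(dim(m), c(3L, 2L))
  expect_equal(sum(m$missing_mask), 1L)
  expect_true(m$missing_mask["P2", "A"])
  expect_identical(m$scale_tag, "raw")

  # a literal 0 is non-detection, not a measured zero: summary statistics
  # must change when the mask is honoured
  f0 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("protein_id\tA\tB\tC",
               "P1\t0\t8\t8"), f0)
  m0 <- read_abundance_table(f0, "plain_tsv")
  expect_true(m0$missing_mask["P1", "A"])
  masked_mean <- mean(m0$values["P1", ], na.rm = TRUE)
  naive_mean <- mean(c(0, 8, 8))
  expect_equal(masked_mean, 8)
  expect_false(isTRUE(all.equal(masked_mean, naive_mean)))
})

test_that("MaxQuant dialect keeps only LFQ intensity columns", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c(paste("Protein IDs", "LFQ intensity A", "LFQ intensity B",
                     "Razor peptides", sep = "\t"),
               "CHI3L1\t1e6\t0\t12",
               "SERPINA3\t2e6\t3e6\t7"), f)
  m <- read_abundance_table(f, "maxquant_lfq")
  expect_identical(m$sample_ids, c("A", "B"))
  expect_identical(m$protein_ids, c("CHI3L1", "SERPINA3"))
  expect_true(m$missing_mask["CHI3L1", "B"])

  f2 <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("Protein IDs\tRazor peptides", "P1\t3"), f2)
  expect_error(read_abundance_table(f2, "maxquant_lfq"),
               "no quantitative columns")
})

test_that("duplicate protein ids are rejected with the offending id", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("protein_id\tA\tB", "P1\t1\t2", "P1\t3\t4"), f)
  expect_error(read_abundance_table(f), "P1")
})

test_that("abundance TSV round-trip preserves values, ids, and mask", {
  m <- toy_matrix(P = 6, n1 = 3, n2 = 3, seed = 11)
  m$values[2, 3] <- NA
  m <- abundance_matrix(m$values, m$protein_ids, m$sample_ids,
                        is.na(m$values), "log2")
  f <- withr::local_tempfile(fileext = ".tsv")
  write_abundance_table(m, f, provenance = c(seed = "1"))
  m2 <- read_abundance_tsv(f)
  expect_identical(m2$protein_ids, m$protein_ids)
  expect_identical(m2$sample_ids, m$sample_ids)
  expect_identical(m2$missing_mask, m$missing_mask)
  expect_equal(m2$values, m$values, tolerance = 1e-12)
  expect_identical(m2$scale_tag, "log2")
})

test_that("sample metadata is validated: enums, bounds, duplicates", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tgroup",
               "S1\tALS", "S2\tALS", "S3\thealthy", "S4\thealthy"), f)
  meta <- read_sample_metadata(f)
  expect_s3_class(meta, "sample_table")
  expect_equal(nrow(meta), 4L)

  expect_error(sample_table(data.frame(sample_id = "S1", group = "ALs")),
               "unknown group")
  expect_error(sample_table(data.frame(sample_id = c("S1", "S1"),
                                       group = c("ALS", "ALS"))),
               "duplicated sample_id")
  expect_error(sample_table(data.frame(sample_id = "S9", group = "ALS",
                                       alsfrs = 49)),
               "S9")
})

test_that("matrix columns missing from metadata raise an alignment error", {
  m <- toy_matrix(n1 = 2, n2 = 2)
  meta <- toy_meta(2, 2)
  meta <- meta[meta$sample_id != "S03", ]
  expect_error(align_samples(m, meta), "S03")
})

test_that("per-stage substream seeds are deterministic and distinct", {
  expect_identical(substream_seed(7, "fdr"), substream_seed(7, "fdr"))
  expect_false(substream_seed(7, "fdr") == substream_seed(7, "impute"))
  expect_false(substream_seed(7, "fdr") == substream_seed(8, "fdr"))
  s <- vapply(1:200, function(i) substream_seed(i, "x"), integer(1))
  expect_true(all(s >= 1 & s <= 2147483646))
})
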