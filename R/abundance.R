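#' Protein-by-sample abundance matrix with explicit missingness
#'
#' The central container of the pipeline: a numeric proteins x samples
#' grid together with a boolean mask of the same shape recording which
#' cells were *not* quantified, and a scale tag (`"raw"` intensities or
#' `"log2"`). Masked cells never contribute to any downstream statistic;
#' in label-free quantification output a reported 0 means "not detected",
#' not an abundance of zero, and is masked at read time.
#'
#' @param values Numeric matrix, proteins in rows and samples in columns.
#' @param protein_ids Character vector of unique protein identifiers.
#' @param sample_ids Character vector of unique sample identifiers.
#' @param missing_mask Logical matrix, same shape as `values`; `TRUE`
#'   marks a non-quantified cell. Defaults to `is.na(values)`.
#' @param scale_tag `"raw"` or `"log2"`.
#' @return An object of class `abundance_matrix`.
#' @export
abundance_matrix <- function(values, protein_ids = rownames(values),
                             sample_ids = colnames(values),
                             missing_mask = NULL,
                             scale_tag = c("raw", "log2")) {
  scale_tag <- match.arg(scale_tag)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(protein_ids) || is.null(sample_ids))
    stop("protein and sample identifiers are required")
  protein_ids <- as.character(protein_ids)
  sample_ids <- as.character(sample_ids)
  if (anyDuplicated(protein_ids))
    stop("duplicate protein id: ",
         paste(unique(protein_ids[duplicated(protein_ids)]), collapse = ", "))
  if (anyDuplicated(sample_ids))
    stop("duplicate sample id: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  if (nrow(values) != length(protein_ids) ||
      ncol(values) != length(sample_ids))
    stop("grid dimensions do not match identifier lists")
  if (is.null(missing_mask)) missing_mask <- is.na(values)
  missing_mask <- as.matrix(missing_mask)
  if (!is.logical(missing_mask) || !identical(dim(missing_mask), dim(values)))
    stop("missing_mask must be a logical matrix of the same shape")
  if (any(is.na(values) & !missing_mask))
    stop("non-finite unmasked values present")
  values[missing_mask] <- NA_real_
  dimnames(values) <- dimnames(missing_mask) <-
    list(protein_ids, sample_ids)
  structure(list(values = values, missing_mask = missing_mask,
                 protein_ids = protein_ids, sample_ids = sample_ids,
                 scale_tag = scale_tag),
            class = "abundance_matrix")
}

#' @export
print.abundance_matrix <- function(x, ...) {
  cat("abundance_matrix: ", length(x$protein_ids), " proteins x ",
      length(x$sample_ids), " samples (", x$scale_tag, " scale), ",
      sum(x$missing_mask), " missing cells (",
      sprintf("%.1f%%", 100 * mean(x$missing_mask)), ")\n", sep = "")
  invisible(x)
}

#' @export
dim.abundance_matrix <- function(x) dim(x$values)

#' Subset an abundance matrix by protein and/or sample
#'
#' @param x An `abundance_matrix`.
#' @param proteins,samples Identifier or index vectors; `NULL` keeps all.
#' @return A new `abundance_matrix`.
#' @export
subset_abundance <- function(x, proteins = NULL, samples = NULL) {
  stopifnot(inherits(x, "abundance_matrix"))
  pi <- if (is.null(proteins)) seq_along(x$protein_ids) else proteins
  si <- if (is.null(samples)) seq_along(x$sample_ids) else samples
  if (is.character(pi)) {
    miss <- setdiff(pi, x$protein_ids)
    if (length(miss)) stop("unknown protein id: ",
                           paste(miss, collapse = ", "))
    pi <- match(pi, x$protein_ids)
  }
  if (is.character(si)) {
    miss <- setdiff(si, x$sample_ids)
    if (length(miss)) stop("unknown sample id: ",
                           paste(miss, collapse = ", "))
    si <- match(si, x$sample_ids)
  }
  abundance_matrix(x$values[pi, si, drop = FALSE],
                   x$protein_ids[pi], x$sample_ids[si],
                   x$missing_mask[pi, si, drop = FALSE],
                   x$scale_tag)
}

#' Read a protein abundance table
#'
#' Reads a tab- or comma-separated protein x sample quantification table.
#' Two dialects are supported: `plain_tsv`, where the first column holds
#' protein identifiers and every remaining column is a sample, and
#' `maxquant_lfq`, the MaxQuant `proteinGroups` convention where sample
#' columns are those whose header starts with `"LFQ intensity "` and the
#' protein identifier column is `Protein IDs` (or the first column).
#'
#' Zeros and empty cells are masked as missing: in LFQ output a zero
#' encodes non-quantification (left-censored non-detection), not a
#' measured zero abundance.
#'
#' @param path Path to a TSV/CSV file.
#' @param dialect `"plain_tsv"` or `"maxquant_lfq"`.
#' @param sep Field separator; defaults to tab, use `","` for CSV.
#' @return An `abundance_matrix` with `scale_tag = "raw"`.
#' @export
read_abundance_table <- function(path, dialect = c("plain_tsv", "maxquant_lfq"),
                                 sep = "\t") {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          comment.char = "")
  if (dialect == "maxquant_lfq") {
    idcol <- if ("Protein IDs" %in% names(df)) "Protein IDs" else names(df)[1]
    quant <- grep("^LFQ intensity ", names(df), value = TRUE)
    if (length(quant) == 0L)
      stop("no quantitative columns: expected headers prefixed 'LFQ intensity '")
    ids <- as.character(df[[idcol]])
    vals <- as.matrix(df[quant])
    colnames(vals) <- sub("^LFQ intensity ", "", quant)
  } else {
    if (ncol(df) < 2L) stop("no quantitative columns found")
    ids <- as.character(df[[1L]])
    vals <- as.matrix(df[-1L])
    if (!is.numeric(vals)) storage.mode(vals) <- "double"
  }
  storage.mode(vals) <- "double"
  mask <- is.na(vals) | vals == 0
  abundance_matrix(vals, ids, colnames(vals), mask, scale_tag = "raw")
}

#' Write an abundance matrix to TSV
#'
#' Masked cells are written as `NA`. A provenance header (key = value
#' comment lines) can be prepended; [read_abundance_table()] does not
#' consume it, so use [read_abundance_tsv()] for round-trips.
#'
#' @param x An `abundance_matrix`.
#' @param path Output path.
#' @param provenance Optional named character vector written as
#'   `# key = value` comment lines.
#' @return `path`, invisibly.
#' @export
write_abundance_table <- function(x, path, provenance = NULL) {
  stopifnot(inherits(x, "abundance_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(provenance))
    writeLines(paste0("# ", names(provenance), " = ", provenance), con)
  writeLines(paste0("# scale = ", x$scale_tag), con)
  df <- data.frame(protein_id = x$protein_ids, x$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV written by [write_abundance_table()]
#'
#' @param path Input path.
#' @return An `abundance_matrix`; `NA` cells are masked, zeros are kept
#'   as measured values (the LFQ zero convention applies only to raw
#'   instrument exports read via [read_abundance_table()]).
#' @export
read_abundance_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  hdr <- grep("^#", lines)
  scale_tag <- "raw"
  if (length(hdr)) {
    sc <- grep("^# scale = ", lines[hdr], value = TRUE)
    if (length(sc)) scale_tag <- sub("^# scale = ", "", sc[1])
  }
  df <- utils::read.table(text = lines, header = TRUE, sep = "\t",
                          check.names = FALSE, comment.char = "#",
                          stringsAsFactors = FALSE)
  vals <- as.matrix(df[-1L])
  storage.mode(vals) <- "double"
  abundance_matrix(vals, as.character(df[[1L]]), colnames(vals),
                   is.na(vals), scale_tag = scale_tag)
}

#' Read and validate a sample metadata table
#'
#' Expects at least `sample_id` and `group` columns; recognised optional
#' columns are `fluid` (CSF/plasma), `age`, `sex`, `cycle` (preparation
#' block), and `alsfrs` (ALS Functional Rating Scale total, an integer
#' 0-48).
#'
#' @param path Path to a TSV/CSV file.
#' @param sep Field separator.
#' @return A validated `data.frame` of class `sample_table`.
#' @export
read_sample_metadata <- function(path, sep = "\t") {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  sample_table(df)
}

#' Validate a sample metadata data.frame
#'
#' @param df A data.frame with `sample_id` and `group` columns.
#' @return `df` with class `sample_table` prepended.
#' @export
sample_table <- function(df) {
  need <- c("sample_id", "group")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("metadata missing required column(s): ",
                         paste(miss, collapse = ", "))
  df$sample_id <- as.character(df$sample_id)
  if (anyDuplicated(df$sample_id))
    stop("duplicated sample_id: ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  groups <- c("ALS", "healthy", "disease_control")
  bad <- setdiff(unique(df$group), groups)
  if (length(bad))
    stop("unknown group label(s): ", paste(bad, collapse = ", "),
         " (expected ", paste(groups, collapse = "/"), ")")
  if ("fluid" %in% names(df)) {
    badf <- setdiff(unique(stats::na.omit(df$fluid)), c("CSF", "plasma"))
    if (length(badf))
      stop("unknown fluid label(s): ", paste(badf, collapse = ", "))
  }
  if ("alsfrs" %in% names(df)) {
    v <- df$alsfrs
    bad <- which(!is.na(v) & (v < 0 | v > 48))
    if (length(bad))
      stop("alsfrs out of range 0-48 for sample(s): ",
           paste(df$sample_id[bad], collapse = ", "))
  }
  class(df) <- c("sample_table", "data.frame")
  df
}

#' Check that a matrix's samples all resolve to metadata rows
#'
#' @param x An `abundance_matrix`.
#' @param meta A `sample_table`.
#' @return Invisibly, the metadata rows reordered to match the matrix
#'   columns. Errors listing orphan columns otherwise.
#' @export
align_samples <- function(x, meta) {
  stopifnot(inherits(x, "abundance_matrix"))
  idx <- match(x$sample_ids, meta$sample_id)
  if (anyNA(idx))
    stop("matrix sample(s) absent from metadata: ",
         paste(x$sample_ids[is.na(idx)], collapse = ", "))
  invisible(meta[idx, , drop = FALSE])
}
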