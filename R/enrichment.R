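#' Hypergeometric over-representation test for one pathway
#'
#' Upper-tail hypergeometric test of whether a hit list drawn from an
#' empirical background overlaps a pathway more than chance:
#' `p = P[X >= k]` for `X ~ Hypergeometric(N, K, n)` with background size
#' N, pathway size K (after intersection with the background), hit-list
#' size n, and overlap k. `k = 0` gives p = 1 (the whole support).
#'
#' @param hits Character vector of significant protein ids (must be a
#'   subset of `background`).
#' @param pathway Character vector of pathway member ids; intersected
#'   with the background before testing.
#' @param background Character vector of detectable protein ids.
#' @param direction Optional named sign vector (+1 up, -1 down) over the
#'   hits, used for the up/down fractions of the overlap.
#' @return A list of class `enrichment_result` with `N`, `K`, `n`, `k`,
#'   `p`, `overlap` ids, `frac_up`, `frac_down`.
#' @export
hypergeometric_enrichment <- function(hits, pathway, background,
                                      direction = NULL) {
  background <- unique(background)
  if (length(background) == 0L) stop("empty background")
  hits <- unique(hits)
  extra <- setdiff(hits, background)
  if (length(extra))
    stop("hit(s) outside the background: ", paste(extra, collapse = ", "))
  pw <- intersect(unique(pathway), background)
  if (length(pw) == 0L) {
    warning("pathway disjoint from background; skipped")
    return(NULL)
  }
  N <- length(background); K <- length(pw); n <- length(hits)
  overlap <- intersect(hits, pw)
  k <- length(overlap)
  p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  frac_up <- frac_down <- NA_real_
  if (!is.null(direction) && k > 0) {
    d <- direction[overlap]
    frac_up <- mean(d > 0, na.rm = TRUE)
    frac_down <- mean(d < 0, na.rm = TRUE)
  }
  structure(list(N = N, K = K, n = n, k = k, p = p, overlap = overlap,
                 frac_up = frac_up, frac_down = frac_down),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat("enrichment: overlap ", x$k, "/", x$n, " hits in a pathway of ",
      x$K, " (background ", x$N, "), p = ", format(x$p, digits = 3),
      "\n", sep = "")
  invisible(x)
}

#' Test a collection of pathways with Benjamini-Hochberg correction
#'
#' @param hits,background As in [hypergeometric_enrichment()].
#' @param pathways Named list of pathway member vectors (e.g. from
#'   [read_gmt()]).
#' @param direction Optional named sign vector over the hits.
#' @return A data.frame, one row per testable pathway, with `p` and
#'   BH-adjusted `p_adj`, sorted by p.
#' @export
enrichment_table <- function(hits, pathways, background, direction = NULL) {
  stopifnot(is.list(pathways), !is.null(names(pathways)))
  rows <- list()
  for (nm in names(pathways)) {
    res <- withCallingHandlers(
      hypergeometric_enrichment(hits, pathways[[nm]], background, direction),
      warning = function(w) invokeRestart("muffleWarning"))
    if (is.null(res)) next
    rows[[length(rows) + 1L]] <- data.frame(
      pathway = nm, N = res$N, K = res$K, n = res$n, k = res$k,
      p = res$p, frac_up = res$frac_up, frac_down = res$frac_down,
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) stop("no pathway overlaps the background")
  out <- do.call(rbind, rows)
  out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out <- out[order(out$p), ]
  rownames(out) <- NULL
  out
}

#' Build the empirical background from a pre-imputation matrix
#'
#' The background for over-representation testing is the set of proteins
#' actually detectable in the experiment: those quantified (unmasked) in
#' at least `min_samples` samples of the pre-imputation matrix.
#'
#' @param x An `abundance_matrix` with its missingness mask intact.
#' @param min_samples Minimum number of quantified samples (default 2).
#' @return Character vector of protein ids.
#' @export
build_empirical_background <- function(x, min_samples = 2L) {
  stopifnot(inherits(x, "abundance_matrix"))
  x$protein_ids[rowSums(!x$missing_mask) >= min_samples]
}

#' Read pathway sets in GMT format
#'
#' @param path Path to a GMT file (tab-separated: set name, description,
#'   then member ids).
#' @return Named list of member id vectors.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (requireNamespace("fgsea", quietly = TRUE))
    return(fgsea::gmtPathways(path))
  lines <- strsplit(readLines(path), "\t", fixed = TRUE)
  lines <- lines[lengths(lines) >= 3L]
  stats::setNames(lapply(lines, function(f) unique(f[-(1:2)])),
                  vapply(lines, `[`, "", 1L))
}
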