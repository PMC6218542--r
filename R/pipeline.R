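#' Run the full discovery pipeline on a matched two-fluid cohort
#'
#' Chains, per fluid: preprocessing (log2 transform if raw, per-group 25%
#' missingness filter, downshift imputation), differential abundance with
#' permutation FDR, correlation-pruned panel selection among the q < 0.05
#' proteins, and repeated cross-validated comparison of the four
#' classifiers. For CSF, additionally fits the best-subset prognostic
#' regression of the functional score on the significant proteins (when
#' scored samples are available). All stochastic stages draw substreams
#' of `cfg$seed`, so a rerun with the same inputs is byte-identical.
#'
#' @param cfg A [run_config()].
#' @param csf,plasma `abundance_matrix` objects (raw or log2 scale).
#' @param meta A `sample_table` covering both matrices' samples.
#' @param contrast Two group labels (positive class first).
#' @param models Classifier kinds for [repeated_cv()].
#' @param run_rfe Run recursive feature elimination on the plasma fluid
#'   (the supervised alternative used when few proteins pass the FDR
#'   cut); default `TRUE` when a plasma matrix is supplied.
#' @param out_dir Optional directory; stage outputs are written there as
#'   TSV files with a provenance header (seed and configuration hash).
#' @return A list of class `promark_run` with one element per fluid
#'   (each holding `preprocess`, `differential`, `panel`, `resamples`,
#'   `summary`, `comparison`, and for CSF `prognostic`), plus `config`.
#' @export
run_pipeline <- function(cfg, csf, plasma = NULL, meta,
                         contrast = c("ALS", "healthy"),
                         models = c("lda", "glm_logit", "svm_rbf", "rf"),
                         run_rfe = !is.null(plasma), out_dir = NULL) {
  stopifnot(inherits(cfg, "promark_config"))
  fluids <- list(csf = csf)
  if (!is.null(plasma)) fluids$plasma <- plasma
  out <- list(config = cfg)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "': ", conditionMessage(e), call. = FALSE))
  }
  for (fl in names(fluids)) {
    x <- fluids[[fl]]
    fl_meta <- meta[meta$sample_id %in% x$sample_ids, , drop = FALSE]
    prep <- stage(paste0(fl, ":preprocess"),
                  preprocess(x, fl_meta, contrast, cfg,
                             substream_seed(cfg$seed, paste0("impute:", fl))))
    diff <- stage(paste0(fl, ":differential"),
                  permutation_fdr(prep$matrix, fl_meta, contrast,
                                  cfg$fdr_permutations,
                                  substream_seed(cfg$seed, paste0("fdr:", fl))))
    sig <- diff$protein_id[diff$q < 0.05]
    panel <- NULL; resamples <- NULL; summary_tab <- NULL; comparison <- NULL
    if (length(sig) >= 2L) {
      pruned <- stage(paste0(fl, ":prune"),
                      prune_correlated(
                        subset_abundance(prep$matrix, proteins = sig),
                        cfg$corr_prune_threshold))
      panel <- stage(paste0(fl, ":select"),
                     select_panel(diff, pruned$retained,
                                  q_max = 0.05, k = cfg$panel_size))
    } else if (length(sig) == 1L) {
      panel <- structure(list(panel = sig, p = diff$p[match(sig, diff$protein_id)],
                              q = diff$q[match(sig, diff$protein_id)],
                              n_qualifying = 1L), class = "feature_panel")
    }
    if (!is.null(panel) && length(panel$panel) >= 2L) {
      pm <- subset_abundance(prep$matrix, proteins = panel$panel)
      resamples <- stage(paste0(fl, ":classify"),
                         repeated_cv(pm, fl_meta, models, contrast, cfg,
                                     seed = substream_seed(cfg$seed,
                                                           paste0("cv:", fl))))
      summary_tab <- summarize_resamples(resamples)
      comparison <- do.call(rbind, lapply(
        c("auc", "accuracy", "youden"),
        function(m) compare_models(resamples, m)))
    }
    res <- list(preprocess = prep$report, matrix = prep$matrix,
                filtered = prep$filtered, differential = diff,
                panel = panel, resamples = resamples,
                summary = summary_tab, comparison = comparison)
    if (fl == "csf" && "alsfrs" %in% names(fl_meta) &&
        sum(!is.na(fl_meta$alsfrs)) >= 10L && length(sig) >= 1L) {
      dp <- stats::setNames(diff$p, diff$protein_id)
      res$prognostic <- stage("csf:prognose",
                              prognostic_regression(prep$matrix, fl_meta, sig,
                                                    cfg, diff_p = dp))
    }
    if (fl == "plasma" && run_rfe) {
      pruned_all <- stage("plasma:prune_all",
                          prune_correlated(prep$matrix,
                                           cfg$corr_prune_threshold))
      pm <- subset_abundance(prep$matrix, proteins = pruned_all$retained)
      res$rfe <- stage("plasma:rfe",
                       rfe(pm, fl_meta, model = "rf", contrast = contrast,
                           cfg = cfg,
                           seed = substream_seed(cfg$seed, "rfe:plasma")))
    }
    out[[fl]] <- res
  }
  class(out) <- "promark_run"
  if (!is.null(out_dir)) write_run(out, out_dir)
  out
}

#' @export
print.promark_run <- function(x, ...) {
  cat("promark pipeline run (seed ", x$config$seed, ")\n", sep = "")
  for (fl in intersect(c("csf", "plasma"), names(x))) {
    d <- x[[fl]]$differential
    cat("  ", fl, ": ", nrow(d), " proteins tested, ",
        sum(d$p < 0.05), " with p < 0.05, ", sum(d$q < 0.05),
        " with q < 0.05", sep = "")
    if (!is.null(x[[fl]]$panel))
      cat("; panel [", paste(x[[fl]]$panel$panel, collapse = ", "), "]",
          sep = "")
    cat("\n")
  }
  if (!is.null(x$csf$prognostic))
    cat("  prognostic: k = ", x$csf$prognostic$chosen_k, ", R2 = ",
        sprintf("%.2f", x$csf$prognostic$model$r_squared), "\n", sep = "")
  invisible(x)
}

write_tsv_prov <- function(df, path, prov) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", names(prov), " = ", prov), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write the stage outputs of a pipeline run as TSV files
#'
#' Every table carries a provenance comment header with the seed and a
#' hash of the configuration, making reruns diffable.
#'
#' @param run A `promark_run`.
#' @param out_dir Output directory (created if absent).
#' @return The paths written, invisibly.
#' @export
write_run <- function(run, out_dir) {
  stopifnot(inherits(run, "promark_run"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  prov <- c(seed = run$config$seed, config_hash = config_hash(run$config))
  paths <- character()
  emit <- function(df, name) {
    p <- file.path(out_dir, paste0(name, ".tsv"))
    write_tsv_prov(df, p, prov)
    paths <<- c(paths, p)
  }
  for (fl in intersect(c("csf", "plasma"), names(run))) {
    r <- run[[fl]]
    emit(r$differential, paste0(fl, "_differential"))
    if (!is.null(r$panel) && length(r$panel$panel))
      emit(data.frame(protein_id = r$panel$panel, p = r$panel$p,
                      q = r$panel$q), paste0(fl, "_panel"))
    if (!is.null(r$resamples)) {
      emit(r$resamples, paste0(fl, "_resamples"))
      emit(r$summary, paste0(fl, "_summary"))
      emit(r$comparison, paste0(fl, "_comparison"))
    }
    if (!is.null(r$rfe))
      emit(data.frame(size = r$rfe$sizes, mean_auc = r$rfe$mean_auc),
           paste0(fl, "_rfe_profile"))
  }
  if (!is.null(run$csf$prognostic)) {
    pr <- run$csf$prognostic
    emit(as.data.frame(pr$search), "csf_prognostic_search")
    emit(data.frame(term = rownames(pr$model$coefficients),
                    pr$model$coefficients, check.names = FALSE),
         "csf_prognostic_coefficients")
  }
  invisible(paths)
}
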