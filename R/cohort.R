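#' Design of a synthetic matched two-fluid cohort
#'
#' Describes the statistical structure of a simulated case-control cohort
#' with matched CSF and plasma measurements: log-normal protein abundances,
#' a planted subset of differential markers with signed log2 mean shifts
#' (attenuated in plasma), intensity-dependent left censoring, a set of
#' proteins correlated across fluids in cases only, and a functional score
#' (0-48 integer scale) linearly driven by three of the planted markers.
#'
#' Defaults mirror a discovery cohort of 33 cases and 30 healthy controls
#' with several hundred quantified proteins, a CSF-rich differential signal
#' that is strongly attenuated in plasma, and a score model whose
#' signal-to-noise implies a multiple R-squared near 0.49.
#'
#' @param n_cases,n_controls Group sizes.
#' @param n_proteins Number of simulated proteins.
#' @param n_markers Number of planted differential proteins.
#' @param effect_log2 Signed log2 mean shift(s) for the planted markers in
#'   CSF; a scalar is recycled with alternating sign starting positive.
#' @param base_mean_log2,base_sd_log2 Protein baseline distribution (log2).
#' @param within_sd_log2 Within-protein between-subject standard deviation.
#' @param censor_midpoint_log2,censor_steepness Logistic left-censoring
#'   parameters; a cell of value v is masked with probability
#'   `plogis((midpoint - v) * steepness)`.
#' @param n_crossfluid Number of proteins correlated across fluids in
#'   cases only.
#' @param rho Target cross-fluid correlation in cases, in (-1, 1).
#' @param score_coeffs Length-3 weights of the score model; the score
#'   proteins are the first three planted markers.
#' @param score_noise_sd Residual standard deviation of the score.
#' @param score_center Target mean functional score for cases.
#' @param plasma_attenuation Multiplier in [0, 1] applied to marker
#'   effects in plasma.
#' @return A list of class `cohort_design`.
#' @export
cohort_design <- function(n_cases = 33L, n_controls = 30L,
                          n_proteins = 500L, n_markers = 25L,
                          effect_log2 = 1,
                          base_mean_log2 = 25, base_sd_log2 = 2,
                          within_sd_log2 = 0.5,
                          censor_midpoint_log2 = 21.5,
                          censor_steepness = 1,
                          n_crossfluid = 2L, rho = 0.7,
                          score_coeffs = c(4, -3, 3),
                          score_noise_sd = 3,
                          score_center = 38,
                          plasma_attenuation = 0.1) {
  if (n_markers > n_proteins) stop("n_markers must not exceed n_proteins")
  if (abs(rho) >= 1) stop("rho must lie in (-1, 1)")
  if (plasma_attenuation < 0 || plasma_attenuation > 1)
    stop("plasma_attenuation must lie in [0, 1]")
  if (n_markers > 0 && n_markers < 3 && any(score_coeffs != 0))
    stop("score model needs at least 3 planted markers (or zero coeffs)")
  if (length(effect_log2) == 1L) {
    effect_log2 <- effect_log2 * rep_len(c(1, -1), n_markers)
  } else if (length(effect_log2) != n_markers) {
    stop("effect_log2 must be scalar or length n_markers")
  }
  structure(list(
    n_cases = as.integer(n_cases), n_controls = as.integer(n_controls),
    n_proteins = as.integer(n_proteins), n_markers = as.integer(n_markers),
    effect_log2 = effect_log2,
    base_mean_log2 = base_mean_log2, base_sd_log2 = base_sd_log2,
    within_sd_log2 = within_sd_log2,
    censor_midpoint_log2 = censor_midpoint_log2,
    censor_steepness = censor_steepness,
    n_crossfluid = as.integer(n_crossfluid), rho = rho,
    score_coeffs = score_coeffs, score_noise_sd = score_noise_sd,
    score_center = score_center,
    plasma_attenuation = plasma_attenuation), class = "cohort_design")
}

#' Apply logistic left-censoring to an abundance matrix
#'
#' Each cell of value v is masked independently with probability
#' `plogis((midpoint - v) * steepness)`: low-abundance cells are lost
#' preferentially, emulating missing-not-at-random non-detection below
#' the instrument's limit. Values are untouched; only the mask changes.
#'
#' @param x An `abundance_matrix` on the log2 scale.
#' @param midpoint Log2 abundance at which the masking probability is 0.5.
#' @param steepness Slope of the logistic; 0 masks every cell with
#'   probability 0.5 regardless of value.
#' @param seed Integer seed.
#' @return The matrix with an augmented missing mask.
#' @export
apply_censoring <- function(x, midpoint, steepness, seed = 1L) {
  stopifnot(inherits(x, "abundance_matrix"))
  if (x$scale_tag != "log2") stop("censoring operates on the log2 scale")
  pmask <- stats::plogis((midpoint - x$values) * steepness)
  pmask[is.na(pmask)] <- 0
  new_mask <- with_seed(seed, {
    matrix(stats::runif(length(pmask)) < pmask, nrow(pmask), ncol(pmask))
  })
  abundance_matrix(x$values, x$protein_ids, x$sample_ids,
                   x$missing_mask | new_mask, "log2")
}

#' Generate a matched two-fluid cohort with known ground truth
#'
#' Simulates log2 abundance matrices for CSF and plasma over the same
#' individuals: protein baselines are drawn once and shared between
#' fluids; planted markers receive their signed log2 effect in cases (CSF)
#' and the attenuated effect in plasma; designated cross-fluid proteins
#' receive a shared latent factor in cases only, calibrated so their
#' CSF-plasma correlation equals `rho` in cases and 0 in controls; the
#' functional score of each case is a linear combination of its three
#' score-protein CSF abundances plus Gaussian noise, rounded and clamped
#' to the 0-48 instrument scale. Both fluids are then left-censored.
#'
#' @param design A [cohort_design()].
#' @param seed Integer seed; all draws derive substreams from it.
#' @return A list with `csf` and `plasma` (`abundance_matrix`, log2 scale,
#'   censored), `meta` (a `sample_table` with group, age, sex, cycle and
#'   case-only `alsfrs`), and `truth` (marker ids with signed effects,
#'   cross-fluid ids, score model, and the pre-censoring matrices).
#' @export
generate_cohort <- function(design = cohort_design(), seed = 1L) {
  stopifnot(inherits(design, "cohort_design"))
  d <- design
  n <- d$n_cases + d$n_controls
  if (n == 0L) stop("empty cohort")
  pid <- sprintf("P%04d", seq_len(d$n_proteins))
  sid <- sprintf("S%03d", seq_len(n))
  is_case <- c(rep(TRUE, d$n_cases), rep(FALSE, d$n_controls))

  base <- with_seed(substream_seed(seed, "baseline"), {
    stats::rnorm(d$n_proteins, d$base_mean_log2, d$base_sd_log2)
  })
  marker_idx <- if (d$n_markers > 0)
    with_seed(substream_seed(seed, "markers"),
              sort(sample.int(d$n_proteins, d$n_markers)))
  else integer()
  non_marker <- setdiff(seq_len(d$n_proteins), marker_idx)
  xf_idx <- if (d$n_crossfluid > 0) {
    pool <- if (length(non_marker) >= d$n_crossfluid) non_marker
            else seq_len(d$n_proteins)
    with_seed(substream_seed(seed, "crossfluid"),
              sort(sample(pool, d$n_crossfluid)))
  } else integer()

  eff_csf <- numeric(d$n_proteins)
  eff_csf[marker_idx] <- d$effect_log2
  eff_pla <- eff_csf * d$plasma_attenuation

  make_fluid <- function(effects, stream) {
    with_seed(substream_seed(seed, stream), {
      eps <- matrix(stats::rnorm(d$n_proteins * n, 0, d$within_sd_log2),
                    d$n_proteins, n)
      base + outer(effects, as.numeric(is_case)) + eps
    })
  }
  csf_v <- make_fluid(eff_csf, "csf")
  pla_v <- make_fluid(eff_pla, "plasma")

  if (length(xf_idx) && d$n_cases > 0 && d$rho != 0) {
    # shared latent factor in cases only; loading a gives cor a^2/(a^2+w^2)
    a <- d$within_sd_log2 * sqrt(abs(d$rho) / (1 - abs(d$rho)))
    z <- with_seed(substream_seed(seed, "latent"), {
      matrix(stats::rnorm(length(xf_idx) * d$n_cases), length(xf_idx))
    })
    ci <- which(is_case)
    csf_v[xf_idx, ci] <- csf_v[xf_idx, ci] + a * z
    pla_v[xf_idx, ci] <- pla_v[xf_idx, ci] + sign(d$rho) * a * z
  }

  alsfrs <- rep(NA_integer_, n)
  score_idx <- integer()
  intercept <- NA_real_
  if (d$n_cases > 0 && d$n_markers >= 3 && any(d$score_coeffs != 0)) {
    score_idx <- marker_idx[1:3]
    mu_case <- base[score_idx] + eff_csf[score_idx]
    intercept <- d$score_center - sum(d$score_coeffs * mu_case)
    noise <- with_seed(substream_seed(seed, "score"),
                       stats::rnorm(d$n_cases, 0, d$score_noise_sd))
    raw <- intercept +
      colSums(d$score_coeffs * csf_v[score_idx, is_case, drop = FALSE]) +
      noise
    alsfrs[is_case] <- as.integer(round(pmin(48, pmax(0, raw))))
  }

  meta <- with_seed(substream_seed(seed, "meta"), {
    data.frame(
      sample_id = sid,
      group = ifelse(is_case, "ALS", "healthy"),
      age = round(stats::rnorm(n, 58, 10)),
      sex = sample(c("F", "M"), n, replace = TRUE),
      cycle = as.integer((seq_len(n) - 1L) %/% 8L + 1L),
      alsfrs = alsfrs,
      stringsAsFactors = FALSE)
  })
  meta <- sample_table(meta)

  pre_csf <- abundance_matrix(csf_v, pid, sid,
                              matrix(FALSE, d$n_proteins, n), "log2")
  pre_pla <- abundance_matrix(pla_v, pid, sid,
                              matrix(FALSE, d$n_proteins, n), "log2")
  csf <- apply_censoring(pre_csf, d$censor_midpoint_log2,
                         d$censor_steepness,
                         substream_seed(seed, "censor_csf"))
  plasma <- apply_censoring(pre_pla, d$censor_midpoint_log2,
                            d$censor_steepness,
                            substream_seed(seed, "censor_plasma"))

  truth <- list(
    marker_ids = pid[marker_idx],
    marker_effects = stats::setNames(eff_csf[marker_idx], pid[marker_idx]),
    crossfluid_ids = pid[xf_idx],
    score_ids = pid[score_idx],
    score_coeffs = if (length(score_idx))
      stats::setNames(d$score_coeffs, pid[score_idx]) else numeric(),
    score_intercept = intercept,
    score_noise_sd = d$score_noise_sd,
    design = d,
    pre_censor = list(csf = pre_csf, plasma = pre_pla))
  list(csf = csf, plasma = plasma, meta = meta, truth = truth)
}

#' Generate a synthetic targeted-peptide report
#'
#' Emulates a stable-isotope-label (SIL) normalized targeted proteomics
#' experiment: for each sample and peptide the light (endogenous) area is
#' log-normal around a group-specific median and the heavy (SIL spike)
#' area is log-normal around a common spike level, so the light/heavy
#' ratio carries the group effect.
#'
#' @param n_per_group Named integer vector of group sizes, e.g.
#'   `c(ALS = 11, disease_control = 15, healthy = 12)`.
#' @param peptide_effects Numeric matrix of median multipliers, peptides
#'   in rows (rownames = peptide ids) and groups in columns (colnames
#'   matching `names(n_per_group)`); 1 means the reference level.
#' @param base_area Median light area at multiplier 1.
#' @param heavy_area Median heavy (spike) area.
#' @param log_sd Log-scale standard deviation of both channels.
#' @param seed Integer seed.
#' @return A list with `report` (a `data.frame` of sample_id, group,
#'   peptide_id, light_area, heavy_area) and `truth` (the design medians).
#' @export
generate_targeted <- function(n_per_group = c(ALS = 11, disease_control = 15,
                                              healthy = 12),
                              peptide_effects = NULL,
                              base_area = 1e6, heavy_area = 5e5,
                              log_sd = 0.3, seed = 1L) {
  if (length(n_per_group) < 2L) stop("need at least 2 groups")
  if (is.null(names(n_per_group)) || any(names(n_per_group) == ""))
    stop("n_per_group must be named by group")
  if (any(n_per_group == 1L))
    warning("group(s) with a single sample: ",
            paste(names(n_per_group)[n_per_group == 1L], collapse = ", "),
            " — downstream tests will refuse them")
  if (is.null(peptide_effects)) {
    peptide_effects <- matrix(
      c(2, 2, 1,
        2, 2, 1,
        1.8, 1.8, 1,
        1.8, 1.8, 1),
      nrow = 4, byrow = TRUE,
      dimnames = list(c("CHI3L1_pep1", "CHI3L1_pep2",
                        "SERPINA3_pep1", "SERPINA3_pep2"),
                      c("ALS", "disease_control", "healthy")))
  }
  miss <- setdiff(names(n_per_group), colnames(peptide_effects))
  if (length(miss)) stop("peptide_effects lacks group column(s): ",
                         paste(miss, collapse = ", "))
  groups <- rep(names(n_per_group), n_per_group)
  sid <- sprintf("T%03d", seq_along(groups))
  peps <- rownames(peptide_effects)
  rows <- with_seed(seed, {
    out <- vector("list", length(peps))
    for (k in seq_along(peps)) {
      med <- base_area * peptide_effects[k, groups]
      light <- stats::rlnorm(length(sid), log(med), log_sd)
      heavy <- stats::rlnorm(length(sid), log(heavy_area), log_sd)
      out[[k]] <- data.frame(sample_id = sid, group = groups,
                             peptide_id = peps[k],
                             light_area = light, heavy_area = heavy,
                             stringsAsFactors = FALSE)
    }
    out
  })
  report <- do.call(rbind, rows)
  rownames(report) <- NULL
  list(report = report,
       truth = list(median_multipliers = peptide_effects,
                    base_area = base_area, heavy_area = heavy_area,
                    log_sd = log_sd))
}
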