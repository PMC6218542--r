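# promark

Biomarker discovery for matched biofluid shotgun proteomics.

`promark` is an R package for the statistical side of a label-free
quantitative (LFQ) proteomics case–control study in which each individual
contributes two matched fluids — cerebrospinal fluid (CSF) and plasma. It
was built around the analysis problems of an ALS biomarker cohort (cases
vs. healthy controls, with ALS functional rating scale scores as the
prognostic outcome), but every stage is generic to two-group biofluid
panels:

- **Preprocessing** — log2 transform; removal of proteins with more than
  25% missing values in *both* groups; left-censored ("downshift")
  imputation, where each missing cell in sample *j* is drawn from
  `N(mean_j − 1.8·sd_j, (0.3·sd_j)²)` over that sample's observed values,
  the Perseus-style model of intensities lost below the detection limit.
- **Differential abundance** — per-protein two-sided pooled-variance
  t-tests with a SAM-style label-permutation false discovery rate
  (default 250 permutations): the expected number of permuted |t|
  statistics exceeding each observed |t|, divided by the observed
  exceedance count, monotonized into a q-value.
- **Cross-fluid correlation** — for a protein measured in both fluids of
  the same individuals, a regression-slope test plus a permutation test
  (default 10,000 permutations of the plasma vector) on the Pearson
  correlation.
- **Panel selection** — filter at q < 0.05, prune correlated proteins
  (|r| > 0.6 keeps the member with the lower average correlation), take
  the top 5 by p-value; or supervised recursive feature elimination under
  repeated (n = 5) 10-fold cross-validation with a 5% AUC simplification
  tolerance.
- **Classifier comparison** — LDA, logistic GLM, SVM (RBF kernel,
  σ = 0.0333, cost tuned over 2⁻²…2¹²), and random forest (m_try tuned
  over 2:5) on identical repeated (n = 50) stratified 5-fold resamples;
  accuracy, sensitivity, specificity, AUC (Mann–Whitney, ties ½), Cohen's
  kappa and the Youden index per resample; paired t-tests between models.
- **Prognostic regression** — exhaustive best-subset OLS of the
  functional score on 1..7 of up to 16 pruned proteins, scored by
  adjusted R², Mallows Cp (`RSS_k/σ̂² − n + 2(k+1)`) and BIC
  (`n·ln(RSS_k/n) + (k+1)·ln n`), with residual diagnostics.
- **Targeted quantification** — stable-isotope-labeled (SIL) peptide
  normalization (light/heavy area ratio) and a permutation test
  (n = 10,000) on group median differences.
- **Enrichment** — upper-tail hypergeometric over-representation against
  an empirical background (proteins detected in ≥ 2 samples), with
  Benjamini–Hochberg correction across pathways.

A synthetic matched-cohort generator (`generate_cohort()`) with planted
differential markers, logistic left-censoring, case-only cross-fluid
correlation, and a linear functional-score model provides ground truth
for every stage, so the whole pipeline is testable without access to the
original cohort.

## Worked example

```r
library(promark)

coh  <- generate_cohort(cohort_design(), seed = 1)   # 33 ALS vs 30 healthy
coh$csf
#> abundance_matrix: 500 proteins x 63 samples (log2 scale), 3059 missing cells (9.7%)

cfg  <- run_config(seed = 1)
prep <- preprocess(coh$csf, coh$meta, cfg = cfg)
prep$report
#> preprocess report: 500 proteins in, 53 removed by missingness, 1455 cells imputed

diff <- permutation_fdr(prep$matrix, coh$meta, n_perm = 250,
                        seed = substream_seed(1, "fdr"))
c(p05 = sum(diff$p < 0.05), q05 = sum(diff$q < 0.05))
#>  p05  q05
#>   44   23

sig    <- diff$protein_id[diff$q < 0.05]
pruned <- prune_correlated(subset_abundance(prep$matrix, proteins = sig), 0.6)
panel  <- select_panel(diff, pruned$retained, k = 5)
panel
#> feature panel (5 of 21 qualifying):
#>   protein_id            p q
#> 1      P0366 5.668994e-12 0
#> ...
length(intersect(panel$panel, coh$truth$marker_ids))
#> [1] 5        # all five panel proteins are planted markers
```

Of the 500 simulated proteins, 44 reach p < 0.05 (25 planted markers plus
the expected ~5% background) and 23 survive the permutation FDR at
q < 0.05; after correlation pruning the five most significant proteins —
all planted markers — form the classification panel. Passing the panel to
`repeated_cv()` and `summarize_resamples()` yields the per-model resample
metrics (on this high-signal synthetic design the median AUC is 1.0 for
every classifier), and `prognostic_regression()` fits the best-subset
score model.

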