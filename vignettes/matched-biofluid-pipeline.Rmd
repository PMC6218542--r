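---
title: "Methods: matched-biofluid biomarker discovery with promark"
author: "promark authors"
output: rmarkdown::html_vignette
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(promark)
```

`promark` implements the statistical pipeline of a matched two-fluid
(CSF/plasma) case–control proteomics study: differential abundance with a
permutation false discovery rate, cross-fluid correlation testing,
correlation-pruned panel selection, resampled classifier comparison,
best-subset prognostic regression, targeted SIL-normalized peptide
comparison, and hypergeometric enrichment. This vignette records the
models, the tunable parameters and why their defaults are what they are,
the design decisions that were genuinely open, and what the synthetic
cohort does and does not establish about real data.

## Data model

An `abundance_matrix` is a proteins × samples grid with an explicit
logical missingness mask and a scale tag (`raw` or `log2`). In label-free
quantification output a reported intensity of 0 means *not quantified*,
not "abundance zero": zeros and blanks are masked at read time, and no
downstream statistic ever consumes a masked cell. All statistics require
the log2 scale.

Missingness in LFQ data is missing-not-at-random (MNAR): the probability
of non-detection rises as abundance falls below the instrument's limit.
Two consequences shape the pipeline: proteins are filtered on a
*per-group* missingness rule, and remaining holes are imputed from a
*downshifted* distribution rather than the observed one.

## Preprocessing

**Missingness filter.** A protein is removed only when its missing
fraction exceeds `filter_max_missing_frac` (default 0.25) in *both*
contrast groups. The asymmetric survival rule is deliberate: a protein
quantified in one group and absent in the other is exactly the kind of
on/off signal a biomarker screen must keep.

**Downshift imputation.** Each missing cell of sample *j* is drawn from

$$N\!\left(\bar{x}_j - 1.8\, s_j,\ (0.3\, s_j)^2\right)$$

with $\bar{x}_j, s_j$ the mean and standard deviation of the sample's
*observed* log2 values. Both factors are expressed in sample standard
deviation units ("width 0.3", "shift 1.8"); an absolute width of 0.3 log2
units would ignore per-sample scale, so the multiplicative reading (the
Perseus convention) is the default and the interpretation is noted here
as switchable in principle. Imputation is column-wise because the
detection limit is a property of a run, not of the experiment; sample
moments are computed after filtering. Observed cells are never altered,
and with a fixed seed the operation is a pure function — both are
asserted by tests.

## Differential abundance

Per protein, a two-sided Student t-test with pooled variance
(`df = n1 + n2 - 2`). Pooled rather than Welch was chosen because the
software lineage this procedure mirrors defaults to pooled; Welch is
exposed via `var_equal = FALSE`. Degenerate inputs are defined, not
accidental: two zero-variance groups with equal means give `t = 0, p = 1`;
with unequal means a `p = 0` sentinel plus warning.

**Permutation FDR.** For `n_perm` (default 250) random relabelings the
full vector of |t| statistics is recomputed. For protein *i*,

- expected false positives: mean over permutations of
  `#{j : |t_j^b| >= |t_i|}` (the SAM-style mean count; a median variant
  is available),
- raw q: that count divided by `#{j : |t_j| >= |t_i|}`,
- final q: the minimum of the raw estimate over all thresholds the
  protein passes (a suffix minimum along decreasing |t|), clipped to
  [0, 1]. This is the standard q-value monotonization; it makes q
  monotone non-decreasing as significance falls, which is asserted on
  every run.

No s₀ fuzz term is added. Relabelings are sampled uniformly with
replacement, excluding the observed labeling; the per-protein permutation
p-value reported alongside q uses the add-one estimator, so finite Monte
Carlo never returns exactly zero and the test stays valid at the nominal
level (verified by the calibration tests).

**Cross-fluid test.** For one protein in two fluids over the same
individuals: the two-sided p-value that the regression slope is non-zero,
plus a permutation p built from Pearson correlations between the original
CSF vector and `n_perm` (default 10,000) permutations of the plasma
vector. The counting rule is one-sided on the signed permuted
correlations (`r_perm > |r_obs|`) and then doubled — implemented verbatim
from the procedure this package reproduces; the symmetric variant
(`|r_perm| > |r_obs|`) is an option, and for null data the two differ
only by Monte Carlo noise. Pairs with a missing value in either fluid are
dropped (observed-only pairing) rather than imputed, since imputation
noise would dilute a correlation estimate. When no permutation exceeds
the observed value the result is reported as `< 2/n_perm` rather than 0.

A subtle numerical point: the observed correlation is computed with the
same centered-sum arithmetic as the permuted ones, so the identity
permutation ties exactly instead of winning or losing by one ulp — at
n = 5 this single tie is visible against exhaustive enumeration.

## Panel selection

Unsupervised route (used for CSF): keep q < 0.05, prune correlated pairs,
take the 5 smallest p. Pruning iterates on the largest offending |r|
(> 0.6) and removes the member with the *larger* mean absolute
correlation against the currently retained set; ties remove the later
protein in input order, making the sweep deterministic. Absolute
correlation is used although the rule is stated for positive r:
anticorrelated duplicates are equally redundant (signed mode available).
The no-retained-pair-above-threshold invariant is asserted on every call.

Supervised route (used for plasma, where few proteins pass the FDR):
recursive feature elimination. Over `rfe_repeats` × `rfe_folds` (5 × 10)
stratified resamples, the model is fit on the training 90% with all
features, features are ranked by model importance (absolute standardized
coefficients for linear models, impurity importance for the forest), and
every candidate size in `rfe_subset_sizes` (1:25, 30, ..., 100) is refit
and scored on the held-out 10% by AUC. The test fold is untouched during
ranking — the no-leakage property the structure tests check. The chosen
size maximizes mean AUC; `simplify_within_tolerance()` returns the
smallest size within 5% of that maximum, trading bounded AUC for a
smaller targeted panel.

## Classifier comparison

Four classifiers — LDA (pooled-covariance, posterior probabilities),
logistic GLM, SVM with RBF kernel `exp(-σ‖u−v‖²)` at fixed σ = 0.0333 and
cost tuned over 2⁻²…2¹², and a random forest with m_try tuned over 2:5 —
are evaluated on an *identical* schedule of repeated (n = 50) stratified
5-fold resamples, so per-resample metrics are paired. Stratification
matters at 33 vs 30: unstratified folds occasionally lose a class
entirely. Centering and scaling are estimated on each training split only
and applied to its test fold; tuning is nested (inner 5-fold resampling
of the training split, best mean accuracy, ties to the smaller grid
value) rather than resolved globally, which avoids the optimistic bias of
tuning on data the outer loop will test on.

Metrics per resample, with cases the positive class: accuracy,
sensitivity, specificity, Cohen's kappa, Youden index
(sens + spec − 1, an identity asserted to machine precision), and AUC as
the Mann–Whitney concordance probability with ties counted ½ — computed
from midranks, and cross-checked against an independent ROC
implementation in the tests. SVM scores are decision values mapped
through the logistic so the 0 boundary coincides with the 0.5 class
threshold; AUC is rank-based, so the monotone map is irrelevant to it.
Test folds containing one class yield an undefined AUC; such rows are
flagged and excluded from AUC aggregation with their count reported.

Models are compared per metric with two-sided paired t-tests over the 250
resample differences (`df = n − 1`); all-zero difference vectors report
`p = 1`. Resample summaries use median and quartiles with linear
interpolation (R type 7), the convention fixed here for reproducibility.

## Prognostic regression

Best-subset OLS of the functional score (ALS-FRS, integer 0–48) on
protein abundances: after q-filtering and correlation pruning, every
combination of 1..7 of up to 16 predictors is fit exhaustively (a guard
refuses more than 20 predictors — prune first). Criteria per size k:

- Mallows `Cp = RSS_k / σ̂² − n + 2(k+1)` with σ̂² from the full model
  (so the full model's Cp equals its parameter count — asserted each
  run),
- `BIC = n·ln(RSS_k/n) + (k+1)·ln n` on the Gaussian profile-likelihood
  scale, constants dropped, matching standard subset-selection software,
- adjusted R².

The default size policy ("elbow-capped") takes the smallest k within 2
BIC units of the minimum, additionally capped at n/10 predictors to guard
against overspecification at small n; a manual choice is reproduced by an
explicit `k`. Residual normality is assessed by Shapiro–Wilk (the
diagnostic density/QQ data are returned for plotting); the test itself is
a fixed choice where only "a density plot" was specified. Both multiple
and adjusted R² are reported — a stated "fraction of variation explained"
is read as multiple R², consistent with an F statistic near 9 at three
predictors and n ≈ 33.

## Targeted quantification

The light/heavy (endogenous/SIL) area ratio cancels preparation and
response variation; rows with non-positive heavy area are rejected by
sample and peptide. Group comparison uses the absolute difference of
group medians against a null of uniform re-assignments of the pooled
values at the original group sizes — chosen over a t-test because
normalized-response distributions deviate from normality. The p estimator
is add-one (never exactly zero; raw-proportion mode retained). The pooled
vector is sorted and the smaller group sampled, which makes the Monte
Carlo draw — not just its distribution — invariant under relabeling of
the groups. The two peptides per protein are tested separately, as
targeted panels report them; pairwise contrasts are used rather than an
omnibus test because the scientific conclusions are pairwise.

## Enrichment

Upper-tail hypergeometric: `p = P[X ≥ k]` for overlap k between hit list
and pathway, both intersected with an *empirical* background — proteins
detected in at least 2 samples of the pre-imputation matrix, not the
whole proteome, because the test must condition on what the instrument
could have seen. Benjamini–Hochberg across pathways. An overlap of 0
spans the whole support, so p = 1 by construction.

## The synthetic cohort: what it emulates, what it does not

`generate_cohort()` draws protein baselines `N(25, 2²)` (log2 LFQ scale),
adds signed log2 effects to planted markers in cases, attenuates those
effects in plasma, left-censors each fluid, injects case-only cross-fluid
correlation through a shared latent factor, and produces a functional
score linearly driven by three markers. Defaults and rationale:

- `n_cases = 33, n_controls = 30`: the cohort geometry of the motivating
  study.
- `n_proteins = 500, n_markers = 25`: a few hundred quantified proteins
  with a marker set the size of the study's q < 0.05 list.
- `effect_log2 = 1` (alternating sign): fold change ~2, the scale of the
  strongest reported CSF markers. This default is also *below the
  redundancy threshold*: a shift *e* with within-protein sd *s* induces
  correlation ≈ (e²/4)/(e²/4 + s²) between any two same-direction markers
  in a balanced cohort (the group difference acts as a shared factor). At
  e = 1, s = 0.5 that is 0.5, under the 0.6 pruning threshold; at e = 2
  it is 0.8, and the pruning rule then removes planted markers *by
  design* — which is why the strong-effect recovery check is phrased on
  q-values, not on panel membership.
- `within_sd_log2 = 0.5`: typical within-group spread of log2 LFQ values.
- `censor_midpoint_log2 = 21.5, censor_steepness = 1`: logistic MNAR
  censoring `P(miss) = logistic((m − v)·k)`, giving ~10% overall
  missingness concentrated in the low tail. A smooth logistic rather than
  a hard threshold because detection near the limit is stochastic.
- `plasma_attenuation = 0.1`: plasma is distal; the study saw 20 vs 118
  nominal discoveries and zero q < 0.05 in plasma, which an attenuation
  of 0.1 reproduces qualitatively.
- `rho = 0.7, n_crossfluid = 2`: two proteins correlated across fluids in
  cases only, injected via a latent factor with loading
  `s·sqrt(ρ/(1−ρ))` so the case correlation equals ρ and the control
  correlation 0.
- score model `coeffs (4, −3, 3), noise sd 3`, centered at 38: implied
  R² = Σβ²s² / (Σβ²s² + σ²) ≈ 0.49, the explained-variation scale of the
  study's three-protein model, on the clamped integer 0–48 instrument
  scale.

What passing tests on this cohort do *not* show: real LFQ data have
correlated proteins (pathway co-regulation), heavier-tailed and
heteroscedastic noise, batch/cycle structure, and markers whose effects
are not exchangeable. The generator's independence between non-marker
proteins makes the FDR calibration cleaner than reality; its Gaussian
within-group noise favors the pooled t; and covariates (age, sex, cycle)
are generated but deliberately not confounded with group, so the
pipeline's lack of covariate adjustment (a stated non-goal) is not
stressed.

## Test problem sizes and numerical choices

The test suite uses deliberately small geometries chosen for statistical
adequacy: exact-enumeration oracles at n₁ = n₂ = 3 (10 distinct splits),
length-5 permutation tests (120 permutations), N ≤ 12 hypergeometric
enumeration; calibration at ≥ 1000 null replicates per procedure with
99% binomial acceptance bands around 0.05; recovery on 500-protein
cohorts at the stated strong-effect conditions. Two calibration points
deserve note. First, a *single* cohort's repeated-CV AUC has
between-cohort sd ≈ 0.075 at n = 60 under the null (its resamples reuse
the same individuals), so the chance-level RFE check averages 10
independent null cohorts. Second, near-saturated logistic models
(p close to n) exhibit the known overfitting reversal — null AUC
systematically *below* 0.5 — so forest-based RFE is used where feature
counts approach sample counts.

The best-subset recovery test uses a high-SNR score design
(`coeffs (5, −4, 4), noise sd 2`): exact-triple recovery requires each
predictor's full-model |t| (≈ β·s·√n/σ) to exceed the expected maximum
(≈ 2.4) of the 13 competing null predictors, which needs |t| ≳ 4.5 —
attainable at that design but not at the realistic default, where best
subset correctly prefers whichever correlated markers happen to fit best.

## Known limitations

- No covariate-adjusted or moderated-variance (empirical Bayes) testing;
  the t-test treats proteins independently.
- Exhaustive best subset is limited to 20 predictors by design; larger
  pools must be pruned or capped (the pipeline caps at the 16 most
  significant).
- The SVM's probability-like scores are monotone transforms of decision
  values; calibrated probabilities would be needed for threshold-moving
  beyond 0.5.
- The permutation FDR's mean-count estimator can exceed 1 before
  clipping and is conservative for small protein counts.
- Quantification itself (peak integration, protein inference, run
  alignment) is upstream and out of scope; the pipeline starts from a
  protein × sample table.
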