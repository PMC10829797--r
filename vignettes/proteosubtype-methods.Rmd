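---
title: "Methods: multiomic subtyping and drug-response modeling with proteosubtype"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multiomic subtyping and drug-response modeling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# Scope

`proteosubtype` implements an end-to-end analysis for proteogenomic cohort
studies in acute myeloid leukemia (AML): TMT proteomics preprocessing and
batch correction, unsupervised multiomic subtype discovery, a proteome-only
subtype classifier, subtype functional enrichment, ex vivo drug-response
stratification, and per-drug AUC prediction. Because the patient data such
studies rest on are access-controlled, the package ships a synthetic-cohort
generator that emulates the statistical structure of the real data; every
stage is developed and tested against it.

# Quantitative preprocessing

**Relative abundance.** TMT reporter intensities are converted per feature to
`log2(sample / reference channel)` and zero-centered across samples
(`relative_abundance()`). Features whose reference intensity is missing or
non-positive are flagged NA rather than silently dropped.

**Filters.** `filter_missingness()` keeps features observed in at least half
the samples; the boundary is inclusive (missing fraction exactly 0.5 is
retained) because "present in at least 50%" reads most naturally as an
inclusive rule. `plex_completeness_filter()` implements both the strict
(observed in every plex) and relaxed (at most m plexes fully missing) rules
used for global and phospho data respectively.

**Median polish.** `median_polish()` wraps Tukey's alternating row/column
median sweep (`stats::medpolish`), returning residuals; the even-count
median is the mean of the middle pair (the standard convention). Because it
is unclear whether published pipelines run the full alternating polish or a
single per-axis centering pass, both are available behind `method =
c("polish", "center")`; the full polish is the default. The polish converges
in total-absolute-residual, so residual row/column medians are near zero but
not exactly zero at finite tolerance — tests assert them below 1e-3 on
standard-normal data.

**KNN imputation.** Missing values are imputed in feature space: the k = 10
nearest features by root-mean-square difference over co-observed samples
donate their mean value at the missing position. Normalizing by the
co-observation count keeps distances comparable between feature pairs that
share different numbers of samples. A feature with no eligible neighbor at a
position falls back to its own row mean. k and the metric are configurable
because the reference implementations of KNN proteomics imputation do not
publish a single canonical setting.

**Empirical-Bayes covariate correction.** `eb_covariate_correction()`
removes loading-mass and plex effects: per feature, an OLS fit on the
standardized continuous and mean-centered one-hot categorical covariates;
coefficients are then shrunk toward their across-feature mean with weight
`tau2 / (tau2 + se2_f)`, where `tau2` is the method-of-moments excess of the
coefficient dispersion over the mean sampling variance. Shrinkage protects
low-information features from overcorrection while leaving well-estimated
coefficients essentially untouched. Because the design columns are centered,
feature means survive the correction exactly. `shrink = 0` gives plain
per-feature residualization (for a single categorical covariate this is
per-level mean centering); `shrink = 1` corrects every feature by the
consensus coefficient. `covariate_effect_scan()` provides the before/after
diagnostic: per-feature association tests with BH adjustment and the
fraction significant at 0.05.

# Subtype discovery by signed-split NMF

Each imputed, corrected modality is z-scored per feature, split into
nonnegative positive/negative parts (`pos = max(x, 0)`, `neg = max(-x, 0)`)
and stacked, doubling the row count (`standardize_and_split()`). Because
z-scoring is per feature, scoring before or after concatenating modalities
is equivalent; it is done per modality.

`nmf_factorize()` minimizes the generalized Kullback-Leibler divergence
with the classic multiplicative updates from uniform random initialization
scaled to the data mean. The update rules guarantee a non-increasing
objective, which the tests assert iteration by iteration. Iteration stops on
a relative objective change below `tol` (checked every 10 iterations) or at
`max_iter`. The inner loop is compiled (RcppArmadillo) because consensus
clustering multiplies single factorizations by runs, ranks and seeds.

`consensus_cluster()` repeats NMF from `n_runs` seeded initializations
(`seed + run - 1`), assigns each sample to the metagene with maximal H
(ties to the lowest index), and averages co-membership indicators into the
consensus matrix A. Final labels cut the average-linkage dendrogram of
`1 - A` at k — consistent with the cophenetic statistic used for model
selection; a representative-run alternative would tie labels to one
arbitrary restart. `cophenetic_correlation()` correlates the off-diagonal
consensus distances with their dendrogram's ultrametric distances;
`select_k()` scans k (default 2–8) and returns the maximizer, ties to the
smaller k.

Consensus runs default to `max_iter = 200`, `tol = 1e-4`: cluster
assignments stabilize one to two hundred iterations before the objective
meets a deep tolerance, and consensus averaging absorbs the residual
run-to-run wobble. A single deep factorization (`nmf_factorize()` defaults:
`max_iter = 2000`, `tol = 1e-6`) is appropriate when W and H themselves are
of interest. Mutation (WES) data are not clustered: binary, sparse mutation
indicators are structurally unlike the dense continuous modalities and are
used downstream for enrichment and stratification instead.

# Proteomic subtype classifier

`fit_multinomial_elasticnet()` fits a symmetric multinomial softmax with the
elastic-net penalty `lambda * ((1 - alpha)/2 ||b||_2^2 + alpha ||b||_1)`
(glmnet, grouped multinomial mode, so a feature enters or leaves all classes
together). Features are standardized with training statistics stored in the
model. Lambda is not specified by the upstream analysis; the default is the
minimizer of mean cross-validated multinomial deviance, recorded in the
model object.

`cross_validate()` runs stratified, repeated 5-fold CV over an alpha grid;
within each repeat a shared lambda path is scored by held-out deviance and
the minimizer evaluated per fold (held-out error, per-class recall and
precision, nonzero-feature count). `select_alpha()` encodes the published
selection logic: find the class hardest to recall on average and pick the
alpha maximizing its recall, breaking ties toward the sparser (larger)
alpha. The number of repeats defaults to 5 and is configurable, since
"repeated" is not quantified upstream.

`predict_proba()` projects any sample set onto the model's feature space;
missing features or values are imputed to the feature mean, i.e. zero after
centering, so they contribute nothing to the linear scores. For external
cohorts (cell lines), `standardize = "self"` standardizes with the new
cohort's own statistics — the transfer procedure described for cell-line
application — while `"training"` (default) is appropriate for samples from
the training platform.

# Enrichment

`subtype_rank_vector()` mean-centers each feature and averages within a
subtype, giving the per-subtype score vector that feeds both tests.
`gsea_preranked()` computes the weighted Kolmogorov-Smirnov enrichment score
(hit steps proportional to `|score|^weight`, miss steps `1/(N - Nh)`) with
significance by gene-set permutation: `n_perm` random same-size sets form
the null, shared across sets of equal size for efficiency; NES divides ES by
the mean |null ES| of the same sign and p-values are BH-adjusted across
sets. Set-size bounds default to [5, 500]. Feature-label permutation was
chosen over sample permutation because the rank vector is a single
per-subtype summary, not a sample-level matrix; the scheme is recorded here
rather than hidden in output.

`ksea()` is the kinase-substrate z-statistic
`z = (mean(substrates) - mean(all sites)) * sqrt(m) / sd(all sites)` with
all quantified sites as the background, two-sided normal p and BH
adjustment.

# Drug-response stratification

`filter_drugs()` applies the screening criteria: at least 100 samples
tested and at least 10 sensitive samples, sensitivity meaning AUC strictly
below 100 on the [1, 300] scale (lower = more sensitive).
`welch_association()` tests each drug's AUC between a group of interest and
the rest (one-vs-rest for multi-level groupings) with Welch's
unequal-variance t-test; positive t means the group of interest is more
resistant. BH adjustment spans the full drug-by-group family of one
analysis — matching a single significance threshold across a heatmap —
rather than per drug. `interaction_analysis()` repeats the mutant-vs-wild-type
contrast within each subtype to localize subtype-restricted mutation
effects, with star annotations per order of magnitude (one star at adjusted
p <= 0.01, two at 0.001, and so on). `fisher_enrichment()` tests subtype
membership against each binary clinical/mutation flag with the two-sided
exact test at raw p < 0.05; samples with co-occurring mutations are not
excluded. `km_logrank()` provides Kaplan-Meier curves and the k-group
log-rank test.

# Per-drug AUC models

`fit_en_regression()` (squared loss + elastic net, alpha default 0.5,
lambda by inner CV) and `fit_gbt_regression()` (gradient-boosted histogram
trees grown leaf-wise: 500 rounds, learning rate 0.05, 31 leaves, early
stopping after 50 stagnant rounds on a 20% validation split) share a
common predict interface with training-mean imputation of missing features.
`repeated_cv_evaluate()` runs 5x5 repeated CV — 25 training instances per
drug — recording held-out Pearson r and RMSE; a fold whose model predicts a
constant is scored r = 0 (no predictive signal) rather than dropped, which
keeps the null distribution of r centered. `final_signature()` refits on
all samples and reports nonzero coefficients or positive importances.
`predict_samples()` retrains on the five fold-complements and predicts new
samples with each, yielding a range (median/min/max) per sample.
`signature_landscape()` embeds samples restricted to a signature in 2-D
(UMAP via uwot when installed, PCA otherwise), seeded and single-threaded
for reproducibility.

# The synthetic cohort generator

`generate_cohort()` draws, per modality, planted per-feature subtype means
(`N(0, subtype_effect_sd^2)`), adds per-feature plex offsets, a per-feature
loading-mass slope times the centered mass, and i.i.d. Gaussian noise.
Missingness is a mixture of missing-completely-at-random deletion and an
intensity-dependent component, logistic in the value's z-score and scaled
by `mnar_strength`, so imputation is exercised on the low-abundance-biased
pattern real reporter data show. Mutations are Bernoulli with per-subtype
rates, drug AUCs are `clamp(baseline + subtype shift + mutation shift +
optional subtype-restricted interaction + noise, 1, 300)` observed on a
per-drug fraction of samples, and survival is exponential with per-subtype
hazard multipliers under independent uniform censoring. Loading mass is
uniform on 30–70 µg and plexes are assigned round-robin; neither
distribution is documented for the real cohort, and nothing downstream is
sensitive to these choices.

Defaults, chosen once as desk-scale study conditions: 160 samples, 4
subtypes, 150/150/100 features (mRNA/protein/phospho), effect and noise sd
1, 8 plexes with offset sd 0.5, loading-mass slope mean 0.05 with sd 0.01,
missing rate 0.05, MNAR strength 0.3. Two points deserve justification:

* The loading-mass slope has a positive *mean*, not just a spread: more
  peptide mass loaded raises measured intensity for essentially all
  features, which is what makes the large majority of features
  mass-associated before correction. A zero-mean slope distribution cannot
  reproduce that regime.
* Feature counts are two orders of magnitude below a real proteome. The
  subtype separation that matters scales with the summed per-feature
  effect, so a few hundred features at effect sd 1 reproduce the clustering
  difficulty regime of thousands of weaker features while keeping the full
  model-selection study (10 cohorts x 7 ranks x 30 NMF restarts)
  runnable on a laptop core in minutes.

What passing tests on this generator do **not** show: robustness to
non-Gaussian heavy-tailed abundance distributions, correlated feature
blocks (co-regulated complexes), plex-by-feature interactions beyond
additive offsets, or informative censoring. Results on real cohorts depend
on those properties; the generator is a correctness and calibration
harness, not a claim of realism.

`generate_resistance_trajectory()` interpolates linearly between two
subtype mean profiles over `n_stages` with small replicate noise, emulating
a homogeneous cell-line series drifting between expression programs during
acquired drug resistance.

# Numerical choices and degenerate inputs

* NMF: `eps = .Machine$double.eps` guards divisions; all-zero H columns
  raise an error at assignment rather than silently labeling.
* Ties: H argmax ties break to the lowest metagene index; cophenetic ties
  in `select_k` break to the smaller k; alpha ties to the larger alpha.
* Zero-variance features are dropped with a warning before z-scoring;
  constant covariates are dropped with a warning; a constant consensus
  matrix yields NA cophenetic correlation.
* Exact tests on degenerate margins return p = 1 or NA rather than erroring
  mid-pipeline; Welch cells with fewer than two observations per group are
  NA.
* glmnet quirks are isolated in the fitting layer: a fixed lambda is always
  embedded in an explicit path (interpolated coefficients are inaccurate,
  badly so for ridge), and single-feature designs are padded with an inert
  zero column.

# Problem sizes used in the shipped checks

The test suite and the acceptance script run the full pipeline at the
default cohort size (n = 160) with 30 NMF restarts per rank over k = 2–8
and consensus `max_iter = 100` for the multi-seed model-order study; unit
tests use a 48-sample mini-cohort. Null-calibration checks use 1000
replicates (Welch, Fisher at n = 2000, KSEA with 1000 kinases, GSEA with
1000 random sets at 500 permutations). These sizes are the package's chosen
desk-scale study conditions.

# Known limitations

* The NMF consensus is the only subtype engine; no joint-view or Bayesian
  variants.
* GSEA significance uses gene-set permutation only; sample-permutation and
  multilevel split schemes are out of scope.
* The drug models treat drugs independently; no multi-task sharing.
* Survival modeling is limited to KM/log-rank; no covariate-adjusted Cox
  models.
* The synthetic generator's independence assumptions (features, samples,
  censoring) are simplifications, as noted above.
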