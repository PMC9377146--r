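---
title: "Models and methods for mucosal-luminal interface microbiome analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for mucosal-luminal interface microbiome analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`cdmli` implements an analysis workflow for paired cecum/sigmoid
mucosal-luminal interface (MLI) microbiome cohorts contrasting Crohn's
disease (CD) in endoscopic remission with non-IBD controls: diversity and
biogeography statistics, negative-binomial (NB) differential abundance, a
CD dysbiosis index, a polygenic genetic risk score (GRS) and its microbiome
associations, a two-stage random-forest classifier, and an untargeted
LC-MS metabolomics stage ending in the cholate:deoxycholate log ratio.
Because the workflow is meant to be exercised without access to any
deposited cohort, it ships a synthetic-cohort generator with known ground
truth; every downstream method is validated against what the generator
plants.

This vignette records the models, the tunable parameters and their
defaults, the numerical choices, and the design decisions that were
genuinely open — in enough detail that a maintainer can re-derive any of
them.

# The synthetic cohort generator

## Count model

For taxon $t$ in sample $s$ (subject $i$, site $k \in$ {cecum, sigmoid}),
the generator draws

$$\log \lambda_{ts} = b_t + x_i^\top \beta_t + u_{it} + \tfrac{\pm 1}{2}
\delta_{it}, \qquad
y_{ts} \sim \mathrm{NB}\!\left(L_s \cdot
\mathrm{softmax}_t(\log \lambda_{\cdot s}),\ \alpha_t\right)$$

* $b_t \sim N(0, 1.5^2)$: baseline log abundances (heavy-tailed
  composition after the softmax).
* $x_i^\top \beta_t$: planted effects, expressed in log2-fold-change units
  and converted by $\ln 2$. Default effect sets: 8 CD-enriched taxa at
  +3, 12 CD-depleted at −3 (depletion broader than enrichment, as in CD
  cohorts), an obesity effect on an overlapping subset at half magnitude
  (applied fully to BMI > 30, at half weight to BMI 25–30, so overweight
  subjects sit between lean and obese), GRS-coupled taxa as a subset of
  the CD-enriched block at 1 log2 unit per GRS unit, 6 consistent
  cecum/sigmoid taxa, and 3 progression-depleted taxa (the first playing
  the dominant *Parasutterella*-like marker). The source study does not
  report per-taxon effect magnitudes, so these are chosen once for
  testability, not realism, and are fully configurable.
* $u_{it} \sim N(0, 0.4^2)$: subject random effects shared by a subject's
  two samples; they control intra-subject cecum–sigmoid similarity.
* $\delta_{it} \sim N(0, \sigma^2_{g(i)})$: per-subject, per-taxon site
  effects applied $+\delta/2$ to the cecum and $-\delta/2$ to the sigmoid.
  The CD group draws with a larger SD (default 0.8 vs 0.25), planting
  CD-specific biogeographic divergence as the simplest mechanism that
  yields a paired-dissimilarity signal; no explicit taxon swaps.
* $L_s \sim \mathrm{LogNormal}(\log 5\times10^4, 0.25)$: library sizes. A
  desk scale — real MLI sequencing depths are an order of magnitude
  larger, but depth beyond ~50k adds nothing to the properties under
  test, and the rarefaction op is exercised regardless.
* $\alpha_t \sim \Gamma(\text{shape}=4, \text{mean}=0.3)$: per-taxon NB
  dispersions, in the range typical of 16S data.

Because effects act on latent log abundances that are renormalized through
a softmax, realized fold changes on relative abundances are attenuated and
*other* taxa move in compensation (compositional coupling). This is
deliberate — the analyzed data are compositional — and has a visible
consequence: when a few taxa are strongly enriched, many unplanted taxa
appear significantly depleted. The same spillover is a recognized feature
of differential-abundance analysis on real relative-abundance data, and
tests therefore assert recovery of the planted sets, not absence of
compensatory calls.

## Genotypes, metabolites, predicted metagenome

Dosages are $\mathrm{Bin}(2, p_i)$ with uniform minor-allele frequencies
on [0.05, 0.5]; weights are per-SNP log odds ratios $N(0, 0.15^2)$ over a
186-variant panel. The CD arm's allele probabilities are tilted along the
weight vector with the tilt solved in closed form so that the expected CD
minus control GRS difference equals `grs_case_offset` (default 0.5, the
order of the published cohort's median gap).

Metabolite log intensities are normal around per-feature means
$N(10, 1.5^2)$ with residual SD 0.6; the first two features act as cholate
and deoxycholate and receive opposite CD shifts of `bile_shift_log2`
(default 1.5) log2 units. Batches add a location shift
($N(0, 0.4^2)$ on the log scale) and a residual-scale factor. Entries are
deleted with probability $\mathrm{logit}^{-1}(3 - 0.6 \log x)$ —
missing-not-at-random against intensity, the standard LC-MS mechanism.
The generator does **not** emulate: correlated metabolite modules, adduct
structure, retention-time drift, or any direct microbe–metabolite coupling
beyond the shared disease label. Consequently residual microbe–metabolite
correlations adjusted for disease are expected to be null on synthetic
data; that stage is validated on constructed monotone examples instead.

The predicted-metagenome stage multiplies taxon relative abundances by a
taxon-to-KO copy-number incidence matrix and renormalizes per sample. The
six bai orthologies (K15868–K15872, K07007) are carried by a subset of the
CD-depleted taxa, so the planted depletion propagates to the bile-acid
7α-dehydroxylation pathway with the correct sign.

## The null configuration

`null_cohort_config()` switches off every planted effect *and* every
latent heterogeneity term (subject effects, site divergence, GRS tilt,
bile shifts), so counts are exactly NB given the library size. This is the
reference condition for type-I calibration: under it, rejection rates
estimate the size of the tests. Leaving log-normal subject/site noise on
in a single-site cross-sectional analysis would instead measure robustness
to a misspecified mixing distribution (NB assumes gamma mixing), which
inflates the NB Wald rejection rate to roughly 0.08 at the default noise
level — a property of the model mismatch, not of the implementation, and
worth knowing but not what a calibration check should assert.

# Statistical conventions

* **Sequential ANOVA.** Covariates enter first, the term of interest
  last; the F-test uses Type-I sums of squares, so term order is part of
  the contract. Reference levels are fixed (nonIBD, female, BMI `lt25`,
  behavior B1, site cecum) so coefficients are comparable across runs.
* **Rank tests.** The Wilcoxon branch uses exact enumeration when the
  combined n is ≤ 20 with no ties, otherwise a tie-corrected normal
  approximation. Dunn post-hoc z tests use midranks with the tie-corrected
  variance, BH-adjusted.
* **Storey q-values.** $\hat\pi_0(\lambda)$ on the grid 0.05–0.95 in
  steps of 0.05, smoothed as the *median over the upper half of the grid*
  ($\lambda \ge 0.5$), capped to (0, 1]; $q = \hat\pi_0 \times$ BH. The
  median-of-tail rule is the simplest stable estimator; with fewer than 50
  p-values the estimate is too noisy and the function falls back to BH
  with a message.
* **PERMANOVA** permutes rows freely (no restricted blocks) with the term
  of interest partitioned last, 9,999 permutations in routine analyses
  (raise to 100,000 for final reporting); $p \ge 1/(n_{perm}+1)$ by
  construction.
* **Alpha diversity** is computed on rarefied counts (bias-corrected
  Chao1, $S_{obs} + F_1(F_1-1)/(2(F_2+1))$; Shannon in natural log —
  the base is a convention, nats chosen and documented). **Beta
  diversity** uses raw counts by default; whether to rarefy first is
  genuinely open in the field, so both are supported and the default is
  documented here rather than hidden.

# Differential abundance

The NB stage follows the median-of-ratios / shrunken-dispersion / Wald
template:

1. **Size factors**: median over reference taxa (those positive in every
   sample) of counts over per-taxon geometric means, rescaled to geometric
   mean 1. When no taxon is all-positive, geometric means use positive
   entries only (logged).
2. **Dispersions**: per-taxon maximum of the Cox–Reid adjusted profile
   likelihood ($\ell(\alpha) - \tfrac12 \log\det X^\top W X$) given means
   fitted under the design; the CR term removes the $O(p/n)$ downward bias
   of plain ML that would otherwise inflate Wald type-I error. A
   parametric trend $\alpha(\mu) = a_0/\mu + a_1$ is then fitted across
   taxa by least squares with one outlier-trimming pass, and the final
   dispersion is the geometric combination
   $\exp((1-w)\log\hat\alpha + w\log\alpha_{trend})$ with $w = 0.5$.
   This is a deliberately simplified empirical-Bayes scheme: the contract
   is calibration and parameter recovery (checked by the acceptance
   tests), not numerical identity with any specific reference tool.
3. **Wald tests**: NB GLM with log size-factor offset at the final
   dispersion; $z$ = coefficient / SE from the expected information;
   q-values over converged taxa; `log2_fold_change` = coefficient / ln 2.
4. **Significance**: $q < 0.05$ (0.1 for GRS analyses) *and* mean
   normalized relative abundance > $10^{-5}$, the abundance filter applied
   after q computation, with the prevalence boundary inclusive (a taxon in
   exactly 25% of samples is kept).

The **dysbiosis index** is the per-sample natural-log ratio of summed
relative abundances of the enriched over the depleted set, with a
pseudocount of $10^{-6}$ on both sums — the raw formula is undefined when
a sample carries none of the depleted taxa, and a shared pseudocount keeps
the index antisymmetric under swapping the sets. Enriched/depleted sets
are derived per site by default (cecal and sigmoid indices are reported
separately); a pooled mode exists for sensitivity analysis.

# Classifier

Feature representation: counts / size factor, renormalized per sample,
then $\log_{10}(x + 10^{-6})$ — the transform is a documented choice, not
an inference. Candidate features are the taxa significant in the matching
covariate-adjusted NB contrast **computed on the training split only**:
deriving them from the whole cohort leaks test information, so the
stricter protocol is the default even though the looser one is common.
Stage 1 fits a random forest (mtry 2, 1001 trees) and computes permutation
importance scaled by its standard error — the mean-decrease-accuracy
z-score, the only importance scale on which a "> 2" cut is meaningful.
Stage 2 refits on the surviving features; if none survive, the refined
stage reuses all features with a warning rather than failing. Test-set
scores are the fraction of trees voting positive; the AUC is the
Mann-Whitney statistic with half-ties; its CI is a stratified percentile
bootstrap (positives and negatives resampled separately, so no resample is
degenerate).

# Metabolomics

Processing order is fixed: prevalence filter (strictly > 10% observed) →
KNN imputation ($k = 10$) → IQR filter → natural-log transform → quantile
normalization → per-batch standardization. KNN neighborhoods are defined
over **features** (Euclidean distance on shared observed samples, rescaled
to the full sample count so different overlaps compare fairly); neighbors
must themselves be observed at the target sample, and a feature-mean
fallback handles the no-neighbor corner. The IQR filter's default
retention rule — keep everything at ≤ 250 features, else drop the
bottom 10% — is explicit and configurable rather than an emulation claim
about any specific tool version. Quantile normalization maps each sample
to the mean sorted profile with average-of-tied-quantiles for ties, and is
idempotent on the log scale. Batch correction is a documented
location/scale standardization per feature (center each batch at the
feature's grand mean, rescale its SD to the pooled within-batch value);
empirical-Bayes batch correction is deliberately out of scope.

Per-feature disease models are ordinary least-squares t-tests with BH —
variance moderation is omitted on purpose, and the null-calibration
acceptance test guards the validity of that simplification. The
cholate:deoxycholate log ratio uses **raw** (pre-normalization)
intensities by default, since it is a within-sample quantity that
normalization can only distort; a processed-scale mode exists.
Microbe–metabolite correlations use NB deviance residuals on the microbe
side, least-squares residuals on the metabolite side, and Spearman
correlation of the residual pairs with BH over the pair grid.

# Problem sizes and determinism

Routine tests and the acceptance study run at desk scale, chosen as the
smallest sizes at which every planted mechanism is comfortably detectable:
60–120 taxa, 20–60 subjects per arm for most recovery studies, 50
subjects per arm for fold-change and biogeography recovery (matching the
recovery criterion's stated n and close to the real cohort's arms), 100 CD
subjects for the GRS coupling study, 200–900 replicates for calibration
studies, 499–9,999 permutations. The analysis scripts run the full
workflow at the real study's arm sizes (88 CD / 110 control, 396 samples).
All randomness flows from a single integer seed per run; the same
configuration and seed reproduce byte-identical outputs.

The biogeography recovery study plants *only* the site-divergence
mechanism (composition effects off, subject effects on): its null twin is
the identical configuration with the divergence SDs equalized, so the
contrast isolates the biogeographic signal. With the full CD composition
effects co-planted the CD arm's composition concentrates on a few enriched
taxa and paired-dissimilarity power drops by roughly ten percentage
points; that interaction is a property of compositional data worth
knowing, but it muddies a recovery check aimed at one mechanism.

# Known limitations

* The generator's independence assumptions (no taxon-taxon interactions,
  no linkage disequilibrium, no metabolite modules) mean passing tests
  demonstrate correctness of the machinery, not performance on real data.
* The NB Wald test is moderately anticonservative under log-normal
  overdispersion (see the null-configuration discussion); on real data the
  q-value stage absorbs some but not all of this.
* Behavior (B1 vs B2/B3) has no planted effect set, so the behavior
  classifier on synthetic data sits near chance by design; it exercises
  the code path, not a biological claim.
* True multivariate-response MANOVA is not attempted; "multivariate"
  models here are univariate-response with multiple covariates, which is
  how the referenced analyses are structured.
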