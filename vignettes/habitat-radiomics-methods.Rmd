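---
title: "Habitat radiomics for occult nodal metastasis: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Habitat radiomics for occult nodal metastasis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(HabitatRadiomics)
```

## The problem

Roughly a third of clinically node-negative (cN0) head-and-neck squamous
cell carcinoma patients harbour occult lymph-node metastases that only
pathology reveals. The package implements an imaging pipeline that predicts
pathological node status (pN+/pN-) from a venous-phase CT tumor
segmentation by modeling three families of regions:

* the **intratumoral** volume (the delineated tumor),
* the **peritumoral** ring (a 1 mm physical outward expansion), and
* **habitat** subregions: voxel-level clusters of locally similar tissue,
  intended to capture the necrotic core, the enhancing vascularised rim and
  the transition zone between them.

Region-level radiomics features feed a selection cascade and three
classifier families; the best model's probability score is evaluated for
discrimination, calibration, clinical net benefit, and prognosis.

## The habitat model

For every in-tumor voxel we compute 18 local features over a cubic window
clipped to the mask: 13 first-order statistics (mean, median, SD, variance,
skewness, excess kurtosis, energy, entropy, uniformity, min, max, range,
robust mean absolute deviation) and 5 statistics of a symmetric,
direction-pooled gray-level co-occurrence matrix at distance one voxel
(contrast, correlation, joint energy, homogeneity, joint entropy). Gray
levels are equal-width quantized over the whole-VOI range; statistics that
are undefined on a constant patch are imputed as 0.

Voxels sampled from all training patients are pooled, z-normalised, and
clustered by K-means (k-means++ seeding, 10 restarts, Lloyd iterations)
for every candidate cluster count `k` in 2..10. The **Davies-Bouldin
index** — the mean over clusters of the worst ratio of summed dispersions
to centroid separation — selects `k` (ties go to the smaller `k`). Clusters
are renamed by ascending mean raw intensity, so habitat 1 is always the
darkest (necrotic-like) region and habitat `k` the brightest
(enhancing-like) one; this makes labels comparable across patients and
runs.

Two design choices were genuinely open:

* **Pooled rather than per-patient clustering.** A single shared model
  makes habitat labels and their region-level features comparable across
  patients, which a per-patient clustering cannot guarantee; a pooled model
  is also what a population-level `k` and population-level region semantics
  presuppose.
* **Intensity-ordered labels.** Cluster numbering from K-means is
  arbitrary; ordering by mean raw intensity is deterministic and maps
  naturally onto the necrosis/transition/enhancement reading of the three
  regions.

Key parameters, all logged in the fitted `HabitatModel`:

| parameter | default | meaning |
|---|---|---|
| `windowMm` | 5 mm | edge length of the local feature window |
| `glcmLevels` | 32 | gray-level bins for entropy/co-occurrence |
| `kRange` | 2..10 | candidate habitat counts |
| `samplePerPatient` | 2000 | voxels pooled per patient for fitting |
| ring `distanceMm` | 1 mm | peritumoral expansion (physical mm) |

## The synthetic cohort

No patient images are distributed, so the package ships a generator whose
defaults define the study conditions for every test:

* **Phantoms** are ellipsoid tumors (10 mm radius, 1 mm isotropic grid)
  painted as three concentric zones occupying 20/30/50% of the volume with
  means 25/60/90 (HU-like) and noise SD 10 — the adjacent-zone separations
  are therefore 3.5x and 3x the noise SD. Each zone's noise has its own
  spatial correlation length (0, 0.75, 1.5 mm): necrotic fluid is
  fine-grained and homogeneous while the enhancing rim shows coarse
  vascular heterogeneity, which is precisely what makes the zones texture
  habitats rather than mere intensity bands. Node-positive phantoms get a
  larger enhancing fraction, tying morphology to outcome.
* **Observer replicates** perturb the mask boundary with a smooth
  band-limited displacement field clamped so the surface never moves more
  than the stated amplitude (defaults: 1 mm inter-observer, 0.5 mm
  intra-observer, giving Dice around 0.9-0.95, a realistic inter-reader
  spread).
* **Clinical covariates** follow the marginals of a predominantly male,
  smoking cN0 cohort with 30% occult-metastasis prevalence; the label is
  drawn from a logistic model on T stage, grade, diameter, radiologic
  features and the enhancing-zone fraction, with the intercept calibrated
  to the target prevalence.
* **Survival** is exponential with hazard ratio 2.5 for pN+ (DFS baseline
  0.015 events/month, OS 0.010) under uniform administrative censoring at
  12-60 months — the simplest model that supports log-rank power checks.

What the generator does *not* emulate: real anatomy, scanner artefacts,
partial-volume effects at the air/bone interfaces, multi-phase contrast
kinetics, or correlated clinical covariates. Passing tests therefore
demonstrate the correctness and statistical calibration of the machinery,
not clinical performance on real CT.

### A known, quantified limitation of the habitat engine

On these phantoms the Davies-Bouldin selection robustly returns `k = 3`,
but voxel-level agreement between habitat labels and painted zones
plateaus around 83%. The disagreement is structural, not a fitting
defect: it concentrates in the one-to-two-voxel bands at the zone
interfaces, where the local window genuinely mixes two tissues. Three
observations pin this down. First, K-means seeded at the true zone
centroids converges to the *same* optimum as free multi-restart K-means,
so the variance-minimising partition itself disagrees with the painted
partition in the mixing bands. Second, assigning each voxel to its
nearest true-zone centroid (an oracle unavailable in practice) still caps
agreement at 0.85-0.91 for every geometry we examined (radii 10-40
voxels, windows 3-7 mm). Third, the cap is not noise-bound: at twice the
separation-to-noise ratio agreement barely moves, and with near-zero
noise the mixing bands crystallise into their own clusters and
Davies-Bouldin prefers a finer partition. In short, window-based voxel
features impose an interface-resolution limit on any hard clustering;
interior voxels are labelled essentially perfectly.

## The feature cascade

Region-level features (shape, 18 first-order statistics, co-occurrence,
run-length and size-zone families; fixed-bin-width quantization, default
width 25) pass through five stages, each operating on the survivors of the
previous one:

1. **Reproducibility**: two-way random-effects absolute-agreement
   single-rater ICC(2,1) against a second observer's and a repeat
   segmentation; keep features with both ICCs > 0.75. The absolute-
   agreement variant is the conservative standard for radiomics
   test-retest work. Habitat features bypass this stage (flagged, not
   filtered): subregions are re-derived per segmentation, so repeat-mask
   ICC does not measure their reproducibility.
2. **Z-score normalisation** fitted on the training set only; test tables
   always reuse training parameters.
3. **Relevance**: two-sided Mann-Whitney U per feature at raw p < 0.05
   (exact null distribution for tiny groups, tie-corrected normal
   approximation otherwise). No multiplicity correction is applied at this
   stage by design — the stage is a coarse pre-filter ahead of LASSO, and
   an optional Benjamini-Hochberg switch exists for users who want one.
4. **Redundancy**: pairwise Spearman correlation; scanning features in
   order of ascending U-test p (ties by name), a feature is kept only if
   |rho| <= 0.9 against everything already kept — of any correlated pair
   the more class-associated member survives, deterministically.
5. **LASSO**: L1-penalised logistic regression with the penalty chosen by
   stratified 5-fold cross-validated deviance at its minimum
   (`lambda.min`); the one-standard-error rule is available but the
   minimum-deviance rule matches the relatively generous selected-feature
   counts this kind of pipeline reports.

Because rank-based stages are invariant to monotone transforms, the
placement of z-scoring before the U test has no effect on stages 3-4; it
matters only for LASSO, which here always sees standardised inputs.

## Classifiers and evaluation

Three families are trained per region: unpenalised logistic regression, an
RBF support vector machine with Platt-scaled probabilities and a small
inner grid search over cost and kernel width, and a 500-tree random forest
(sqrt-p features per split) whose score is the class-vote fraction. All
use the same stratified 5-fold assignment derived from the seed, so fold
prevalence is within one patient of the cohort's.

Evaluation follows standard practice, with every statistic matched against
an independent brute-force oracle in the test suite:

* AUC via the Mann-Whitney statistic (ties count one half), DeLong
  structural-component variance, Wald CIs (z = 1.96, clipped to [0, 1]),
  and the paired DeLong test for correlated AUCs.
* Operating cutoffs by the maximum Youden index over observed scores, with
  classification inclusive at the cutoff (`score >= cutoff`) — the
  convention is fixed and documented because confusion counts depend on it.
* Equal-frequency calibration curves with a logistic recalibration slope
  and intercept; decision curves with net benefit
  `TP/n - FP/n * pt/(1 - pt)` against treat-all and treat-none.
* Kaplan-Meier curves (events precede censoring at ties), 3-year rates as
  the step function at 36 months, and the 1-df log-rank test.
* Baseline tables: cross-product odds ratios with Wald CIs using
  z = 1.96 exactly — this choice, not 1.959964, reproduces published
  3-decimal CIs — Pearson chi-square without continuity correction,
  Fisher's exact test whenever an expected cell drops below 5, Welch t or
  Mann-Whitney for continuous variables after a Shapiro-Wilk screen.

## Numerical conventions and degenerate inputs

* All physical distances are millimetres; voxel (0,0,0) sits at the
  volume origin and physical position = origin + index x spacing.
* The peritumoral ring uses exact Euclidean distances in physical mm
  (computed by a capped distance transform), so anisotropic voxels are
  handled correctly; ring voxels beyond the volume border are clipped with
  a warning.
* Zero-variance features are dropped with a warning at the z-scoring
  stage; constant-patch statistics are imputed as 0; regions smaller than
  `minVoxels` (default 10) yield flagged all-missing vectors imputed by
  cohort medians during table assembly.
* Ties: Davies-Bouldin ties resolve to the smaller k; Youden ties to the
  lowest cutoff; Spearman-pruning ties on p to alphabetical order.
  K-means uses k-means++ seeding with 10 restarts under a derived seed,
  so fits are reproducible to the bit.
* Degenerate designs: perfect separation in logistic screening is flagged
  (`unstable`) rather than hidden; collinear multivariable designs fall
  back to a lightly ridge-penalised fit with a warning; a DeLong
  comparison with zero variance difference returns p = 1.

## Problem sizes used by the automated checks

The test suite and the acceptance script work at sizes chosen to exercise
every code path at desk scale: 20 phantoms of 36^3 voxels (about 4200
tumor voxels each) for the habitat engine, cohorts of 150-400 synthetic
patients for calibration checks, and 20-seed replications for the
selection-recovery and held-out-AUC experiments (n = 300 per cohort, 3
informative among 50 features, generator Bayes AUC 0.90). These sizes keep
the full suite under a minute while leaving Monte-Carlo error well inside
the asserted margins.
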