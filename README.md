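# HabitatRadiomics

Occult lymph-node metastasis — nodal disease that pathology finds in
patients who looked node-negative (cN0) on imaging — drives prognosis in
head-and-neck squamous cell carcinoma and forces an uncomfortable choice
between prophylactic neck dissection and watchful waiting.
**HabitatRadiomics** implements a habitat-radiomics pipeline that predicts
pathological node status (pN+/pN−) from a venous-phase CT tumor
segmentation, for imaging scientists who want a fully testable, end-to-end
reference implementation.

The pipeline models three region families per patient:

- **intratumoral**: the delineated tumor volume;
- **peritumoral**: the ring of tissue obtained by expanding the mask
  outward by 1 mm of *physical* distance (exact Euclidean, anisotropy-aware);
- **habitat**: tumor subregions found by clustering voxel-level feature
  vectors. For every in-tumor voxel, 18 local features (13 first-order +
  5 gray-level co-occurrence statistics over a 5 mm window) are computed;
  voxels pooled across training patients are z-normalised and clustered by
  K-means for k = 2…10, and the **Davies–Bouldin index**

  DB = (1/k) Σᵢ maxⱼ≠ᵢ (Sᵢ + Sⱼ) / d(cᵢ, cⱼ)

  selects the cluster number (lower is better). Clusters are renamed by
  ascending mean intensity, so habitat 1 is the necrotic-like core and
  habitat k the enhancing rim.

Region-level radiomics features (shape, first-order, GLCM, GLRLM, GLSZM)
then pass a selection cascade — ICC(2,1) > 0.75 reproducibility filter →
z-score → Mann–Whitney U (p < 0.05) → Spearman redundancy pruning
(|ρ| > 0.9) → LASSO at the cross-validated deviance minimum — and feed
logistic-regression, SVM and random-forest classifiers. Evaluation covers
ROC/AUC with DeLong variance and paired DeLong model comparison, Youden
cutoffs, confusion-matrix metrics, calibration and decision curves,
Kaplan–Meier 3-year survival with the log-rank test, and baseline
contingency statistics (cross-product odds ratios with z = 1.96 Wald CIs,
chi-square/Fisher, Welch-t/Mann–Whitney).

Because the underlying patient images are not public, the package ships a
first-class synthetic-cohort module: three-zone ellipsoid tumor phantoms
(necrotic core / transition shell / enhancing rim, each with its own
intensity and noise texture), duplicate observer masks for ICC work, a
clinical covariate table with realistic cN0 marginals, a calibrated
logistic outcome model, and exponential survival tied to node status.

## Worked example

```r
library(HabitatRadiomics)

## synthetic imaging cohort and habitat model ------------------------------
coh  <- generateCohort(cohortSpec(nPatients = 12, seed = 7), images = TRUE)
maps <- lapply(coh$patients, function(p)
    voxelFeatureMap(p$image, p$mask, windowMm = 5))
model <- fitHabitatModel(maps, kRange = 2:6, samplePerPatient = 1000, seed = 7)
model
#> HabitatModel: k = 3 habitats (Davies-Bouldin over k = 2..6)
#>   18 voxel features, seed 7
model@kSearch          # Davies-Bouldin score per candidate k (3 wins)
#>   k        db
#> 1 2 1.1773076
#> 2 3 0.9253953
#> 3 4 1.0702444
#> ...

## published baseline counts round-trip ------------------------------------
sm <- subset(hnsccBaselineCounts(), variable == "smoking")
oddsRatio(sm$pn_pos[1], sm$pn_neg[1], sm$pn_pos[2], sm$pn_neg[2])
#> $or 0.7765487   $ci 0.3247816 1.8567177   $p 0.569609
prevalencePct(86, 330)
#> [1] 26.06

## selection cascade and classifier on a simulated feature cohort ----------
sim <- simulateFeatureTable(n = 300, nInformative = 3, nNoise = 47, seed = 7)
rep <- selectFeatures(sim$table, sim$labels, seed = 7)
rep
#> Feature-selection cascade:
#>   input    50 features
#>   zscore   50 features
#>   mwu      5 features
#>   spearman 5 features
#>   lasso    5 features
fit <- trainClassifier("rf", zscoreApply(rep$transform, sim$table)[rep$selected],
                       sim$labels, seed = 7)
#> RF classifier on 5 features; CV AUC 0.877 (SD 0.038)

## held-out evaluation ------------------------------------------------------
held <- simulateFeatureTable(n = 300, nInformative = 3, nNoise = 47, seed = 1007)
sc <- radiomicsScore(fit, zscoreApply(rep$transform, held$table)[rep$selected])
rocAuc(sc, held$labels)
#> AUC 0.869 (95% CI 0.829-0.910), 155+/145-
yc <- youdenCutoff(sc, held$labels)       # cutoff 0.748 (J = 0.58)
thresholdMetrics(sc, held$labels, yc$cutoff)
#> accuracy 0.787 sensitivity 0.677 specificity 0.903
```

The AUC of ~0.87 sits where it should: the feature generator's
Bayes-optimal AUC is 0.90, the cascade recovers the three informative
features, and the random forest gives most of the attainable
discrimination back. The Davies–Bouldin minimum at k = 3 recovers the
three painted tissue zones of the phantoms.

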