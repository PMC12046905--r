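test_that("noise-free phantoms paint the zone means exactly", {
    spec <- tinyPhantomSpec(zoneSds = c(0, 0, 0), smoothingSigmaMm = 0,
                            backgroundSd = 0)
    p <- generatePhantom(spec, seed = 1)
    img <- voxelData(p$image); z <- voxelData(p$zones)
    for (k in 1:3)
        expect_true(all(img[z == k] == spec$zoneMeans[k]))
    expect_true(all(img[z == 0] == spec$backgroundMean))
    # all three zones exist and partition the mask
    expect_identical(z > 0, voxelData(p$mask) > 0)
    expect_setequal(unique(z[z > 0]), 1:3)
})

test_that("phantom generation is bit-identical under one seed", {
    spec <- tinyPhantomSpec()
    p1 <- generatePhantom(spec, seed = 42)
    p2 <- generatePhantom(spec, seed = 42)
    expect_identical(voxelData(p1$image), voxelData(p2$image))
    expect_identical(voxelData(p1$mask), voxelData(p2$mask))
    p3 <- generatePhantom(spec, seed = 43)
    expect_false(identical(voxelData(p1$image), voxelData(p3$image)))
})

test_that("per-zone intensities match their sampling distribution", {
    spec <- phantomSpec(gridShape = c(36, 36, 36), tumorRadiusMm = c(12, 12, 12),
                        zoneMeans = c(25, 60, 90), zoneSds = c(5, 8, 10),
                        textureGrainMm = c(0, 0, 0), smoothingSigmaMm = 0)
    p <- generatePhantom(spec, seed = 7)
    img <- voxelData(p$image); z <- voxelData(p$zones)
    for (k in 1:3) {
        n <- sum(z == k)
        expect_gt(n, 1000)
        se <- spec$zoneSds[k] / sqrt(n)
        expect_lt(abs(mean(img[z == k]) - spec$zoneMeans[k]), 3 * se)
    }
})

test_that("node-positive phantoms carry a larger enhancing fraction", {
    spec <- tinyPhantomSpec()
    p0 <- generatePhantom(spec, pnLabel = 0, seed = 1)
    p1 <- generatePhantom(spec, pnLabel = 1, seed = 1)
    frac <- function(p) mean(voxelData(p$zones)[voxelData(p$mask) > 0] == 3)
    expect_gt(frac(p1), frac(p0))
})

test_that("oversized tumors are rejected with a sizing error", {
    expect_error(phantomSpec(gridShape = c(16, 16, 16),
                             tumorRadiusMm = c(10, 10, 10)), "fit")
    expect_error(phantomSpec(zoneFractions = c(0.5, 0.6, 0.2)), "sum")
    expect_error(phantomSpec(spacingMm = c(1, 0, 1)), "positive")
})

test_that("mask perturbation is identity at zero and respects the distance bound", {
    mask <- generatePhantom(tinyPhantomSpec(), seed = 3)$mask
    expect_identical(perturbMask(mask, 0), mask)
    mag <- 1.5
    pert <- perturbMask(mask, mag, seed = 5)
    orig <- voxelData(mask) > 0
    new <- voxelData(pert) > 0
    # distance-transform oracle: brute-force physical distances
    idxO <- which(orig, arr.ind = TRUE)
    idxB <- which(!orig, arr.ind = TRUE)
    added <- which(new & !orig, arr.ind = TRUE)
    removed <- which(orig & !new, arr.ind = TRUE)
    minDist <- function(pts, ref) {
        vapply(seq_len(nrow(pts)), function(i)
            sqrt(min(colSums((t(ref) - pts[i, ])^2))), 0)
    }
    if (nrow(added) > 0)
        expect_lte(max(minDist(added, idxO)), mag + 1e-9)
    if (nrow(removed) > 0)
        expect_lte(max(minDist(removed, idxB)), mag + 1e-9)
    expect_gt(sum(new), 0)
})

test_that("expected Dice decreases as the perturbation magnitude grows", {
    mask <- generatePhantom(tinyPhantomSpec(), seed = 2)$mask
    orig <- voxelData(mask) > 0
    dice <- function(m) {
        new <- voxelData(m) > 0
        2 * sum(orig & new) / (sum(orig) + sum(new))
    }
    d05 <- vapply(1:20, function(s) dice(perturbMask(mask, 0.5, seed = s)), 0)
    d20 <- vapply(1:20, function(s) dice(perturbMask(mask, 2.0, seed = s)), 0)
    expect_gt(mean(d05), mean(d20))
    expect_gt(mean(d05), 0.9)  # realistic inter-observer overlap at 0.5 mm
})

test_that("cohort prevalence stays within its binomial interval", {
    coh <- generateCohort(cohortSpec(nPatients = 400, prevalence = 0.30,
                                     seed = 9), images = FALSE)
    phat <- mean(coh$clinical$pn)
    half <- qnorm(0.995) * sqrt(0.3 * 0.7 / 400)
    expect_lt(abs(phat - 0.30), half)
    # deterministic under seed
    coh2 <- generateCohort(cohortSpec(nPatients = 400, prevalence = 0.30,
                                      seed = 9), images = FALSE)
    expect_identical(coh$clinical, coh2$clinical)
    expect_error(cohortSpec(nPatients = 1), "at least 2")
    expect_error(cohortSpec(prevalence = 1.2), "strictly")
})

test_that("null effect sizes leave covariates independent of the label", {
    ps <- vapply(1:50, function(s) {
        spec <- cohortSpec(nPatients = 150, seed = s,
                           effectSizes = c(tStage = 0, gradePoor = 0,
                                           diameterCm = 0,
                                           enhancingFraction = 0,
                                           necrosis = 0, heterogeneous = 0))
        cl <- generateCohort(spec, images = FALSE)$clinical
        suppressWarnings(chisq.test(table(cl$tStage, cl$pn))$p.value)
    }, 0)
    expect_lt(mean(ps < 0.05), 0.16)   # near-nominal false-positive rate
    expect_gt(mean(ps), 0.35)          # p-values roughly uniform
    expect_lt(mean(ps), 0.65)
})

test_that("unit hazard ratio gives exchangeable survival between label groups", {
    rejected <- vapply(1:20, function(s) {
        spec <- cohortSpec(nPatients = 200, seed = s,
                           survivalModel = list(baselineHazardDfs = 0.02,
                                                baselineHazardOs = 0.012,
                                                hazardRatio = 1,
                                                censorMinMonths = 1000,
                                                censorMaxMonths = 1001))
        cl <- generateCohort(spec, images = FALSE)$clinical
        expect_true(all(cl$dfsEvent == 1))  # no effective censoring
        logrankTest(cl$dfsMonths, cl$dfsEvent, cl$pn)$p < 0.05
    }, FALSE)
    expect_lte(mean(rejected), 0.25)
})

test_that("a written cohort round-trips through NIfTI and CSV", {
    spec <- cohortSpec(nPatients = 2, seed = 4)
    coh <- generateCohort(spec, phantom = phantomSpec(
        gridShape = c(24, 24, 24), tumorRadiusMm = c(6, 6, 6)))
    d <- file.path(tempdir(), "cohort-test")
    writeCohort(coh, d)
    cl <- read.csv(file.path(d, "clinical.csv"))
    expect_equal(nrow(cl), 2)
    expect_equal(cl$pn, coh$clinical$pn)
    img <- readVolume(file.path(d, paste0(cl$id[1], "_image.nii.gz")))
    expect_equal(voxelData(img), voxelData(coh$patients[[1]]$image),
                 tolerance = 1e-6)
    m2 <- readVolume(file.path(d, paste0(cl$id[1], "_mask_observer2.nii.gz")),
                     mask = TRUE)
    expect_identical(voxelData(m2),
                     voxelData(coh$patients[[1]]$maskObserver2))
    unlink(d, recursive = TRUE)
})

test_that("simulated feature tables realise the requested Bayes AUC", {
    sim <- simulateFeatureTable(n = 5000, nInformative = 3, nNoise = 2,
                                bayesAuc = 0.90, seed = 17)
    bayesScore <- rowSums(sim$table[, 1:3])
    expect_lt(abs(rocAuc(bayesScore, sim$labels)$auc - 0.90), 0.02)
})
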