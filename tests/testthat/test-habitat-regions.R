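test_that("peritumoral ring reproduces forced geometry", {
    m <- array(0L, c(7, 7, 7)); m[4, 4, 4] <- 1L
    ring <- peritumoralRing(maskVolume(m), 1)
    idx <- which(voxelData(ring) > 0, arr.ind = TRUE)
    expect_equal(nrow(idx), 6)   # face neighbours only; diagonals at sqrt(2)
    expect_true(all(rowSums(abs(sweep(idx, 2, c(4, 4, 4)))) == 1))
    # anisotropic spacing: a 3 mm axis is out of reach at 1 mm
    ringA <- peritumoralRing(maskVolume(m, spacing = c(1, 1, 3)), 1)
    idxA <- which(voxelData(ringA) > 0, arr.ind = TRUE)
    expect_true(all(idxA[, 3] == 4))
    expect_equal(nrow(idxA), 4)
    expect_error(peritumoralRing(maskVolume(array(0L, c(4, 4, 4))), 1),
                 "empty")
})

test_that("ring equals brute-force distance-transform thresholding on a blob", {
    set.seed(23)
    m <- array(0L, c(14, 14, 14))
    pts <- cbind(sample(5:10, 12, TRUE), sample(5:10, 12, TRUE),
                 sample(5:10, 12, TRUE))
    m[pts] <- 1L
    sp <- c(1, 1.5, 2)
    mask <- maskVolume(m, spacing = sp)
    ring <- peritumoralRing(mask, 2)
    fgIdx <- which(m > 0, arr.ind = TRUE)
    phys <- sweep(fgIdx, 2, sp, `*`)
    bruteRing <- array(FALSE, dim(m))
    for (i in which(m == 0)) {
        co <- arrayInd(i, dim(m))
        d <- sqrt(min(colSums((t(phys) - as.numeric(co * sp))^2)))
        bruteRing[i] <- d <= 2
    }
    expect_identical(voxelData(ring) > 0, bruteRing)
    # disjoint from the mask by construction
    expect_true(!any(voxelData(ring) > 0 & m > 0))
})

test_that("ring warns when clipped at the volume border", {
    m <- array(0L, c(5, 5, 5)); m[1, 3, 3] <- 1L
    expect_warning(peritumoralRing(maskVolume(m), 1), "clipped")
})

test_that("voxel features honour constant fields and symmetric windows", {
    img <- imageVolume(array(13, c(8, 8, 8)))
    mask <- maskVolume(array(1L, c(8, 8, 8)))
    vm <- voxelFeatureMap(img, mask, windowMm = 3)
    zeroFeats <- c("sd", "variance", "skewness", "kurtosis", "range",
                   "glcm_contrast", "glcm_joint_entropy")
    for (f in zeroFeats)
        expect_true(all(vm$features[, f] == 0), info = f)
    expect_true(all(vm$features[, "mean"] == 13))
    expect_true(all(vm$features[, "uniformity"] == 1))
    # linear ramp: symmetric window preserves the centre value in the mean
    ramp <- imageVolume(array(rep(1:8, 64), c(8, 8, 8)))
    vr <- voxelFeatureMap(ramp, mask, windowMm = 3)
    interior <- vr$coords[, 1] > 1 & vr$coords[, 1] < 8
    expect_equal(vr$features[interior, "mean"],
                 voxelData(ramp)[vr$coords[interior, , drop = FALSE]],
                 tolerance = 1e-12)
})

test_that("all 18 voxel features match the brute-force oracle on a toy patch", {
    set.seed(33)
    img <- imageVolume(array(rnorm(5^3, 50, 12), c(5, 5, 5)))
    m <- array(1L, c(5, 5, 5)); m[1, 1, 1] <- 0L  # irregular mask edge
    mask <- maskVolume(m)
    vm <- voxelFeatureMap(img, mask, windowMm = 3, glcmLevels = 8)
    oracle <- bruteVoxelFeatures(img, mask, half = c(1, 1, 1), nlevels = 8)
    expect_equal(unname(vm$features), unname(oracle), tolerance = 1e-10)
})

test_that("Davies-Bouldin matches its formula oracle and behaves monotonically", {
    expect_equal(daviesBouldin(rbind(c(0, 0), c(0, 0), c(3, 0), c(3, 0)),
                               c(1, 1, 2, 2)), 0)
    # brute-force oracle written independently of the implementation
    dbOracle <- function(P, lab) {
        labs <- sort(unique(lab))
        cen <- lapply(labs, function(l) colMeans(P[lab == l, , drop = FALSE]))
        S <- vapply(seq_along(labs), function(i)
            mean(sqrt(rowSums(sweep(P[lab == labs[i], , drop = FALSE], 2,
                                    cen[[i]])^2))), 0)
        mean(vapply(seq_along(labs), function(i)
            max(vapply(setdiff(seq_along(labs), i), function(j)
                (S[i] + S[j]) / sqrt(sum((cen[[i]] - cen[[j]])^2)), 0)), 0))
    }
    set.seed(41)
    P <- matrix(rnorm(100), 50, 2)
    lab <- sample(1:3, 50, TRUE)
    expect_equal(daviesBouldin(P, lab), dbOracle(P, lab), tolerance = 1e-10)
    # moving two centroids closer (dispersion fixed) raises the score
    mk <- function(d) rbind(matrix(rnorm(60, 0, 0.3), 30),
                            sweep(matrix(rnorm(60, 0, 0.3), 30), 2, c(d, 0),
                                  `+`))
    set.seed(2)
    far <- mk(6); set.seed(2); near <- mk(2)
    lab2 <- rep(1:2, each = 30)
    expect_gt(daviesBouldin(near, lab2), daviesBouldin(far, lab2))
    expect_error(daviesBouldin(P, rep(1, 50)), "2 clusters")
})

test_that("habitat model selection is forced by a singleton k range", {
    phantoms <- lapply(1:2, function(i)
        generatePhantom(tinyPhantomSpec(), seed = i))
    maps <- lapply(phantoms, function(p)
        voxelFeatureMap(p$image, p$mask, windowMm = 5))
    model <- fitHabitatModel(maps, kRange = 2, samplePerPatient = 400,
                             seed = 1)
    expect_equal(model@k, 2L)
    expect_error(fitHabitatModel(maps[1], kRange = 2:3), "2 patients")
    expect_error(fitHabitatModel(maps, kRange = 1:3), "within")
})

test_that("habitat fitting recovers the three painted zones with ordered labels", {
    phantoms <- lapply(1:4, function(i)
        generatePhantom(phantomSpec(), pnLabel = i %% 2, seed = i))
    maps <- lapply(phantoms, function(p)
        voxelFeatureMap(p$image, p$mask, windowMm = 5))
    model <- fitHabitatModel(maps, kRange = 2:6, samplePerPatient = 1000,
                             seed = 3)
    expect_equal(model@k, 3L)
    expect_equal(model@kSearch$k[which.min(model@kSearch$db)], 3)
    agree <- vapply(seq_along(phantoms), function(i) {
        hab <- assignHabitats(model, maps[[i]], phantoms[[i]]$mask)
        fg <- voxelData(phantoms[[i]]$mask) > 0
        mean(voxelData(hab)[fg] == voxelData(phantoms[[i]]$zones)[fg])
    }, 0)
    expect_gt(mean(agree), 0.75)  # gross three-zone structure recovered
    # necrotic-core voxels carry the lowest-intensity habitat label
    hab <- assignHabitats(model, maps[[1]], phantoms[[1]]$mask)
    core <- voxelData(phantoms[[1]]$zones) == 1
    expect_gt(mean(voxelData(hab)[core] == 1), 0.5)
    # habitat 1 has the lowest mean raw intensity
    fg <- voxelData(phantoms[[1]]$mask) > 0
    ints <- tapply(voxelData(phantoms[[1]]$image)[fg], voxelData(hab)[fg],
                   mean)
    expect_equal(order(ints), seq_len(model@k))
    # determinism of fit and assignment
    model2 <- fitHabitatModel(maps, kRange = 2:6, samplePerPatient = 1000,
                              seed = 3)
    expect_equal(model@centroids, model2@centroids, tolerance = 1e-12)
    hab2 <- assignHabitats(model2, maps[[1]], phantoms[[1]]$mask)
    expect_identical(voxelData(hab), voxelData(hab2))
})

test_that("habitat assignment is invariant to per-feature affine rescaling", {
    phantoms <- lapply(1:2, function(i)
        generatePhantom(tinyPhantomSpec(), seed = i))
    maps <- lapply(phantoms, function(p)
        voxelFeatureMap(p$image, p$mask, windowMm = 5))
    model <- fitHabitatModel(maps, kRange = 3, samplePerPatient = 500,
                             seed = 2)
    a <- runif(18, 0.5, 3); b <- rnorm(18)
    mapsT <- lapply(maps, function(m) {
        m$features <- sweep(sweep(m$features, 2, a, `*`), 2, b, `+`)
        m
    })
    modelT <- fitHabitatModel(mapsT, kRange = 3, samplePerPatient = 500,
                              seed = 2)
    h1 <- assignHabitats(model, maps[[1]], phantoms[[1]]$mask)
    h2 <- assignHabitats(modelT, mapsT[[1]], phantoms[[1]]$mask)
    expect_identical(voxelData(h1), voxelData(h2))
    # voxel exactly at a centroid maps to that habitat
    mapC <- maps[[1]]
    zc <- model@centroids[2, ] * model@scale + model@center
    mapC$features[1, ] <- zc
    hC <- assignHabitats(model, mapC, phantoms[[1]]$mask)
    expect_equal(voxelData(hC)[mapC$coords[1, , drop = FALSE]], 2)
})

test_that("a built VoiSet satisfies disjointness and exact partition", {
    phantoms <- lapply(1:2, function(i)
        generatePhantom(tinyPhantomSpec(), seed = i))
    maps <- lapply(phantoms, function(p)
        voxelFeatureMap(p$image, p$mask, windowMm = 5))
    model <- fitHabitatModel(maps, kRange = 2:4, samplePerPatient = 500,
                             seed = 1)
    voi <- buildVoiSet(phantoms[[1]]$image, phantoms[[1]]$mask, model)
    it <- voxelData(voi@intratumoral) > 0
    pt <- voxelData(voi@peritumoral) > 0
    hb <- voxelData(voi@habitat)
    expect_false(any(it & pt))
    expect_identical(hb > 0, it)
    expect_true(all(hb[it] %in% seq_len(model@k)))
    expect_output(show(voi), "VoiSet")
})
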