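test_that("shape features follow their definitions on forced geometry", {
    # 10 voxels at 1 mm isotropic: volume 10 mm^3
    m <- array(0L, c(8, 8, 8)); m[2:6, 4, 4] <- 1L; m[2:6, 5, 4] <- 1L
    fv <- extractFeatures(imageVolume(array(5, c(8, 8, 8))), maskVolume(m))
    expect_equal(unname(fv["shape_volume_mm3"]), 10)
    # 3x3x3 cube: 54 exposed faces, max diagonal 2*sqrt(3)
    cube <- cubeMask(3, 9)
    fc <- extractFeatures(imageVolume(array(1, c(9, 9, 9))), cube)
    expect_equal(unname(fc["shape_volume_mm3"]), 27)
    expect_equal(unname(fc["shape_surface_area_mm2"]), 54)
    expect_equal(unname(fc["shape_max_diameter_mm"]), 2 * sqrt(3))
    expect_equal(unname(fc["shape_elongation"]), 1, tolerance = 1e-10)
    # anisotropic spacing scales the physical volume
    fa <- extractFeatures(imageVolume(array(1, c(9, 9, 9)),
                                      spacing = c(1, 1, 2)),
                          cubeMask(3, 9, spacing = c(1, 1, 2)))
    expect_equal(unname(fa["shape_volume_mm3"]), 54)
})

test_that("first-order features are exact on a constant region", {
    img <- imageVolume(array(42, c(8, 8, 8)))
    fv <- extractFeatures(img, cubeMask(4, 8))
    expect_equal(unname(fv["fo_mean"]), 42)
    expect_equal(unname(fv["fo_variance"]), 0)
    expect_equal(unname(fv["fo_entropy"]), 0)
    expect_equal(unname(fv["fo_uniformity"]), 1)
    expect_equal(unname(fv["fo_rms"]), 42)
    expect_error(extractFeatures(img, maskVolume(array(0L, c(8, 8, 8)))),
                 "empty")
})

test_that("region GLCM contrast matches a hand-built co-occurrence matrix", {
    # 4x4x1-slab checkerboard of two gray levels inside a 6^3 volume
    v <- array(0, c(6, 6, 6))
    m <- array(0L, c(6, 6, 6))
    for (x in 2:5) for (y in 2:5) {
        v[x, y, 3] <- ((x + y) %% 2) * 30
        m[x, y, 3] <- 1L
    }
    cfg <- featureConfig(binWidth = 25, minVoxels = 5)
    fv <- extractFeatures(imageVolume(v), maskVolume(m), cfg)
    # hand GLCM over the 13 symmetric directions within the slab
    dirs <- rbind(c(1,0,0), c(0,1,0), c(0,0,1), c(1,1,0), c(1,-1,0),
                  c(1,0,1), c(1,0,-1), c(0,1,1), c(0,1,-1), c(1,1,1),
                  c(1,1,-1), c(1,-1,1), c(1,-1,-1))
    counts <- matrix(0, 2, 2)
    code <- function(x, y) ((x + y) %% 2) + 1
    for (x in 2:5) for (y in 2:5) for (d in seq_len(13)) {
        q <- c(x, y, 3) + dirs[d, ]
        if (q[1] < 2 || q[1] > 5 || q[2] < 2 || q[2] > 5 || q[3] != 3) next
        i <- code(x, y); j <- code(q[1], q[2])
        counts[i, j] <- counts[i, j] + 1
        counts[j, i] <- counts[j, i] + 1
    }
    P <- counts / sum(counts)
    expect_equal(unname(fv["glcm_contrast"]),
                 sum(P * (row(P) - col(P))^2), tolerance = 1e-12)
    expect_equal(unname(fv["glcm_joint_energy"]), sum(P^2),
                 tolerance = 1e-12)
})

test_that("run-length and size-zone features are exact on a striped region", {
    # two gray levels in alternating 4-voxel x-runs on one slab row
    v <- array(0, c(10, 4, 4)); m <- array(0L, c(10, 4, 4))
    v[1:8, 2, 2] <- rep(c(0, 40), each = 4)
    m[1:8, 2, 2] <- 1L
    cfg <- featureConfig(binWidth = 30, minVoxels = 4)
    fv <- extractFeatures(imageVolume(v), maskVolume(m), cfg)
    # x-direction: two runs of length 4; other 12 directions: 8 runs of 1
    # RLN = sum over lengths of (runs with that length)^2 / total runs
    totalRuns <- 2 + 12 * 8
    expect_equal(unname(fv["glrlm_rln"]), (2^2 + 96^2) / totalRuns,
                 tolerance = 1e-12)
    expect_equal(unname(fv["glrlm_run_percentage"]), totalRuns / (8 * 13),
                 tolerance = 1e-12)
    # size zones: two 26-connected zones of 4 voxels each
    expect_equal(unname(fv["glszm_zone_percentage"]), 2 / 8)
    expect_equal(unname(fv["glszm_lae"]), 16)
})

test_that("features are invariant to background padding and intensity structure", {
    p <- generatePhantom(tinyPhantomSpec(), seed = 5)
    fv <- extractFeatures(p$image, p$mask)
    # pad the volume with background on every side
    pad <- function(a, fill) {
        out <- array(fill, dim(a) + 6)
        out[4:(3 + dim(a)[1]), 4:(3 + dim(a)[2]), 4:(3 + dim(a)[3])] <- a
        out
    }
    fvPad <- extractFeatures(imageVolume(pad(voxelData(p$image), -500)),
                             maskVolume(pad(voxelData(p$mask), 0)))
    expect_equal(fv, fvPad, tolerance = 1e-12)
    # shape is invariant to intensity rescaling; mean is shift-equivariant
    img2 <- imageVolume(voxelData(p$image) * 4 + 100,
                        spacing = voxelSpacing(p$image))
    fv2 <- extractFeatures(img2, p$mask)
    shape <- grep("^shape_", names(fv))
    expect_equal(fv[shape], fv2[shape], tolerance = 1e-12)
    expect_equal(unname(fv2["fo_mean"]), unname(4 * fv["fo_mean"] + 100),
                 tolerance = 1e-10)
})

test_that("small regions are flagged and imputed during table assembly", {
    tiny <- extractFeatures(imageVolume(array(1, c(6, 6, 6))), cubeMask(2, 6),
                            featureConfig(minVoxels = 10))
    expect_true(all(is.na(tiny)))
    expect_true(attr(tiny, "flagged"))
    expect_error(featureConfig(classes = character(0)))
})

test_that("assembled tables have region-prefixed blocks and deterministic rows", {
    phantoms <- lapply(1:3, function(i)
        generatePhantom(tinyPhantomSpec(), seed = i))
    maps <- lapply(phantoms, function(p)
        voxelFeatureMap(p$image, p$mask, windowMm = 5))
    model <- fitHabitatModel(maps, kRange = 3, samplePerPatient = 400,
                             seed = 1)
    vois <- lapply(1:3, function(i)
        buildVoiSet(phantoms[[i]]$image, phantoms[[i]]$mask, model))
    images <- lapply(phantoms, `[[`, "image")
    tabs <- assembleFeatureTables(images, vois, config = featureConfig())
    F <- ncol(tabs$intra) - 1
    expect_equal(ncol(tabs$habitat) - 1, 3 * F)   # k = 3 blocks of F features
    expect_true(all(startsWith(names(tabs$peri)[-1], "peri_")))
    expect_true(all(grepl("^habitat[123]_", names(tabs$habitat)[-1])))
    expect_false(anyNA(tabs$habitat))
    # identical patients produce identical rows
    tabs2 <- assembleFeatureTables(images[c(1, 1)], vois[c(1, 1)],
                                   ids = c("a", "b"))
    expect_equal(unname(as.matrix(tabs2$intra[1, -1])),
                 unname(as.matrix(tabs2$intra[2, -1])))
    # patient order permutation permutes rows only
    tabs3 <- assembleFeatureTables(images[c(2, 1, 3)], vois[c(2, 1, 3)],
                                   ids = c("P2", "P1", "P3"))
    expect_equal(as.matrix(tabs3$intra[tabs3$intra$id == "P1", -1]),
                 as.matrix(tabs$intra[1, -1]), ignore_attr = TRUE)
})
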