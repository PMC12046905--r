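#' Peritumoral ring by physical outward expansion
#'
#' The ring is the set of background voxels whose Euclidean distance to the
#' tumor mask, measured in physical millimetres, is at most `distanceMm`.
#' It is disjoint from the mask by construction.  Ring voxels that would
#' fall outside the volume are clipped; a warning is emitted when the mask
#' touches the border closely enough for clipping to occur.
#'
#' @param mask nonempty binary [MaskVolume-class].
#' @param distanceMm expansion distance in mm (default 1, the margin used
#'   throughout the analysis).
#' @return A binary [MaskVolume-class] holding the ring.
#' @examples
#' m <- array(0L, c(7, 7, 7)); m[4, 4, 4] <- 1L
#' ring <- peritumoralRing(maskVolume(m), 1)
#' sum(voxelData(ring))  # the 6 face neighbours
#' @export
peritumoralRing <- function(mask, distanceMm = 1) {
    fg <- mask@values > 0
    if (!any(fg)) stop("mask is empty")
    if (distanceMm <= 0) stop("distanceMm must be positive")
    d <- dim(mask@values)
    dist <- cpp_capped_distance(as.logical(fg), d, mask@spacing, distanceMm)
    ring <- array(dist > 0 & dist <= distanceMm, d)
    # clipping check: would the ring extend past the volume border?
    reach <- ceiling(distanceMm / mask@spacing)
    idx <- which(fg, arr.ind = TRUE)
    lo <- apply(idx, 2, min); hi <- apply(idx, 2, max)
    if (any(lo - reach < 1) || any(hi + reach > d))
        warning("peritumoral ring clipped at the volume border")
    maskVolume(array(as.integer(ring), d), spacing = mask@spacing,
               origin = mask@origin)
}

voxelFeatureNames <- c("mean", "median", "sd", "variance", "skewness",
                       "kurtosis", "energy", "entropy", "uniformity", "min",
                       "max", "range", "rmad", "glcm_contrast",
                       "glcm_correlation", "glcm_joint_energy",
                       "glcm_homogeneity", "glcm_joint_entropy")

#' Per-voxel local radiomics feature map
#'
#' For every in-mask voxel, computes 18 local features over a cubic window
#' clipped to the mask: 13 first-order statistics (mean, median, SD,
#' variance, skewness, excess kurtosis, energy, entropy, uniformity, min,
#' max, range, robust mean absolute deviation) and 5 statistics of a
#' symmetric direction-pooled co-occurrence matrix at distance one voxel
#' (contrast, correlation, joint energy, homogeneity, joint entropy).
#' Gray levels are equal-width quantized to `glcmLevels` bins over the
#' whole-VOI intensity range; statistics undefined on a constant patch
#' (skewness, kurtosis, correlation) are imputed as 0.
#'
#' @param image [ImageVolume-class].
#' @param mask nonempty [MaskVolume-class] on the same grid.
#' @param windowMm cubic window edge length in mm (half-width
#'   `max(1, floor(windowMm / (2 * spacing)))` voxels per axis).
#' @param glcmLevels quantization bin count.
#' @return A list of class `VoxelFeatureMap`: `features` (n x 18 matrix),
#'   `intensity` (raw centre-voxel values), `coords` (1-based voxel
#'   indices), `featureNames`, `windowMm`, `glcmLevels`.
#' @seealso [fitHabitatModel()], [assignHabitats()]
#' @export
voxelFeatureMap <- function(image, mask, windowMm = 5, glcmLevels = 32) {
    checkSameGrid(image, mask)
    fg <- mask@values > 0
    if (!any(fg)) stop("mask is empty")
    half <- pmax(1L, as.integer(floor(windowMm / (2 * image@spacing))))
    if (windowMm < max(image@spacing)) stop("window smaller than one voxel")
    codes <- quantizeCodes(image@values, fg, glcmLevels)
    res <- cpp_voxel_feature_map(as.numeric(image@values),
                                 as.integer(codes), as.logical(fg),
                                 dim(image@values), half,
                                 as.integer(glcmLevels))
    colnames(res$features) <- voxelFeatureNames
    out <- list(features = res$features, intensity = res$intensity,
                coords = res$coords, featureNames = voxelFeatureNames,
                windowMm = windowMm, glcmLevels = glcmLevels)
    class(out) <- "VoxelFeatureMap"
    out
}

#' Davies-Bouldin cluster-validity score
#'
#' The standard index: for each cluster the dispersion `S_i` is the mean
#' Euclidean distance of its points to the centroid; the score is the mean
#' over clusters of `max_{j != i} (S_i + S_j) / d(c_i, c_j)`.  Lower is
#' better.
#'
#' @param points numeric matrix (points x features).
#' @param labels cluster assignment, at least 2 nonempty clusters.
#' @return The Davies-Bouldin score.
#' @export
daviesBouldin <- function(points, labels) {
    points <- as.matrix(points)
    labs <- sort(unique(labels))
    k <- length(labs)
    if (k < 2) stop("need at least 2 clusters")
    centroids <- matrix(0, k, ncol(points))
    S <- numeric(k)
    for (i in seq_len(k)) {
        P <- points[labels == labs[i], , drop = FALSE]
        centroids[i, ] <- colMeans(P)
        S[i] <- mean(sqrt(rowSums(sweep(P, 2, centroids[i, ])^2)))
    }
    M <- as.matrix(dist(centroids))
    R <- outer(S, S, `+`) / M
    diag(R) <- -Inf
    mean(apply(R, 1, max))
}

# k-means++ seeding followed by Lloyd iterations; several restarts, best
# total within-cluster sum of squares wins.  Deterministic under the
# current RNG state.
kmeansRestarts <- function(X, k, nstart = 10, iterMax = 100) {
    n <- nrow(X)
    best <- NULL
    for (r in seq_len(nstart)) {
        ctr <- matrix(0, k, ncol(X))
        ctr[1, ] <- X[sample.int(n, 1), ]
        d2 <- rowSums(sweep(X, 2, ctr[1, ])^2)
        for (j in 2:k) {
            p <- d2 / sum(d2)
            ctr[j, ] <- X[sample.int(n, 1, prob = p), ]
            d2 <- pmin(d2, rowSums(sweep(X, 2, ctr[j, ])^2))
        }
        fit <- suppressWarnings(kmeans(X, centers = ctr, iter.max = iterMax,
                                       algorithm = "Lloyd"))
        if (is.null(best) || fit$tot.withinss < best$tot.withinss)
            best <- fit
    }
    best
}

#' Fit a pooled habitat clustering model
#'
#' Pools sampled in-tumor voxels across training patients, z-normalises the
#' 18 per-voxel features on the pooled sample, fits K-means (k-means++
#' seeding, multiple restarts) for every candidate cluster number, and
#' selects the `k` minimising the Davies-Bouldin score (ties broken toward
#' the smaller `k`).  Clusters are renamed into habitat regions by ascending
#' mean raw image intensity, so habitat 1 is always the darkest (necrotic-
#' like) region and habitat `k` the brightest (enhancing-like) region.
#'
#' @param maps list of [voxelFeatureMap()] results, one per training patient
#'   (at least 2).
#' @param kRange candidate cluster numbers, a subset of `2:10`.
#' @param samplePerPatient voxels sampled per patient for the pooled fit.
#' @param seed integer seed (sampling and K-means restarts).
#' @param nstart K-means restarts per candidate `k`.
#' @return A [HabitatModel-class].
#' @export
fitHabitatModel <- function(maps, kRange = 2:10, samplePerPatient = 2000,
                            seed = 1, nstart = 10) {
    if (length(maps) < 2) stop("need voxel maps from at least 2 patients")
    if (any(kRange < 2) || any(kRange > 10))
        stop("kRange must lie within [2, 10]")
    kRange <- sort(unique(as.integer(kRange)))
    featNames <- maps[[1]]$featureNames
    withSeed(deriveSeed(seed, 1L), {
        pooled <- lapply(maps, function(m) {
            n <- nrow(m$features)
            idx <- if (n > samplePerPatient)
                sort(sample.int(n, samplePerPatient)) else seq_len(n)
            list(f = m$features[idx, , drop = FALSE],
                 int = m$intensity[idx])
        })
    })
    X <- do.call(rbind, lapply(pooled, `[[`, "f"))
    rawInt <- unlist(lapply(pooled, `[[`, "int"))
    if (nrow(X) < max(kRange))
        stop("fewer pooled voxels than the largest candidate k")
    ctr <- colMeans(X)
    scl <- apply(X, 2, sd)
    scl[scl == 0] <- 1
    Z <- sweep(sweep(X, 2, ctr), 2, scl, `/`)
    fits <- vector("list", length(kRange))
    db <- numeric(length(kRange))
    for (i in seq_along(kRange)) {
        fits[[i]] <- withSeed(deriveSeed(seed, 100L + kRange[i]),
                              kmeansRestarts(Z, kRange[i], nstart = nstart))
        db[i] <- daviesBouldin(Z, fits[[i]]$cluster)
    }
    kSel <- kRange[which.min(db)]           # which.min takes the first tie
    fit <- fits[[which.min(db)]]
    meanInt <- vapply(seq_len(kSel),
                      function(j) mean(rawInt[fit$cluster == j]), 0)
    ord <- order(meanInt)                   # ord[h] = raw cluster of habitat h
    labelOrder <- integer(kSel)
    labelOrder[ord] <- seq_len(kSel)        # raw cluster -> habitat number
    new("HabitatModel", k = as.integer(kSel),
        centroids = fit$centers[ord, , drop = FALSE],
        featureNames = featNames, center = ctr, scale = scl,
        labelOrder = labelOrder,
        kSearch = data.frame(k = kRange, db = db), seed = as.integer(seed))
}

#' Assign habitat labels to a tumor
#'
#' Normalises a patient's per-voxel features with the model's pooled
#' parameters, assigns each voxel to the nearest centroid, and writes the
#' intensity-ordered habitat labels `1..k` into a label volume.
#' Deterministic given the model.
#'
#' @param model a [HabitatModel-class].
#' @param map the patient's [voxelFeatureMap()].
#' @param mask the patient's tumor [MaskVolume-class] (geometry source).
#' @return A [MaskVolume-class] with labels `1..k` on the tumor voxels.
#' @export
assignHabitats <- function(model, map, mask) {
    if (!identical(map$featureNames, model@featureNames))
        stop("feature names do not match the habitat model")
    Z <- sweep(sweep(map$features, 2, model@center), 2, model@scale, `/`)
    # centroid rows already follow habitat order: nearest row = habitat label
    d2 <- sapply(seq_len(model@k), function(j)
        rowSums(sweep(Z, 2, model@centroids[j, ])^2))
    hab <- max.col(-d2, ties.method = "first")
    out <- array(0L, dim(mask@values))
    out[map$coords] <- hab
    maskVolume(out, spacing = mask@spacing, origin = mask@origin)
}

#' Build the full VOI family for one patient
#'
#' Convenience wrapper: intratumoral mask, peritumoral ring and habitat
#' label map combined into a validated [VoiSet-class].
#'
#' @param image the patient's [ImageVolume-class].
#' @param mask the tumor [MaskVolume-class].
#' @param model a fitted [HabitatModel-class].
#' @param ringMm peritumoral expansion distance in mm.
#' @param windowMm,glcmLevels forwarded to [voxelFeatureMap()]; must match
#'   the settings the model was fitted with.
#' @return A [VoiSet-class].
#' @export
buildVoiSet <- function(image, mask, model, ringMm = 1, windowMm = 5,
                        glcmLevels = 32) {
    map <- voxelFeatureMap(image, mask, windowMm = windowMm,
                           glcmLevels = glcmLevels)
    voiSet(intratumoral = mask,
           peritumoral = peritumoralRing(mask, ringMm),
           habitat = assignHabitats(model, map, mask))
}
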