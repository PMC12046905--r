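#' Region-level feature extraction configuration
#'
#' Controls the feature classes, gray-level discretisation and the minimum
#' region size.  Texture classes use fixed-bin-width quantization of the raw
#' intensities (IBSI-style); regions smaller than `minVoxels` yield an
#' all-missing vector flagged for downstream median imputation.
#'
#' @param classes feature classes to compute, a subset of
#'   `c("shape", "firstorder", "glcm", "glrlm", "glszm")`.
#' @param binWidth fixed bin width for gray-level discretisation.
#' @param minVoxels minimum region size for a defined feature vector.
#' @return A `FeatureConfig` list carrying a reproducibility hash.
#' @export
featureConfig <- function(classes = c("shape", "firstorder", "glcm", "glrlm",
                                      "glszm"),
                          binWidth = 25, minVoxels = 10) {
    classes <- match.arg(classes, several.ok = TRUE)
    if (length(classes) == 0) stop("at least one feature class is required")
    cfg <- list(classes = classes, binWidth = binWidth,
                minVoxels = as.integer(minVoxels))
    cfg$hash <- configHash(cfg)
    class(cfg) <- "FeatureConfig"
    cfg
}

# polynomial rolling hash of the serialized config, for provenance logging
configHash <- function(cfg) {
    s <- paste(deparse(cfg[setdiff(names(cfg), "hash")]), collapse = "")
    h <- 0
    for (b in utf8ToInt(s)) h <- (h * 131 + b) %% 2147483647
    sprintf("%08x", h)
}

# fixed-bin-width 0-based codes over the region values
binWidthCodes <- function(values, fg, binWidth) {
    v <- values[fg]
    codes <- array(0L, dim(values))
    q <- floor((values - min(v)) / binWidth)
    codes[] <- as.integer(q - min(q[fg]))
    nlev <- max(codes[fg]) + 1L
    list(codes = codes, nlevels = nlev)
}

shapeFeatures <- function(fg, spacing) {
    d <- dim(fg)
    n <- sum(fg)
    voxVol <- prod(spacing)
    # exposed-face surface area
    area <- 0
    faceArea <- c(spacing[2] * spacing[3], spacing[1] * spacing[3],
                  spacing[1] * spacing[2])
    for (a in 1:3) {
        off <- c(0L, 0L, 0L); off[a] <- 1L
        nb1 <- shiftArray(fg * 1, off) > 0
        nb2 <- shiftArray(fg * 1, -off) > 0
        area <- area + faceArea[a] * (sum(fg & !nb1) + sum(fg & !nb2))
    }
    V <- n * voxVol
    sphericity <- pi^(1 / 3) * (6 * V)^(2 / 3) / area
    # boundary voxels: any face neighbour outside the mask
    interior <- fg
    for (a in 1:3) {
        off <- c(0L, 0L, 0L); off[a] <- 1L
        interior <- interior & shiftArray(fg * 1, off) > 0 &
            shiftArray(fg * 1, -off) > 0
    }
    bidx <- which(fg & !interior, arr.ind = TRUE)
    if (nrow(bidx) == 0) bidx <- which(fg, arr.ind = TRUE)
    pts <- sweep(bidx - 1, 2, spacing, `*`)
    maxDiam <- if (nrow(pts) > 1) max(dist(pts)) else 0
    # principal-axis ratios from the voxel-position covariance
    allpts <- sweep(which(fg, arr.ind = TRUE) - 1, 2, spacing, `*`)
    ev <- if (nrow(allpts) > 1) {
        ev <- eigen(cov(allpts), symmetric = TRUE, only.values = TRUE)$values
        pmax(ev, 0)
    } else c(0, 0, 0)
    elongation <- if (ev[1] > 0) sqrt(ev[2] / ev[1]) else 0
    flatness <- if (ev[1] > 0) sqrt(ev[3] / ev[1]) else 0
    c(shape_volume_mm3 = V, shape_surface_area_mm2 = area,
      shape_sphericity = sphericity, shape_max_diameter_mm = maxDiam,
      shape_elongation = elongation, shape_flatness = flatness)
}

firstOrderFeatures <- function(v, codes, nlevels) {
    m <- length(v)
    mu <- mean(v)
    m2 <- mean((v - mu)^2)
    sdv <- sqrt(m2)
    qs <- quantile(v, c(0.10, 0.5, 0.90), names = FALSE, type = 7)
    iqr <- diff(quantile(v, c(0.25, 0.75), names = FALSE, type = 7))
    sel <- v >= qs[1] & v <= qs[3]
    rmad <- if (any(sel)) mean(abs(v[sel] - mean(v[sel]))) else 0
    p <- tabulate(codes + 1L, nbins = nlevels) / m
    p <- p[p > 0]
    c(fo_mean = mu, fo_median = qs[2], fo_min = min(v), fo_max = max(v),
      fo_range = max(v) - min(v), fo_p10 = qs[1], fo_p90 = qs[3],
      fo_iqr = iqr, fo_variance = m2, fo_sd = sdv,
      fo_skewness = if (sdv > 0) mean((v - mu)^3) / sdv^3 else 0,
      fo_kurtosis = if (m2 > 0) mean((v - mu)^4) / m2^2 - 3 else 0,
      fo_energy = sum(v^2), fo_entropy = -sum(p * log2(p)),
      fo_uniformity = sum(p^2), fo_rmad = rmad,
      fo_mad = mean(abs(v - mu)), fo_rms = sqrt(mean(v^2)))
}

glcmRegionFeatures <- function(codes, fg, nlevels) {
    counts <- cpp_region_glcm(as.integer(codes), as.logical(fg), dim(fg),
                              nlevels)
    tot <- sum(counts)
    if (tot == 0)
        return(c(glcm_joint_energy = 0, glcm_joint_entropy = 0,
                 glcm_contrast = 0, glcm_correlation = 0,
                 glcm_inverse_difference = 0, glcm_idm = 0,
                 glcm_cluster_shade = 0, glcm_cluster_prominence = 0))
    P <- counts / tot
    i <- row(P) - 1; j <- col(P) - 1
    px <- rowSums(P)
    mu <- sum((0:(nlevels - 1)) * px)
    sig2 <- sum(((0:(nlevels - 1)) - mu)^2 * px)
    pp <- P[P > 0]
    corr <- if (sig2 > 0) sum(P * (i - mu) * (j - mu)) / sig2 else 0
    c(glcm_joint_energy = sum(P^2),
      glcm_joint_entropy = -sum(pp * log2(pp)),
      glcm_contrast = sum(P * (i - j)^2),
      glcm_correlation = corr,
      glcm_inverse_difference = sum(P / (1 + abs(i - j))),
      glcm_idm = sum(P / (1 + (i - j)^2)),
      glcm_cluster_shade = sum(P * (i + j - 2 * mu)^3),
      glcm_cluster_prominence = sum(P * (i + j - 2 * mu)^4))
}

glrlmRegionFeatures <- function(codes, fg, nlevels) {
    counts <- cpp_region_glrlm(as.integer(codes), as.logical(fg), dim(fg),
                               nlevels)
    Nr <- sum(counts)
    Np <- sum(fg) * 13  # voxels per direction family
    lev <- row(counts); len <- col(counts)
    p <- counts / Nr
    pp <- p[p > 0]
    c(glrlm_sre = sum(p / len^2), glrlm_lre = sum(p * len^2),
      glrlm_gln = sum(rowSums(counts)^2) / Nr,
      glrlm_rln = sum(colSums(counts)^2) / Nr,
      glrlm_run_percentage = Nr / Np,
      glrlm_lglre = sum(p / lev^2), glrlm_hglre = sum(p * lev^2),
      glrlm_run_entropy = -sum(pp * log2(pp)))
}

glszmRegionFeatures <- function(codes, fg, nlevels) {
    zones <- cpp_region_glszm(as.integer(codes), as.logical(fg), dim(fg))
    lev <- zones[, 1] + 1
    siz <- zones[, 2]
    Nz <- nrow(zones)
    Np <- sum(fg)
    p <- rep(1 / Nz, Nz)
    glCounts <- tapply(rep(1, Nz), lev, sum)
    szCounts <- tapply(rep(1, Nz), siz, sum)
    cellCounts <- table(paste(lev, siz))
    pcell <- as.numeric(cellCounts) / Nz
    c(glszm_sae = mean(1 / siz^2), glszm_lae = mean(siz^2),
      glszm_gln = sum(glCounts^2) / Nz,
      glszm_zsn = sum(szCounts^2) / Nz,
      glszm_zone_percentage = Nz / Np,
      glszm_lglze = mean(1 / lev^2), glszm_hglze = mean(lev^2),
      glszm_zone_entropy = -sum(pcell * log2(pcell)))
}

#' Extract region-level radiomics features
#'
#' Computes a deterministic named feature vector for one volume of interest:
#' shape descriptors, 18 first-order statistics, and gray-level
#' co-occurrence, run-length and size-zone texture families, following
#' IBSI-style definitions with fixed-bin-width discretisation.  Regions
#' smaller than `config$minVoxels` return an all-`NA` vector with attribute
#' `flagged = TRUE` so that [assembleFeatureTables()] can impute them.
#'
#' @param image [ImageVolume-class].
#' @param voi [MaskVolume-class]; voxels with `label` (default any > 0) form
#'   the region.
#' @param config a [featureConfig()].
#' @param label which mask label defines the region (`NULL` = all > 0).
#' @return Named numeric vector with attribute `config` (the config hash).
#' @examples
#' p <- generatePhantom(phantomSpec(gridShape = c(24, 24, 24),
#'                                  tumorRadiusMm = c(7, 7, 7)), seed = 1)
#' head(extractFeatures(p$image, p$mask))
#' @export
extractFeatures <- function(image, voi, config = featureConfig(),
                            label = NULL) {
    checkSameGrid(image, voi)
    fg <- if (is.null(label)) voi@values > 0 else voi@values == label
    n <- sum(fg)
    if (n == 0) stop("empty VOI")
    out <- numeric(0)
    if (n < config$minVoxels) {
        out <- featureSkeleton(config)
        out[] <- NA_real_
        attr(out, "flagged") <- TRUE
        attr(out, "config") <- config$hash
        return(out)
    }
    v <- image@values[fg]
    bw <- binWidthCodes(image@values, fg, config$binWidth)
    if ("shape" %in% config$classes)
        out <- c(out, shapeFeatures(fg, image@spacing))
    if ("firstorder" %in% config$classes)
        out <- c(out, firstOrderFeatures(v, bw$codes[fg], bw$nlevels))
    if ("glcm" %in% config$classes)
        out <- c(out, glcmRegionFeatures(bw$codes, fg, bw$nlevels))
    if ("glrlm" %in% config$classes)
        out <- c(out, glrlmRegionFeatures(bw$codes, fg, bw$nlevels))
    if ("glszm" %in% config$classes)
        out <- c(out, glszmRegionFeatures(bw$codes, fg, bw$nlevels))
    attr(out, "config") <- config$hash
    out
}

# feature-name skeleton for a config (used for all-NA flagged vectors)
featureSkeleton <- function(config) {
    tiny <- array(0, c(4, 4, 4))
    tiny[2:3, 2:3, 2:3] <- seq_len(8)
    fg <- tiny > 0
    cfgFull <- config
    cfgFull$minVoxels <- 1L
    v <- extractFeatures(imageVolume(tiny), maskVolume(array(as.integer(fg),
                                                             dim(tiny))),
                         cfgFull)
    setNames(numeric(length(v)), names(v))
}

#' Assemble cohort feature tables per region family
#'
#' Extracts features for the intratumoral mask, the peritumoral ring, and
#' every habitat subregion of each patient, and binds them into three
#' patient x feature tables with region-prefixed names (`intra_*`, `peri_*`,
#' `habitat<j>_*`).  Habitat blocks flagged as too small are imputed with
#' the per-feature median over the remaining patients; the imputation count
#' is recorded in attribute `imputed`.
#'
#' @param images list of [ImageVolume-class], one per patient.
#' @param vois list of [VoiSet-class], aligned with `images`.
#' @param ids patient identifiers (default `P1..Pn`).
#' @param config a [featureConfig()].
#' @param k habitat count; defaults to the maximum label over patients, and
#'   every patient's habitat map must stay within `1..k`.
#' @return list of data.frames `intra`, `peri`, `habitat`, each with an
#'   `id` column first.
#' @export
assembleFeatureTables <- function(images, vois, ids = NULL,
                                  config = featureConfig(), k = NULL) {
    n <- length(images)
    if (length(vois) != n) stop("images and vois must align")
    if (is.null(ids)) ids <- sprintf("P%d", seq_len(n))
    ks <- vapply(vois, function(v) max(v@habitat@values), 0)
    if (is.null(k)) k <- max(ks)
    if (any(ks > k)) stop("inconsistent habitat count across patients")
    oneRegion <- function(getMask, prefix, label = NULL) {
        rows <- lapply(seq_len(n), function(i)
            extractFeatures(images[[i]], getMask(vois[[i]]), config,
                            label = label))
        M <- do.call(rbind, rows)
        colnames(M) <- paste0(prefix, colnames(M))
        M
    }
    intra <- oneRegion(function(v) v@intratumoral, "intra_")
    peri <- oneRegion(function(v) v@peritumoral, "peri_")
    habs <- lapply(seq_len(k), function(j)
        oneRegion(function(v) v@habitat, sprintf("habitat%d_", j), label = j))
    habitat <- do.call(cbind, habs)
    nImputed <- sum(!complete.cases(habitat))
    if (nImputed > 0) {
        for (col in seq_len(ncol(habitat))) {
            bad <- is.na(habitat[, col])
            if (any(bad))
                habitat[bad, col] <- median(habitat[!bad, col])
        }
        message(nImputed, " patient(s) had small habitat regions imputed ",
                "by cohort medians")
    }
    wrap <- function(M) {
        df <- data.frame(id = ids, M, stringsAsFactors = FALSE,
                         check.names = FALSE)
        rownames(df) <- NULL
        df
    }
    out <- list(intra = wrap(intra), peri = wrap(peri),
                habitat = wrap(habitat))
    attr(out$habitat, "imputed") <- nImputed
    out
}
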