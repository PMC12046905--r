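#' @useDynLib HabitatRadiomics, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
#' @importFrom stats approx aov as.formula binomial chisq.test coef complete.cases
#'   cor fisher.test glm kmeans lm median pchisq pnorm predict qlogis qnorm
#'   quantile rbinom rexp rnorm runif sd setNames shapiro.test t.test uniroot
#'   var wilcox.test plogis rmultinom dist ecdf
#' @importFrom utils head read.csv write.csv
NULL

#' 3D image volume with physical geometry
#'
#' A scalar 3D grid with per-axis voxel spacing and a physical origin, the
#' in-memory stand-in for a (venous-phase CT) NIfTI volume.  Physical
#' coordinates follow `origin + index * spacing` with 0-based indices; all
#' distances are millimetres.
#'
#' @slot values 3D numeric array of voxel values.
#' @slot spacing numeric(3), voxel size per axis in mm (all > 0).
#' @slot origin numeric(3), physical position of voxel (0,0,0) in mm.
#'
#' @seealso [imageVolume()], [maskVolume()], [readVolume()]
#' @export
setClass("ImageVolume",
         representation(values = "array", spacing = "numeric",
                        origin = "numeric"))

setValidity("ImageVolume", function(object) {
    if (length(dim(object@values)) != 3L)
        return("values must be a 3D array")
    if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
        any(object@spacing <= 0))
        return("spacing must be 3 positive finite values (mm)")
    if (length(object@origin) != 3L || any(!is.finite(object@origin)))
        return("origin must be 3 finite values (mm)")
    if (any(!is.finite(object@values)))
        return("voxel values must be finite")
    TRUE
})

#' Label/mask volume
#'
#' An [ImageVolume-class] whose voxels are integer labels (0 background,
#' positive labels foreground).  Binary tumor masks use label 1; habitat
#' maps use labels `1..k`.
#'
#' @seealso [maskVolume()], [peritumoralRing()], [assignHabitats()]
#' @export
setClass("MaskVolume", contains = "ImageVolume")

setValidity("MaskVolume", function(object) {
    v <- object@values
    if (any(v < 0) || any(v != round(v)))
        return("mask labels must be non-negative integers")
    TRUE
})

#' Construct an ImageVolume
#'
#' @param values 3D numeric array.
#' @param spacing voxel size per axis in mm.
#' @param origin physical origin in mm.
#' @return An [ImageVolume-class].
#' @examples
#' vol <- imageVolume(array(rnorm(64), c(4, 4, 4)), spacing = c(1, 1, 2))
#' voxelSpacing(vol)
#' @export
imageVolume <- function(values, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
    new("ImageVolume", values = values, spacing = as.numeric(spacing),
        origin = as.numeric(origin))
}

#' Construct a MaskVolume
#'
#' @param labels 3D array of non-negative integer labels (0 = background).
#' @param spacing,origin geometry, as for [imageVolume()].
#' @return A [MaskVolume-class].
#' @export
maskVolume <- function(labels, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
    storage.mode(labels) <- "double"
    new("MaskVolume", values = labels, spacing = as.numeric(spacing),
        origin = as.numeric(origin))
}

#' @describeIn ImageVolume-class voxel array dimensions
#' @param x an `ImageVolume`
#' @export
setMethod("dim", "ImageVolume", function(x) dim(x@values))

#' Accessors for volume geometry and data
#'
#' `voxelData()` returns the raw array, `voxelSpacing()` the per-axis voxel
#' size in mm and `voxelOrigin()` the physical origin.
#'
#' @param x an [ImageVolume-class] or [MaskVolume-class].
#' @return array / numeric(3).
#' @export
setGeneric("voxelData", function(x) standardGeneric("voxelData"))

#' @rdname voxelData
#' @export
setMethod("voxelData", "ImageVolume", function(x) x@values)

#' @rdname voxelData
#' @export
setGeneric("voxelSpacing", function(x) standardGeneric("voxelSpacing"))

#' @rdname voxelData
#' @export
setMethod("voxelSpacing", "ImageVolume", function(x) x@spacing)

#' @rdname voxelData
#' @export
setGeneric("voxelOrigin", function(x) standardGeneric("voxelOrigin"))

#' @rdname voxelData
#' @export
setMethod("voxelOrigin", "ImageVolume", function(x) x@origin)

setMethod("show", "ImageVolume", function(object) {
    d <- dim(object@values)
    cat(sprintf("%s %d x %d x %d, spacing %s mm\n", class(object),
                d[1], d[2], d[3],
                paste(format(object@spacing, digits = 3), collapse = " x ")))
    if (is(object, "MaskVolume")) {
        labs <- sort(unique(as.vector(object@values)))
        labs <- labs[labs > 0]
        cat(sprintf("  foreground: %d voxels, labels {%s}\n",
                    sum(object@values > 0),
                    paste(labs, collapse = ", ")))
    } else {
        cat(sprintf("  value range [%.3g, %.3g]\n", min(object@values),
                    max(object@values)))
    }
    invisible(NULL)
})

# shared-grid check used before any image/mask computation
checkSameGrid <- function(a, b) {
    if (!identical(dim(a@values), dim(b@values)))
        stop("image and mask grids differ in shape")
    if (max(abs(a@spacing - b@spacing)) > 1e-8)
        stop("image and mask voxel spacings differ")
    invisible(TRUE)
}

#' Tumor region families for one patient
#'
#' Holds the three volume-of-interest families used throughout the analysis:
#' the intratumoral mask (the delineated tumor), the peritumoral ring
#' (physical outward expansion, background only) and the habitat label map
#' (subregions `1..k` partitioning the intratumoral voxels).
#'
#' @slot intratumoral binary [MaskVolume-class].
#' @slot peritumoral binary [MaskVolume-class], disjoint from the tumor.
#' @slot habitat [MaskVolume-class] with labels `1..k` exactly covering the
#'   intratumoral foreground.
#'
#' @seealso [voiSet()], [peritumoralRing()], [assignHabitats()]
#' @export
setClass("VoiSet",
         representation(intratumoral = "MaskVolume",
                        peritumoral = "MaskVolume",
                        habitat = "MaskVolume"))

setValidity("VoiSet", function(object) {
    it <- object@intratumoral@values > 0
    pt <- object@peritumoral@values > 0
    hb <- object@habitat@values
    if (!identical(dim(it), dim(pt)) || !identical(dim(it), dim(hb)))
        return("all VOI grids must share one shape")
    if (any(it & pt))
        return("peritumoral ring must be disjoint from the tumor")
    if (!identical(hb > 0, it))
        return("habitat labels must exactly cover the intratumoral voxels")
    TRUE
})

#' Construct a VoiSet
#'
#' @param intratumoral,peritumoral,habitat see [VoiSet-class].
#' @return A [VoiSet-class].
#' @export
voiSet <- function(intratumoral, peritumoral, habitat) {
    new("VoiSet", intratumoral = intratumoral, peritumoral = peritumoral,
        habitat = habitat)
}

setMethod("show", "VoiSet", function(object) {
    k <- max(object@habitat@values)
    cat(sprintf("VoiSet: %d tumor voxels, %d ring voxels, %d habitats\n",
                sum(object@intratumoral@values > 0),
                sum(object@peritumoral@values > 0), k))
    invisible(NULL)
})

#' Fitted habitat clustering model
#'
#' A pooled K-means model over per-voxel feature vectors: z-normalisation
#' parameters estimated from the pooled training sample, centroids for the
#' selected cluster number `k`, the Davies-Bouldin score for every candidate
#' `k`, and the permutation that renames raw clusters into habitat regions
#' ordered by ascending mean raw image intensity (habitat 1 = darkest, e.g.
#' the necrotic zone; habitat k = brightest, the enhancing zone).
#'
#' @slot k selected number of habitats.
#' @slot centroids k x p matrix in normalised feature space (rows follow the
#'   habitat ordering, i.e. row 1 is habitat 1).
#' @slot featureNames character(p), the per-voxel feature names.
#' @slot center,scale numeric(p), pooled z-normalisation parameters.
#' @slot labelOrder integer(k): `labelOrder[j]` is the habitat number given
#'   to raw cluster j.
#' @slot kSearch data.frame with columns `k` and `db` (Davies-Bouldin score).
#' @slot seed integer seed the fit was run under.
#'
#' @seealso [fitHabitatModel()], [assignHabitats()]
#' @export
setClass("HabitatModel",
         representation(k = "integer", centroids = "matrix",
                        featureNames = "character", center = "numeric",
                        scale = "numeric", labelOrder = "integer",
                        kSearch = "data.frame", seed = "integer"))

setValidity("HabitatModel", function(object) {
    k <- object@k
    if (k < 2L || k > 10L) return("k must lie in [2, 10]")
    if (nrow(object@centroids) != k) return("centroids must have k rows")
    if (!setequal(object@labelOrder, seq_len(k)))
        return("labelOrder must be a permutation of 1..k")
    if (length(object@center) != ncol(object@centroids) ||
        length(object@scale) != ncol(object@centroids))
        return("normalization parameters must match centroid dimension")
    kk <- object@kSearch$k[which.min(object@kSearch$db)]
    if (length(kk) && min(object@kSearch$k[object@kSearch$db ==
                                           min(object@kSearch$db)]) != k)
        return("k must minimize the recorded Davies-Bouldin scores")
    TRUE
})

setMethod("show", "HabitatModel", function(object) {
    cat(sprintf("HabitatModel: k = %d habitats (Davies-Bouldin over k = %s)\n",
                object@k, paste(range(object@kSearch$k), collapse = "..")))
    cat(sprintf("  %d voxel features, seed %d\n", ncol(object@centroids),
                object@seed))
    invisible(NULL)
})
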