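#' Read a 3D volume from NIfTI
#'
#' Reads a `.nii`/`.nii.gz` file into an [ImageVolume-class] (or
#' [MaskVolume-class] when `mask = TRUE`), taking voxel spacing and origin
#' from the header.
#'
#' @param path file path.
#' @param mask logical; interpret voxels as integer labels.
#' @return An [ImageVolume-class] or [MaskVolume-class].
#' @seealso [writeVolume()]
#' @export
readVolume <- function(path, mask = FALSE) {
    if (!file.exists(path)) stop("file not found: ", path)
    img <- RNifti::readNifti(path)
    arr <- as.array(img)
    arr <- array(as.vector(arr), dim = dim(arr))  # strip image attributes
    if (length(dim(arr)) == 4L && dim(arr)[4] == 1L)
        arr <- arr[, , , 1, drop = TRUE]
    if (length(dim(arr)) != 3L)
        stop("expected a 3D volume, got ", length(dim(arr)), " dimensions")
    sp <- RNifti::pixdim(img)[1:3]
    hdr <- RNifti::niftiHeader(img)
    org <- c(hdr$qoffset_x, hdr$qoffset_y, hdr$qoffset_z)
    if (mask) maskVolume(round(arr), spacing = sp, origin = org)
    else imageVolume(arr * 1.0, spacing = sp, origin = org)
}

#' Write a 3D volume to NIfTI
#'
#' @param vol an [ImageVolume-class].
#' @param path output `.nii` / `.nii.gz` path.
#' @return `path`, invisibly.
#' @export
writeVolume <- function(vol, path) {
    img <- RNifti::asNifti(vol@values)
    aff <- diag(c(vol@spacing, 1))
    aff[1:3, 4] <- vol@origin
    RNifti::qform(img) <- structure(aff, code = 2L)
    RNifti::pixdim(img) <- vol@spacing
    RNifti::writeNifti(img, path)
    invisible(path)
}

#' Resample a volume to isotropic spacing
#'
#' Trilinear (images) or nearest-neighbour (masks) resampling onto an
#' isotropic grid.  The physical extent `dim * spacing` is preserved to
#' within one output voxel; voxel centres sit at `origin + index * target`.
#'
#' @param vol [ImageVolume-class] or [MaskVolume-class].
#' @param targetMm target isotropic voxel size in mm.
#' @param interpolation `"linear"` or `"nearest"`; masks always use nearest.
#' @return A resampled volume of the same class.
#' @examples
#' vol <- imageVolume(array(rnorm(8^3), c(8, 8, 8)), spacing = c(0.5, 0.5, 2))
#' dim(resampleIsotropic(vol, 1))
#' @export
resampleIsotropic <- function(vol, targetMm = 1,
                              interpolation = c("linear", "nearest")) {
    interpolation <- match.arg(interpolation)
    if (targetMm <= 0) stop("targetMm must be positive")
    d <- dim(vol@values)
    extent <- d * vol@spacing
    if (targetMm > max(extent)) stop("target spacing exceeds volume extent")
    isMask <- is(vol, "MaskVolume")
    if (isMask) interpolation <- "nearest"
    nd <- pmax(1L, as.integer(round(extent / targetMm)))
    if (identical(nd, d) && max(abs(vol@spacing - targetMm)) < 1e-12)
        return(vol)
    # continuous input index for each output index (centre-aligned lattice)
    ix <- (seq_len(nd[1]) - 1) * targetMm / vol@spacing[1]
    iy <- (seq_len(nd[2]) - 1) * targetMm / vol@spacing[2]
    iz <- (seq_len(nd[3]) - 1) * targetMm / vol@spacing[3]
    if (interpolation == "nearest") {
        gx <- pmin(d[1], pmax(1L, as.integer(round(ix)) + 1L))
        gy <- pmin(d[2], pmax(1L, as.integer(round(iy)) + 1L))
        gz <- pmin(d[3], pmax(1L, as.integer(round(iz)) + 1L))
        out <- vol@values[gx, gy, gz, drop = FALSE]
    } else {
        x0 <- pmin(d[1] - 1L, pmax(1L, floor(ix) + 1L)); wx <- ix + 1 - x0
        y0 <- pmin(d[2] - 1L, pmax(1L, floor(iy) + 1L)); wy <- iy + 1 - y0
        z0 <- pmin(d[3] - 1L, pmax(1L, floor(iz) + 1L)); wz <- iz + 1 - z0
        wx <- pmin(1, pmax(0, wx)); wy <- pmin(1, pmax(0, wy))
        wz <- pmin(1, pmax(0, wz))
        v <- vol@values
        corner <- function(ax, ay, az) v[ax, ay, az, drop = FALSE]
        WX <- array(wx, dim = nd)
        WY <- array(rep(wy, each = nd[1]), dim = nd)
        WZ <- array(rep(wz, each = nd[1] * nd[2]), dim = nd)
        out <- corner(x0, y0, z0) * (1 - WX) * (1 - WY) * (1 - WZ) +
            corner(x0 + 1L, y0, z0) * WX * (1 - WY) * (1 - WZ) +
            corner(x0, y0 + 1L, z0) * (1 - WX) * WY * (1 - WZ) +
            corner(x0 + 1L, y0 + 1L, z0) * WX * WY * (1 - WZ) +
            corner(x0, y0, z0 + 1L) * (1 - WX) * (1 - WY) * WZ +
            corner(x0 + 1L, y0, z0 + 1L) * WX * (1 - WY) * WZ +
            corner(x0, y0 + 1L, z0 + 1L) * (1 - WX) * WY * WZ +
            corner(x0 + 1L, y0 + 1L, z0 + 1L) * WX * WY * WZ
    }
    sp <- rep(targetMm, 3)
    if (isMask) maskVolume(round(out), spacing = sp, origin = vol@origin)
    else imageVolume(out, spacing = sp, origin = vol@origin)
}

#' Normalise voxel intensities
#'
#' `method = "zscore"` centres and scales to unit SD over the body voxels
#' (the whole volume by default, or `mask` foreground when supplied);
#' `method = "window"` clips to `[low, high]` and rescales to `[0, 1]`.
#'
#' @param vol an [ImageVolume-class].
#' @param method `"zscore"` or `"window"`.
#' @param low,high window bounds (required for `"window"`).
#' @param mask optional [MaskVolume-class] defining the body voxels for the
#'   z-score statistics.
#' @return A normalised [ImageVolume-class].
#' @export
normalizeIntensity <- function(vol, method = c("zscore", "window"),
                               low = NULL, high = NULL, mask = NULL) {
    method <- match.arg(method)
    v <- vol@values
    if (method == "zscore") {
        body <- if (is.null(mask)) v else {
            checkSameGrid(vol, mask)
            v[mask@values > 0]
        }
        mu <- mean(body)
        sdv <- sd(as.vector(body))
        if (!is.finite(sdv) || sdv == 0)
            stop("z-score normalization needs nonzero intensity variance")
        out <- (v - mu) / sdv
    } else {
        if (is.null(low) || is.null(high) || high <= low)
            stop("window normalization needs low < high")
        out <- (pmin(pmax(v, low), high) - low) / (high - low)
    }
    imageVolume(out, spacing = vol@spacing, origin = vol@origin)
}
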