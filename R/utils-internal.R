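# internal array / numeric helpers shared across modules

# shift a 3D array by integer offset, zero-filling exposed planes
shiftArray <- function(arr, off) {
    d <- dim(arr)
    out <- array(0, d)
    src <- dst <- vector("list", 3)
    for (a in 1:3) {
        o <- off[a]
        if (abs(o) >= d[a]) return(out)
        if (o >= 0) { src[[a]] <- 1:(d[a] - o); dst[[a]] <- (1 + o):d[a] }
        else { src[[a]] <- (1 - o):d[a]; dst[[a]] <- 1:(d[a] + o) }
    }
    out[dst[[1]], dst[[2]], dst[[3]]] <- arr[src[[1]], src[[2]], src[[3]]]
    out
}

# separable Gaussian blur; sigma in voxels per axis, zero-phase, kernel
# renormalised at the borders (replicate-free, sum-preserving inside)
gaussSmooth <- function(arr, sigmaVox) {
    for (a in 1:3) {
        s <- sigmaVox[a]
        if (s <= 0) next
        r <- max(1L, ceiling(3 * s))
        k <- exp(-(seq(-r, r))^2 / (2 * s^2))
        k <- k / sum(k)
        acc <- array(0, dim(arr))
        wgt <- array(0, dim(arr))
        one <- array(1, dim(arr))
        for (i in seq_along(k)) {
            off <- c(0L, 0L, 0L)
            off[a] <- i - r - 1L
            acc <- acc + k[i] * shiftArray(arr, off)
            wgt <- wgt + k[i] * shiftArray(one, off)
        }
        arr <- acc / wgt
    }
    arr
}

# equal-width quantization to 0-based integer codes over the mask range
quantizeCodes <- function(values, mask, nlevels) {
    v <- values[mask]
    lo <- min(v); hi <- max(v)
    codes <- array(0L, dim(values))
    if (hi > lo) {
        q <- floor((values - lo) / (hi - lo) * nlevels)
        codes[] <- as.integer(pmin(q, nlevels - 1))
    }
    codes
}

# half-up decimal rounding (R's round() is half-even)
roundHalfUp <- function(x, digits = 0) {
    m <- 10^digits
    sign(x) * trunc(abs(x) * m + 0.5 + 1e-9) / m
}

# stratified fold assignment, deterministic under the current RNG state
stratifiedFolds <- function(labels, nFolds) {
    folds <- integer(length(labels))
    for (cl in unique(labels)) {
        idx <- which(labels == cl)
        folds[idx] <- sample(rep_len(seq_len(nFolds), length(idx)))
    }
    folds
}

# small-integer seed derived from a base seed and a stream tag
deriveSeed <- function(seed, tag) {
    (as.integer(seed) * 1103L + as.integer(tag) * 12347L) %% 2147483000L
}

withSeed <- function(seed, expr) {
    old <- if (exists(".Random.seed", envir = globalenv()))
        get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
        if (is.null(old)) {
            if (exists(".Random.seed", envir = globalenv()))
                rm(".Random.seed", envir = globalenv())
        } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
    expr
}
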