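# small shared fixtures, built in code at test time

# compact phantom for geometry-level tests
tinyPhantomSpec <- function(...) {
    phantomSpec(gridShape = c(24, 24, 24), tumorRadiusMm = c(7, 7, 7), ...)
}

# cube mask centred in a grid
cubeMask <- function(side = 3, grid = 9, spacing = c(1, 1, 1)) {
    m <- array(0L, rep(grid, 3))
    lo <- (grid - side) %/% 2 + 1
    m[lo:(lo + side - 1), lo:(lo + side - 1), lo:(lo + side - 1)] <- 1L
    maskVolume(m, spacing = spacing)
}

# brute-force per-voxel feature oracle, independent of the compiled path
bruteVoxelFeatures <- function(image, mask, half, nlevels) {
    v <- voxelData(image)
    fg <- voxelData(mask) > 0
    d <- dim(v)
    rng <- range(v[fg])
    codes <- if (diff(rng) > 0)
        pmin(floor((v - rng[1]) / diff(rng) * nlevels), nlevels - 1)
    else array(0, d)
    dirs <- rbind(c(1,0,0), c(0,1,0), c(0,0,1), c(1,1,0), c(1,-1,0),
                  c(1,0,1), c(1,0,-1), c(0,1,1), c(0,1,-1), c(1,1,1),
                  c(1,1,-1), c(1,-1,1), c(1,-1,-1))
    idx <- which(fg, arr.ind = TRUE)
    out <- matrix(NA_real_, nrow(idx), 18)
    for (vv in seq_len(nrow(idx))) {
        c0 <- idx[vv, ]
        lo <- pmax(c0 - half, 1); hi <- pmin(c0 + half, d)
        nb <- expand.grid(x = lo[1]:hi[1], y = lo[2]:hi[2], z = lo[3]:hi[3])
        keep <- fg[as.matrix(nb)]
        nb <- nb[keep, , drop = FALSE]
        vals <- v[as.matrix(nb)]
        m <- length(vals)
        mu <- mean(vals)
        m2 <- mean((vals - mu)^2); sdv <- sqrt(m2)
        p10 <- quantile(vals, 0.1, names = FALSE)
        p90 <- quantile(vals, 0.9, names = FALSE)
        sel <- vals >= p10 & vals <= p90
        rmad <- if (any(sel)) mean(abs(vals[sel] - mean(vals[sel]))) else 0
        cc <- codes[as.matrix(nb)]
        pr <- table(cc) / m
        # co-occurrence within the window, clipped to mask
        P <- matrix(0, nlevels, nlevels)
        for (r in seq_len(nrow(nb))) for (k in seq_len(13)) {
            q <- as.numeric(nb[r, ]) + dirs[k, ]
            if (any(q < lo) || any(q > hi)) next
            if (!fg[q[1], q[2], q[3]]) next
            ci <- codes[nb[r, 1], nb[r, 2], nb[r, 3]] + 1
            cj <- codes[q[1], q[2], q[3]] + 1
            P[ci, cj] <- P[ci, cj] + 1
            P[cj, ci] <- P[cj, ci] + 1
        }
        gl <- if (sum(P) > 0) {
            P <- P / sum(P)
            i <- row(P) - 1; j <- col(P) - 1
            px <- rowSums(P)
            muI <- sum((0:(nlevels - 1)) * px)
            varI <- sum(((0:(nlevels - 1)) - muI)^2 * px)
            pp <- P[P > 0]
            c(sum(P * (i - j)^2),
              if (varI > 0) sum(P * (i - muI) * (j - muI)) / varI else 0,
              sum(P^2), sum(P / (1 + abs(i - j))), -sum(pp * log2(pp)))
        } else c(0, 0, 0, 0, 0)
        out[vv, ] <- c(mu, median(vals), sdv, m2,
                       if (sdv > 0) mean((vals - mu)^3) / sdv^3 else 0,
                       if (m2 > 0) mean((vals - mu)^4) / m2^2 - 3 else 0,
                       sum(vals^2), -sum(pr * log2(pr)), sum(pr^2),
                       min(vals), max(vals), diff(range(vals)), rmad, gl)
    }
    out
}
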