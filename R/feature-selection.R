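#' Intraclass correlation coefficient, two-way random effects ICC(2,1)
#'
#' Absolute-agreement, single-rater ICC from the two-way random-effects
#' variance decomposition (Shrout & Fleiss convention): with subject,
#' rater and residual mean squares `MSR`, `MSC`, `MSE` over `n` subjects
#' and `k` raters,
#' `ICC = (MSR - MSE) / (MSR + (k-1) MSE + k/n (MSC - MSE))`.
#' Absolute agreement penalises systematic rater offsets, which is why a
#' constant-shift replicate scores below 1.
#'
#' @param x matrix or data.frame, subjects x raters (>= 3 subjects).
#' @return The ICC(2,1) value.
#' @export
icc21 <- function(x) {
    x <- as.matrix(x)
    n <- nrow(x); k <- ncol(x)
    if (n < 3) stop("ICC needs at least 3 replicate subjects")
    grand <- mean(x)
    rowM <- rowMeans(x); colM <- colMeans(x)
    MSR <- k * sum((rowM - grand)^2) / (n - 1)
    MSC <- n * sum((colM - grand)^2) / (k - 1)
    SSE <- sum((sweep(sweep(x, 1, rowM), 2, colM) + grand)^2)
    MSE <- SSE / ((n - 1) * (k - 1))
    (MSR - MSE) / (MSR + (k - 1) * MSE + k / n * (MSC - MSE))
}

# split a feature table into id column + numeric matrix
tableMatrix <- function(table) {
    idCol <- intersect("id", names(table))
    M <- as.matrix(table[setdiff(names(table), idCol)])
    list(id = if (length(idCol)) table$id else NULL, M = M)
}

#' Reproducibility (ICC) filter
#'
#' Computes, for every feature, the intra-observer ICC(2,1) (primary
#' segmentation vs the same reader's repeat) and the inter-observer ICC(2,1)
#' (primary vs a second reader), over the replicate subset of patients, and
#' keeps features whose ICCs both exceed `threshold`.  Habitat-region
#' features (names starting `habitat`) bypass the filter: subregion
#' membership is re-derived per segmentation, so repeat-segmentation ICC is
#' not a meaningful reproducibility measure for them.  Bypassed features are
#' flagged, not filtered.
#'
#' @param primary feature table (`id` column plus features) from the
#'   original segmentation.
#' @param interRep,intraRep feature tables from the second observer and the
#'   repeat segmentation; may cover a patient subset (matched by `id`).
#' @param threshold ICC cutoff (default 0.75).
#' @return list: `kept` (character), `stats` (data.frame feature/iccIntra/
#'   iccInter/bypassed/kept), `threshold`.
#' @export
iccFilter <- function(primary, interRep, intraRep, threshold = 0.75) {
    p <- tableMatrix(primary)
    keepStats <- lapply(list(inter = interRep, intra = intraRep), function(r) {
        rr <- tableMatrix(r)
        ids <- intersect(p$id, rr$id)
        if (length(ids) < 3) stop("ICC needs at least 3 replicate subjects")
        a <- p$M[match(ids, p$id), , drop = FALSE]
        b <- rr$M[match(ids, rr$id), colnames(p$M), drop = FALSE]
        vapply(seq_len(ncol(a)),
               function(j) icc21(cbind(a[, j], b[, j])), 0)
    })
    feats <- colnames(p$M)
    bypass <- startsWith(feats, "habitat")
    kept <- bypass | (keepStats$intra > threshold &
                      keepStats$inter > threshold)
    stats <- data.frame(feature = feats, iccIntra = keepStats$intra,
                        iccInter = keepStats$inter, bypassed = bypass,
                        kept = kept, stringsAsFactors = FALSE)
    list(kept = feats[kept], stats = stats, threshold = threshold)
}

#' Z-score normalisation fitted on the training set
#'
#' `zscoreFit()` learns per-feature mean and SD on the training table
#' (dropping zero-variance features with a warning); `zscoreApply()` applies
#' the training parameters to any table, so test sets are scaled with
#' training statistics.
#'
#' @param train training feature table.
#' @return A `ZscoreTransform` list with `center`, `scale`, `features`.
#' @export
zscoreFit <- function(train) {
    t <- tableMatrix(train)
    ctr <- colMeans(t$M)
    scl <- apply(t$M, 2, sd)
    drop <- !is.finite(scl) | scl == 0
    if (any(drop))
        warning("dropping ", sum(drop), " zero-variance feature(s): ",
                paste(head(colnames(t$M)[drop], 5), collapse = ", "))
    keep <- colnames(t$M)[!drop]
    out <- list(center = ctr[keep], scale = scl[keep], features = keep)
    class(out) <- "ZscoreTransform"
    out
}

#' @rdname zscoreFit
#' @param transform a fitted `ZscoreTransform`.
#' @param table any feature table with the training features.
#' @return `zscoreApply()`: the transformed table (id column preserved).
#' @export
zscoreApply <- function(transform, table) {
    t <- tableMatrix(table)
    miss <- setdiff(transform$features, colnames(t$M))
    if (length(miss)) stop("table lacks features: ",
                           paste(head(miss, 5), collapse = ", "))
    M <- sweep(sweep(t$M[, transform$features, drop = FALSE], 2,
                     transform$center), 2, transform$scale, `/`)
    df <- if (is.null(t$id)) as.data.frame(M)
        else data.frame(id = t$id, M, stringsAsFactors = FALSE,
                        check.names = FALSE)
    rownames(df) <- NULL
    df
}

#' Mann-Whitney U relevance filter
#'
#' Two-sided Mann-Whitney U test per feature between the outcome classes;
#' features with `p < alpha` survive.  The exact distribution is used when
#' both groups have fewer than 8 observations (and no ties); otherwise the
#' normal approximation with tie correction.
#'
#' @param table feature table.
#' @param labels 0/1 outcome, both classes with >= 2 members.
#' @param alpha significance threshold (default 0.05).
#' @return list: `kept`, `stats` (feature, U, p, kept), `alpha`.
#' @export
mwuFilter <- function(table, labels, alpha = 0.05) {
    t <- tableMatrix(table)
    labels <- as.integer(labels)
    if (length(unique(labels)) < 2) stop("both classes must be present")
    n1 <- sum(labels == 1); n0 <- sum(labels == 0)
    exact <- n1 < 8 && n0 < 8
    res <- apply(t$M, 2, function(x) {
        w <- suppressWarnings(wilcox.test(x[labels == 1], x[labels == 0],
                                          exact = exact, correct = FALSE))
        c(w$statistic, w$p.value)
    })
    stats <- data.frame(feature = colnames(t$M), U = res[1, ], p = res[2, ],
                        kept = res[2, ] < alpha, stringsAsFactors = FALSE)
    rownames(stats) <- NULL
    list(kept = stats$feature[stats$kept], stats = stats, alpha = alpha)
}

#' Spearman redundancy pruning
#'
#' Removes one member of every highly correlated feature pair
#' (`|rho| > threshold`).  Features are ranked by ascending Mann-Whitney p
#' (ties broken by name); scanning in that order, a feature is kept only if
#' its absolute Spearman correlation with every already-kept feature stays
#' at or below the threshold -- so of any correlated pair the member with
#' the smaller p survives.  Deterministic.
#'
#' @param table feature table.
#' @param pvalues named vector of per-feature Mann-Whitney p-values (from
#'   [mwuFilter()]); features missing from it rank last.
#' @param threshold correlation cutoff (default 0.9).
#' @return list: `kept`, `dropped` (with the partner that displaced each),
#'   `threshold`.
#' @export
spearmanPrune <- function(table, pvalues = NULL, threshold = 0.9) {
    t <- tableMatrix(table)
    feats <- colnames(t$M)
    if (length(feats) < 2)
        return(list(kept = feats,
                    dropped = data.frame(feature = character(),
                                         partner = character()),
                    threshold = threshold))
    p <- if (is.null(pvalues)) setNames(rep(1, length(feats)), feats)
        else pvalues[feats]
    p[is.na(p)] <- Inf
    ord <- order(p, feats)
    rho <- abs(cor(t$M, method = "spearman"))
    kept <- character(0)
    dropped <- character(0); partner <- character(0)
    for (f in feats[ord]) {
        conflict <- kept[rho[f, kept] > threshold]
        if (length(conflict) == 0) kept <- c(kept, f)
        else { dropped <- c(dropped, f); partner <- c(partner, conflict[1]) }
    }
    list(kept = feats[feats %in% kept],  # restore table order
         dropped = data.frame(feature = dropped, partner = partner,
                              stringsAsFactors = FALSE),
         threshold = threshold)
}

#' LASSO feature selection
#'
#' L1-penalised logistic regression with the penalty chosen by stratified
#' cross-validated binomial deviance; features with nonzero coefficients at
#' the selected penalty survive.  `lambdaRule = "min"` (default) takes the
#' deviance minimiser, `"1se"` the usual one-standard-error choice.
#'
#' @param table feature table (already z-scored in the cascade).
#' @param labels 0/1 outcome.
#' @param nFolds cross-validation folds (stratified).
#' @param seed integer seed for the fold assignment.
#' @param lambdaRule `"min"` or `"1se"`.
#' @return list: `kept`, `coefficients` (nonzero, named), `lambda`,
#'   `lambdaRule`, `cvFit` (the `cv.glmnet` object).
#' @export
lassoSelect <- function(table, labels, nFolds = 5, seed = 1,
                        lambdaRule = c("min", "1se")) {
    lambdaRule <- match.arg(lambdaRule)
    t <- tableMatrix(table)
    if (ncol(t$M) < 2) stop("LASSO needs at least 2 features")
    labels <- as.integer(labels)
    foldid <- withSeed(deriveSeed(seed, 42L),
                       stratifiedFolds(labels, nFolds))
    cvFit <- glmnet::cv.glmnet(t$M, labels, family = "binomial",
                               type.measure = "deviance", foldid = foldid,
                               standardize = FALSE)
    lam <- if (lambdaRule == "min") cvFit$lambda.min else cvFit$lambda.1se
    cf <- as.matrix(coef(cvFit, s = lam))[-1, 1]
    kept <- names(cf)[cf != 0]
    list(kept = kept, coefficients = cf[cf != 0], lambda = lam,
         lambdaRule = lambdaRule, cvFit = cvFit)
}

#' Run the full feature-selection cascade
#'
#' Reproducibility filter (when replicate tables are supplied), z-score
#' normalisation fitted on the training set, Mann-Whitney U relevance
#' filter, Spearman redundancy pruning, and LASSO -- in that order.  Each
#' stage operates on the previous stage's survivors, so the surviving sets
#' are nested by construction.
#'
#' @param train training feature table (`id` + features).
#' @param labels 0/1 outcome aligned with `train` rows.
#' @param interRep,intraRep optional replicate tables for the ICC stage;
#'   when `NULL` the stage is skipped (recorded in the report).
#' @param iccThreshold,alpha,rhoThreshold,nFolds,lambdaRule stage
#'   parameters; see the stage functions.
#' @param seed integer seed (LASSO folds).
#' @return A `SelectionReport` list: `stages` (named list of surviving
#'   feature vectors, in cascade order), `counts`, per-stage detail tables,
#'   `transform` (the fitted z-score), `selected` (final features),
#'   `coefficients`, `seed`.
#' @examples
#' sim <- simulateFeatureTable(n = 120, seed = 3)
#' rep <- selectFeatures(sim$table, sim$labels, seed = 3)
#' rep$counts
#' @export
selectFeatures <- function(train, labels, interRep = NULL, intraRep = NULL,
                           iccThreshold = 0.75, alpha = 0.05,
                           rhoThreshold = 0.9, nFolds = 5,
                           lambdaRule = "min", seed = 1) {
    stages <- list()
    detail <- list()
    t0 <- tableMatrix(train)
    stages$input <- colnames(t0$M)
    current <- train
    if (!is.null(interRep) && !is.null(intraRep)) {
        icc <- iccFilter(current, interRep, intraRep, iccThreshold)
        detail$icc <- icc$stats
        current <- current[, c(intersect("id", names(current)), icc$kept),
                           drop = FALSE]
        stages$icc <- icc$kept
    }
    transform <- zscoreFit(current)
    current <- zscoreApply(transform, current)
    stages$zscore <- transform$features
    mwu <- mwuFilter(current, labels, alpha)
    detail$mwu <- mwu$stats
    if (length(mwu$kept) == 0)
        stop("no features pass the Mann-Whitney filter")
    current <- current[, c(intersect("id", names(current)), mwu$kept),
                       drop = FALSE]
    stages$mwu <- mwu$kept
    sp <- spearmanPrune(current, setNames(mwu$stats$p, mwu$stats$feature),
                        rhoThreshold)
    detail$spearman <- sp$dropped
    current <- current[, c(intersect("id", names(current)), sp$kept),
                       drop = FALSE]
    stages$spearman <- sp$kept
    if (length(sp$kept) >= 2) {
        las <- lassoSelect(current, labels, nFolds = nFolds, seed = seed,
                           lambdaRule = lambdaRule)
        stages$lasso <- las$kept
        coefs <- las$coefficients
        detail$lasso <- data.frame(feature = names(coefs),
                                   coefficient = as.numeric(coefs),
                                   stringsAsFactors = FALSE)
    } else {
        stages$lasso <- sp$kept
        coefs <- NULL
    }
    out <- list(stages = stages,
                counts = vapply(stages, length, 0L),
                detail = detail, transform = transform,
                selected = stages$lasso, coefficients = coefs, seed = seed)
    class(out) <- "SelectionReport"
    out
}

#' @export
print.SelectionReport <- function(x, ...) {
    cat("Feature-selection cascade:\n")
    for (s in names(x$stages))
        cat(sprintf("  %-8s %d features\n", s, length(x$stages[[s]])))
    invisible(x)
}

#' Serialise a selection report to JSON
#'
#' @param report a `SelectionReport`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeSelectionReport <- function(report, path) {
    jsonlite::write_json(list(stages = report$stages,
                              counts = as.list(report$counts),
                              selected = report$selected,
                              seed = report$seed),
                         path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
    invisible(path)
}
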