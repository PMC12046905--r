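#' Train a radiomics classifier
#'
#' Fits one of the three model families on the selected features -- logistic
#' regression (`"lr"`), radial-kernel support vector machine (`"svm"`, with
#' Platt-scaled probabilities and a small inner grid search over cost and
#' kernel width), or random forest (`"rf"`, 500 trees, score = class-vote
#' fraction) -- and records stratified cross-validated AUCs.  All scores are
#' probabilities in `[0, 1]`; everything is deterministic under `seed`.
#'
#' @param kind `"lr"`, `"svm"` or `"rf"`.
#' @param table feature table (`id` column optional), selected features only.
#' @param labels 0/1 outcome, both classes present.
#' @param nFolds cross-validation folds (default 5, stratified).
#' @param seed integer seed (folds, forest, grid search).
#' @param ntree random-forest size.
#' @param costGrid,gammaScale SVM grid: costs tried, and multipliers of the
#'   default kernel width `1/p`.
#' @return A `FittedClassifier` list: `kind`, `features`, `model`, `cv`
#'   (per-fold AUC), `cvAuc`, `cvAucSd`, `folds`, `seed`.
#' @examples
#' sim <- simulateFeatureTable(n = 150, nNoise = 5, seed = 2)
#' fit <- trainClassifier("rf", sim$table, sim$labels, seed = 2)
#' round(fit$cvAuc, 2)
#' @export
trainClassifier <- function(kind = c("lr", "svm", "rf"), table, labels,
                            nFolds = 5, seed = 1, ntree = 500,
                            costGrid = c(0.1, 1, 10),
                            gammaScale = c(0.5, 1, 2)) {
    kind <- match.arg(kind)
    t <- tableMatrix(table)
    labels <- as.integer(labels)
    if (length(unique(labels)) < 2) stop("both classes must be present")
    folds <- withSeed(deriveSeed(seed, 7L), stratifiedFolds(labels, nFolds))
    fitOne <- function(X, y, seedTag) {
        switch(kind,
            lr = {
                df <- data.frame(y = y, X, check.names = FALSE)
                suppressWarnings(glm(y ~ ., data = df, family = binomial()))
            },
            svm = withSeed(deriveSeed(seed, seedTag), {
                e1071::svm(X, factor(y, levels = c(0, 1)),
                           kernel = "radial", cost = attr(X, "cost") %||% 1,
                           gamma = attr(X, "gamma") %||% (1 / ncol(X)),
                           probability = TRUE)
            }),
            rf = withSeed(deriveSeed(seed, seedTag), {
                randomForest::randomForest(
                    X, factor(y, levels = c(0, 1)), ntree = ntree,
                    mtry = max(1, floor(sqrt(ncol(X)))))
            }))
    }
    predictOne <- function(model, X) {
        switch(kind,
            lr = as.numeric(predict(model,
                                    newdata = as.data.frame(X,
                                                            check.names = FALSE),
                                    type = "response")),
            svm = {
                pr <- attr(predict(model, X, probability = TRUE),
                           "probabilities")
                as.numeric(pr[, "1"])
            },
            rf = as.numeric(predict(model, X, type = "prob")[, "1"]))
    }
    hyper <- NULL
    if (kind == "svm") {
        # inner grid search: stratified CV AUC over (cost, gamma)
        best <- NULL
        for (cost in costGrid) for (gs in gammaScale) {
            gamma <- gs / ncol(t$M)
            aucs <- vapply(seq_len(nFolds), function(f) {
                tr <- folds != f
                X <- t$M[tr, , drop = FALSE]
                attr(X, "cost") <- cost; attr(X, "gamma") <- gamma
                m <- fitOne(X, labels[tr], 200L + f)
                rocAuc(predictOne(m, t$M[!tr, , drop = FALSE]),
                       labels[!tr])$auc
            }, 0)
            if (is.null(best) || mean(aucs) > best$auc)
                best <- list(cost = cost, gamma = gamma, auc = mean(aucs))
        }
        hyper <- best
    }
    withHyper <- function(X) {
        if (kind == "svm") { attr(X, "cost") <- hyper$cost
                             attr(X, "gamma") <- hyper$gamma }
        X
    }
    cvAuc <- vapply(seq_len(nFolds), function(f) {
        tr <- folds != f
        m <- fitOne(withHyper(t$M[tr, , drop = FALSE]), labels[tr], 300L + f)
        rocAuc(predictOne(m, t$M[!tr, , drop = FALSE]), labels[!tr])$auc
    }, 0)
    model <- fitOne(withHyper(t$M), labels, 400L)
    out <- list(kind = kind, features = colnames(t$M), model = model,
                hyper = hyper, cv = cvAuc, cvAuc = mean(cvAuc),
                cvAucSd = sd(cvAuc), folds = folds, seed = seed,
                predictFun = predictOne)
    class(out) <- "FittedClassifier"
    out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.FittedClassifier <- function(x, ...) {
    cat(sprintf("%s classifier on %d features; CV AUC %.3f (SD %.3f)\n",
                toupper(x$kind), length(x$features), x$cvAuc, x$cvAucSd))
    invisible(x)
}

#' Radiomics score (predicted probability of node positivity)
#'
#' @param fit a [trainClassifier()] result.
#' @param table feature table containing the training feature schema.
#' @return Numeric scores in `[0, 1]`, one per row.
#' @export
radiomicsScore <- function(fit, table) {
    t <- tableMatrix(table)
    miss <- setdiff(fit$features, colnames(t$M))
    if (length(miss)) stop("table lacks model features: ",
                           paste(head(miss, 5), collapse = ", "))
    fit$predictFun(fit$model, t$M[, fit$features, drop = FALSE])
}

# one logistic fit -> OR rows with Wald CI (z = 1.96) and Wald p
orRows <- function(model, variable) {
    cf <- summary(model)$coefficients
    cf <- cf[setdiff(rownames(cf), "(Intercept)"), , drop = FALSE]
    data.frame(variable = variable, term = rownames(cf),
               or = exp(cf[, 1]),
               ciLow = exp(cf[, 1] - 1.96 * cf[, 2]),
               ciHigh = exp(cf[, 1] + 1.96 * cf[, 2]),
               p = 2 * pnorm(-abs(cf[, 1] / cf[, 2])),
               unstable = abs(cf[, 1]) > 10 | cf[, 2] > 10,
               stringsAsFactors = FALSE, row.names = NULL)
}

#' Univariable logistic screening
#'
#' One univariable logistic regression per candidate variable against the
#' node label; categorical variables are expanded against their reference
#' level (first factor level).  Odds ratios with Wald 95% CIs (`z = 1.96`)
#' and Wald p-values, the layout of a standard baseline-predictor table.
#' Perfect separation is flagged in the `unstable` column rather than
#' suppressed.
#'
#' @param data data.frame of candidate variables (factors for categorical).
#' @param labels 0/1 outcome.
#' @param variables which columns to screen (default all).
#' @return data.frame of class `OrTable`: variable, term, or, ciLow,
#'   ciHigh, p, unstable.
#' @export
univariableScreen <- function(data, labels, variables = names(data)) {
    labels <- as.integer(labels)
    rows <- lapply(variables, function(v) {
        x <- data[[v]]
        if (is.character(x)) x <- factor(x)
        if (is.factor(x) && nlevels(droplevels(x)) < 2)
            stop("variable ", v, " has fewer than 2 levels")
        if (is.numeric(x) && var(x) == 0)
            stop("variable ", v, " has zero variance")
        df <- data.frame(y = labels, x = x)
        orRows(suppressWarnings(glm(y ~ x, df, family = binomial())), v)
    })
    out <- do.call(rbind, rows)
    out$term <- sub("^x", "", out$term)
    class(out) <- c("OrTable", class(out))
    out
}

#' Multivariable logistic model with adjusted odds ratios
#'
#' Joint logistic MLE over the screened variables; adjusted ORs with Wald
#' CIs and p-values.  A collinear design (aliased coefficients) falls back
#' to a lightly ridge-penalised fit with a warning.  The hybrid occult-LNM
#' model is this fit on the screened survivors including the radiomics
#' score; the clinical model is the same call without the score.
#'
#' @param data data.frame of covariates.
#' @param labels 0/1 outcome.
#' @param variables model terms (default all columns).
#' @return list: `orTable` (class `OrTable`), `model` (the `glm`),
#'   `predict(newdata)` returning probabilities.
#' @export
multivariableModel <- function(data, labels, variables = names(data)) {
    labels <- as.integer(labels)
    df <- data.frame(y = labels, data[variables], check.names = FALSE)
    nParam <- sum(vapply(data[variables], function(x)
        if (is.factor(x) || is.character(x))
            nlevels(factor(x)) - 1L else 1L, 0L)) + 1L
    if (nrow(df) < 10 * nParam)
        warning("fewer than 10 events-free observations per parameter")
    fml <- as.formula(paste("y ~",
                            paste(sprintf("`%s`", variables),
                                  collapse = " + ")))
    model <- suppressWarnings(glm(fml, df, family = binomial()))
    if (anyNA(coef(model))) {
        warning("collinear design; using a ridge-stabilized fit")
        X <- model.matrix(model)[, -1, drop = FALSE]
        rg <- glmnet::glmnet(X, labels, family = "binomial", alpha = 0,
                             lambda = 1e-3)
        beta <- as.matrix(coef(rg))[, 1]
        model$coefficients[names(beta)] <- beta
    }
    ot <- orRows(model, "joint")
    ot$variable <- sub("`?([^`]*)`?.*", "\\1",
                       vapply(ot$term, function(tm) {
                           hit <- variables[startsWith(tm,
                                                       paste0("`", variables,
                                                              "`")) |
                                            startsWith(tm, variables)]
                           if (length(hit)) hit[which.max(nchar(hit))] else tm
                       }, ""))
    ot$term <- mapply(function(tm, v) sub(paste0("^`?", v, "`?"), "", tm),
                      ot$term, ot$variable, USE.NAMES = FALSE)
    class(ot) <- c("OrTable", class(ot))
    list(orTable = ot, model = model,
         predict = function(newdata)
             as.numeric(predict(model, newdata = newdata,
                                type = "response")))
}

#' Permutation feature importance
#'
#' Mean AUC drop over `nPerm` random permutations of each feature column,
#' the model-agnostic stand-in for per-feature contribution plots.
#'
#' @param fit a [trainClassifier()] result.
#' @param table feature table.
#' @param labels 0/1 outcome.
#' @param nPerm permutations per feature.
#' @param seed integer seed.
#' @return data.frame: feature, aucDrop, sorted descending.
#' @export
permutationImportance <- function(fit, table, labels, nPerm = 10, seed = 1) {
    t <- tableMatrix(table)
    base <- rocAuc(radiomicsScore(fit, table), labels)$auc
    drops <- withSeed(deriveSeed(seed, 77L), {
        vapply(fit$features, function(f) {
            mean(vapply(seq_len(nPerm), function(i) {
                M <- t$M
                M[, f] <- sample(M[, f])
                base - rocAuc(fit$predictFun(fit$model,
                                             M[, fit$features,
                                               drop = FALSE]),
                              labels)$auc
            }, 0))
        }, 0)
    })
    out <- data.frame(feature = fit$features, aucDrop = drops,
                      stringsAsFactors = FALSE, row.names = NULL)
    out[order(-out$aucDrop), ]
}
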