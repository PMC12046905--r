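test_that("ICC(2,1) matches the variance-components oracle and penalises offsets", {
    # brute-force oracle straight from the two-way ANOVA decomposition
    iccOracle <- function(x) {
        n <- nrow(x); k <- ncol(x)
        df <- data.frame(y = as.vector(x),
                         subj = factor(rep(seq_len(n), k)),
                         rater = factor(rep(seq_len(k), each = n)))
        ms <- anova(lm(y ~ subj + rater, df))[["Mean Sq"]]
        (ms[1] - ms[3]) / (ms[1] + (k - 1) * ms[3] + k / n * (ms[2] - ms[3]))
    }
    set.seed(7)
    for (i in 1:5) {
        x <- cbind(rnorm(6, 10, 3), rnorm(6, 10, 3))
        x[, 2] <- 0.8 * x[, 1] + 0.2 * x[, 2]
        expect_equal(icc21(x), iccOracle(x), tolerance = 1e-8)
    }
    base <- rnorm(10, 5, 2)
    expect_equal(icc21(cbind(base, base)), 1, tolerance = 1e-12)
    # constant offset: absolute agreement < 1
    expect_lt(icc21(cbind(base, base + 2)), 1)
    expect_error(icc21(cbind(rnorm(2), rnorm(2))), "at least 3")
})

test_that("ICC filter keeps reproducible features and bypasses habitat features", {
    set.seed(15)
    n <- 30
    stable <- rnorm(n, 50, 10)
    fragile <- rnorm(n)
    tab <- data.frame(id = sprintf("P%02d", 1:n),
                      intra_stable = stable, intra_fragile = fragile,
                      habitat1_any = rnorm(n))
    jitter <- function(x, sd) x + rnorm(length(x), 0, sd)
    rep1 <- tab; rep1$intra_stable <- jitter(stable, 1)
    rep1$intra_fragile <- rnorm(n); rep1$habitat1_any <- rnorm(n)
    rep2 <- tab; rep2$intra_stable <- jitter(stable, 1)
    rep2$intra_fragile <- rnorm(n); rep2$habitat1_any <- rnorm(n)
    res <- iccFilter(tab, rep1, rep2)
    expect_true("intra_stable" %in% res$kept)
    expect_false("intra_fragile" %in% res$kept)
    expect_true("habitat1_any" %in% res$kept)  # bypass, not filtered
    expect_true(res$stats$bypassed[res$stats$feature == "habitat1_any"])
})

test_that("z-scoring is fitted on training data and applied with training parameters", {
    set.seed(4)
    train <- data.frame(id = sprintf("T%d", 1:50), a = rnorm(50, 5, 2),
                        b = runif(50), flat = rep(3, 50))
    expect_warning(tr <- zscoreFit(train), "zero-variance")
    expect_false("flat" %in% tr$features)
    z <- zscoreApply(tr, train)
    expect_true(all(abs(colMeans(z[tr$features])) < 1e-12))
    expect_true(all(abs(apply(z[tr$features], 2, sd) - 1) < 1e-12))
    test <- data.frame(id = "X", a = 7, b = 0.5, flat = 3)
    zt <- zscoreApply(tr, test)
    expect_equal(zt$a, (7 - mean(train$a)) / sd(train$a), tolerance = 1e-12)
})

test_that("Mann-Whitney filter matches exact enumeration and drops null features", {
    tab <- data.frame(sep = c(1, 2, 3, 4, 5, 6), null = rep(1, 6))
    labels <- c(0, 0, 0, 1, 1, 1)
    res <- mwuFilter(tab, labels, alpha = 0.2)
    expect_equal(res$stats$p[res$stats$feature == "sep"], 0.1)  # U = 0 exact
    expect_true("sep" %in% res$kept)
    expect_false("null" %in% res$kept)
    # strong separation at n = 20/20 is detected
    set.seed(2)
    big <- data.frame(f = c(rnorm(20), rnorm(20) + 5))
    res2 <- mwuFilter(big, rep(c(0, 1), each = 20))
    expect_lt(res2$stats$p, 1e-6)
})

test_that("Mann-Whitney filter is calibrated under the null", {
    kept <- vapply(1:50, function(s) {
        set.seed(s)
        tab <- as.data.frame(matrix(rnorm(60 * 40), 60))
        length(mwuFilter(tab, rep(c(0, 1), 30))$kept) / 40
    }, 0)
    expect_lt(abs(mean(kept) - 0.05), 0.02)
})

test_that("Spearman pruning follows the greedy best-p rule", {
    set.seed(8)
    n <- 200
    A <- rnorm(n)
    B <- A + rnorm(n, 0, 0.12)  # rho(A,B) > 0.9
    C <- B + rnorm(n, 0, 0.14)  # rho(B,C) > 0.9, rho(A,C) a bit lower
    tab <- data.frame(A = A, B = B, C = C)
    rho <- cor(tab, method = "spearman")
    # construct the chain case: A-B and B-C correlated, A-C below threshold
    skipChain <- !(abs(rho["A", "B"]) > 0.9 && abs(rho["B", "C"]) > 0.9 &&
                   abs(rho["A", "C"]) <= 0.9)
    res <- spearmanPrune(tab, pvalues = c(A = 0.01, B = 0.02, C = 0.03),
                         threshold = 0.9)
    if (!skipChain) expect_equal(res$kept, c("A", "C"))
    # duplicated column: exactly one survives, the one with smaller p
    dup <- data.frame(x = A, y = A)
    resDup <- spearmanPrune(dup, pvalues = c(x = 0.5, y = 0.1))
    expect_equal(resDup$kept, "y")
    # orthogonal features all survive
    orth <- as.data.frame(matrix(rnorm(300), 100))
    expect_equal(length(spearmanPrune(orth)$kept), 3)
})

test_that("LASSO shrinks fully at large lambda and approaches the MLE at small lambda", {
    set.seed(19)
    n <- 200
    x1 <- rnorm(n); x2 <- rnorm(n)
    y <- rbinom(n, 1, plogis(1.2 * x1 - 0.8 * x2))
    X <- cbind(x1 = x1, x2 = x2)
    fit <- glmnet::glmnet(X, y, family = "binomial", standardize = FALSE)
    big <- as.matrix(coef(fit, s = 5))[-1, 1]
    expect_true(all(big == 0))
    small <- as.matrix(coef(fit, s = 1e-5, exact = TRUE, x = X, y = y,
                            family = "binomial", standardize = FALSE))[, 1]
    mle <- coef(glm(y ~ x1 + x2, family = binomial()))
    expect_equal(unname(small), unname(mle), tolerance = 1e-3)
})

test_that("the cascade recovers informative features and nests its stages", {
    hits <- vapply(1:10, function(s) {
        sim <- simulateFeatureTable(n = 300, nInformative = 3, nNoise = 47,
                                    seed = s)
        rep <- selectFeatures(sim$table, sim$labels, seed = s)
        # nested survivors
        st <- rep$stages
        for (i in seq_along(st)[-1])
            expect_true(all(st[[i]] %in% st[[i - 1]]))
        all(sprintf("inf_%d", 1:3) %in% rep$selected)
    }, FALSE)
    expect_gte(mean(hits), 0.9)
})

test_that("the cascade is deterministic under a fixed seed", {
    sim <- simulateFeatureTable(n = 150, seed = 5)
    r1 <- selectFeatures(sim$table, sim$labels, seed = 11)
    r2 <- selectFeatures(sim$table, sim$labels, seed = 11)
    expect_identical(r1$stages, r2$stages)
    expect_identical(r1$coefficients, r2$coefficients)
})
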