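#' Odds ratio with Wald confidence interval
#'
#' Cross-product odds ratio for a 2x2 table with cells `a` =
#' exposed/positive, `b` = exposed/negative, `c` = unexposed/positive,
#' `d` = unexposed/negative: `OR = (a d) / (b c)`, Wald 95% CI
#' `exp(log OR +/- 1.96 sqrt(1/a + 1/b + 1/c + 1/d))` and Wald p-value.
#' This equals `exp(beta)` of the univariable logistic regression on the
#' exposure indicator.  Any zero cell triggers the Haldane-Anscombe +0.5
#' correction, flagged in the result.
#'
#' @param a,b,c,d cell counts, or `a` may be a 2x2 matrix with exposure in
#'   rows (exposed first) and outcome in columns (positive first).
#' @param z CI multiplier (default 1.96).
#' @return list: `or`, `ci`, `p`, `corrected`.
#' @examples
#' oddsRatio(78, 226, 8, 18)  # smoker vs non-smoker occult-LNM odds
#' @export
oddsRatio <- function(a, b = NULL, c = NULL, d = NULL, z = 1.96) {
    if (is.matrix(a)) {
        d <- a[2, 2]; c <- a[2, 1]; b <- a[1, 2]; a <- a[1, 1]
    }
    cells <- c(a, b, c, d)
    if (any(cells < 0)) stop("counts must be non-negative")
    if (sum(cells[1:2]) == 0 || sum(cells[3:4]) == 0 ||
        sum(cells[c(1, 3)]) == 0 || sum(cells[c(2, 4)]) == 0)
        stop("zero margin: odds ratio undefined")
    corrected <- any(cells == 0)
    if (corrected) cells <- cells + 0.5
    lo <- log(cells[1]) + log(cells[4]) - log(cells[2]) - log(cells[3])
    se <- sqrt(sum(1 / cells))
    list(or = exp(lo), ci = exp(lo + c(-z, z) * se),
         p = 2 * pnorm(-abs(lo / se)), corrected = corrected)
}

#' Per-level odds ratios against a reference level
#'
#' Each non-reference exposure level is compared with the reference as a
#' 2x2 [oddsRatio()]; identical to dummy-coded univariable logistic
#' regression.
#'
#' @param counts r x 2 matrix: rows = exposure levels (rownames = level
#'   names), columns = (positive, negative) outcome counts.
#' @param reference reference level name or row index (default first row).
#' @param z CI multiplier.
#' @return data.frame: level, or, ciLow, ciHigh, p.
#' @examples
#' tstage <- rbind(T1 = c(13, 75), T2 = c(23, 88),
#'                 T3 = c(31, 63), T4 = c(19, 18))
#' categoricalOr(tstage)
#' @export
categoricalOr <- function(counts, reference = 1, z = 1.96) {
    counts <- as.matrix(counts)
    if (is.character(reference)) reference <- match(reference,
                                                    rownames(counts))
    if (sum(counts[reference, ]) == 0) stop("reference row is empty")
    ref <- counts[reference, ]
    rows <- lapply(setdiff(seq_len(nrow(counts)), reference), function(i) {
        o <- oddsRatio(counts[i, 1], counts[i, 2], ref[1], ref[2], z = z)
        data.frame(level = rownames(counts)[i] %||% as.character(i),
                   or = o$or, ciLow = o$ci[1], ciHigh = o$ci[2], p = o$p,
                   stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
}

#' Chi-square or Fisher test for a contingency table
#'
#' `chiSquare()` is the Pearson test without continuity correction (Yates
#' optional); `fisherExact()` the exact hypergeometric test;
#' `associationTest()` applies the conventional switching rule -- Fisher
#' whenever any expected cell count is below 5 -- and records the choice.
#'
#' @param counts contingency table of non-negative counts.
#' @param yates apply the continuity correction.
#' @return list: `statistic`, `df`, `p` (and `method` for
#'   `associationTest`).
#' @export
chiSquare <- function(counts, yates = FALSE) {
    counts <- as.matrix(counts)
    if (sum(counts) == 0) stop("all-zero table")
    ct <- suppressWarnings(chisq.test(counts, correct = yates))
    list(statistic = unname(ct$statistic), df = unname(ct$parameter),
         p = ct$p.value)
}

#' @rdname chiSquare
#' @export
fisherExact <- function(counts) {
    counts <- as.matrix(counts)
    if (sum(counts) == 0) stop("all-zero table")
    list(p = fisher.test(counts)$p.value)
}

#' @rdname chiSquare
#' @export
associationTest <- function(counts) {
    counts <- as.matrix(counts)
    if (sum(counts) == 0) stop("all-zero table")
    expected <- outer(rowSums(counts), colSums(counts)) / sum(counts)
    if (any(expected < 5)) {
        out <- fisherExact(counts)
        out$method <- "fisher"
    } else {
        out <- chiSquare(counts)
        out$method <- "chi-square"
    }
    out
}

#' Compare a continuous variable between two groups
#'
#' `method = "auto"` applies the conventional rule: Welch t-test when both
#' groups pass a Shapiro-Wilk normality screen (p > 0.05), Mann-Whitney U
#' otherwise; the choice is recorded.  Exact Mann-Whitney for small
#' tie-free samples, as in [mwuFilter()].
#'
#' @param x,y the two groups (each >= 2 values).
#' @param method `"auto"`, `"t"` or `"mwu"`.
#' @return list: `statistic`, `p`, `method`.
#' @export
compareContinuous <- function(x, y, method = c("auto", "t", "mwu")) {
    method <- match.arg(method)
    if (length(x) < 2 || length(y) < 2) stop("both groups need >= 2 values")
    if (method == "auto") {
        normal <- function(v) length(unique(v)) > 2 &&
            shapiro.test(v)$p.value > 0.05
        method <- if (normal(x) && normal(y)) "t" else "mwu"
    }
    if (method == "t") {
        if (sd(x) == 0 && sd(y) == 0) {
            warning("zero variance in both groups")
            return(list(statistic = 0,
                        p = if (mean(x) == mean(y)) 1 else 0,
                        method = "t"))
        }
        tt <- t.test(x, y)
        list(statistic = unname(tt$statistic), p = tt$p.value, method = "t")
    } else {
        exact <- length(x) < 8 && length(y) < 8
        w <- suppressWarnings(wilcox.test(x, y, exact = exact,
                                          correct = FALSE))
        list(statistic = unname(w$statistic), p = w$p.value,
             method = "mwu")
    }
}

#' Prevalence as a percentage
#'
#' `100 * positives / total`, rounded half-up to two decimals (matching the
#' reporting convention of clinical baseline tables).
#'
#' @param positives,total non-negative counts, `positives <= total`,
#'   `total > 0`.
#' @return Percentage with two decimals.
#' @examples
#' prevalencePct(86, 330)
#' @export
prevalencePct <- function(positives, total) {
    if (total <= 0) stop("total must be positive")
    if (positives < 0 || positives > total)
        stop("positives must lie in [0, total]")
    roundHalfUp(100 * positives / total, 2)
}

#' Baseline characteristics table
#'
#' Summarises a cohort's covariates by node status the way clinical
#' baseline tables do: mean (SD) with a t / Mann-Whitney p for continuous
#' variables, counts (percent) with a chi-square / Fisher p for categorical
#' ones.
#'
#' @param data cohort data.frame.
#' @param labels 0/1 node status.
#' @param variables columns to summarise.
#' @return data.frame: variable, level, negative, positive, p, test.
#' @export
baselineTable <- function(data, labels,
                          variables = setdiff(names(data), "id")) {
    labels <- as.integer(labels)
    rows <- lapply(variables, function(v) {
        x <- data[[v]]
        if (is.numeric(x) && length(unique(x)) > 6) {
            cmp <- compareContinuous(x[labels == 0], x[labels == 1])
            data.frame(variable = v, level = "",
                       negative = sprintf("%.2f (%.2f)",
                                          mean(x[labels == 0]),
                                          sd(x[labels == 0])),
                       positive = sprintf("%.2f (%.2f)",
                                          mean(x[labels == 1]),
                                          sd(x[labels == 1])),
                       p = cmp$p, test = cmp$method,
                       stringsAsFactors = FALSE)
        } else {
            x <- factor(x)
            tab <- table(x, factor(labels, levels = c(0, 1)))
            at <- associationTest(tab)
            data.frame(variable = v, level = levels(x),
                       negative = sprintf("%d (%.1f%%)", tab[, 1],
                                          100 * tab[, 1] / sum(tab[, 1])),
                       positive = sprintf("%d (%.1f%%)", tab[, 2],
                                          100 * tab[, 2] / sum(tab[, 2])),
                       p = at$p, test = at$method,
                       stringsAsFactors = FALSE)
        }
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}
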