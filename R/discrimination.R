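#' ROC AUC with DeLong variance
#'
#' AUC by the Mann-Whitney statistic (ties count one half) with the DeLong
#' structural-component variance and a Wald 95% CI clipped to `[0, 1]`.
#'
#' @param scores numeric predictions (higher = more positive).
#' @param labels 0/1 outcome, both classes present.
#' @return list of class `RocResult`: `auc`, `var`, `ci` (length 2),
#'   `nPos`, `nNeg`, `v10`, `v01` (structural components).
#' @examples
#' rocAuc(c(0.9, 0.8, 0.3, 0.2), c(1, 1, 0, 0))$auc
#' @export
rocAuc <- function(scores, labels) {
    labels <- as.integer(labels)
    pos <- scores[labels == 1]; neg <- scores[labels == 0]
    m <- length(pos); n <- length(neg)
    if (m == 0 || n == 0) stop("both classes must be present")
    # placement values via midranks: one pass instead of all pairs
    r <- rank(c(pos, neg), ties.method = "average")
    v10 <- (r[seq_len(m)] - rank(pos, ties.method = "average")) / n
    v01 <- 1 - (r[m + seq_len(n)] - rank(neg, ties.method = "average")) / m
    auc <- mean(v10)
    v <- if (m > 1 && n > 1) var(v10) / m + var(v01) / n else 0
    ci <- pmin(1, pmax(0, auc + c(-1.96, 1.96) * sqrt(v)))
    out <- list(auc = auc, var = v, ci = ci, nPos = m, nNeg = n,
                v10 = v10, v01 = v01)
    class(out) <- "RocResult"
    out
}

#' @export
print.RocResult <- function(x, ...) {
    cat(sprintf("AUC %.3f (95%% CI %.3f-%.3f), %d+/%d-\n", x$auc, x$ci[1],
                x$ci[2], x$nPos, x$nNeg))
    invisible(x)
}

#' DeLong test for two correlated AUCs
#'
#' Paired comparison of two score vectors on the same patients via the
#' covariance of the DeLong structural components; two-sided p-value.
#' A zero variance of the difference (e.g. a model against itself) gives
#' `p = 1`.
#'
#' @param scoresA,scoresB score vectors on the same patients.
#' @param labels 0/1 outcome.
#' @return list: `aucA`, `aucB`, `z`, `p`, `varDiff`.
#' @export
delongCompare <- function(scoresA, scoresB, labels) {
    if (length(scoresA) != length(scoresB))
        stop("score vectors must cover the same patients")
    a <- rocAuc(scoresA, labels); b <- rocAuc(scoresB, labels)
    m <- a$nPos; n <- a$nNeg
    varDiff <- (var(a$v10) + var(b$v10) - 2 * cov(a$v10, b$v10)) / m +
        (var(a$v01) + var(b$v01) - 2 * cov(a$v01, b$v01)) / n
    if (varDiff <= .Machine$double.eps)
        return(list(aucA = a$auc, aucB = b$auc, z = 0, p = 1, varDiff = 0))
    z <- (a$auc - b$auc) / sqrt(varDiff)
    list(aucA = a$auc, aucB = b$auc, z = z, p = 2 * pnorm(-abs(z)),
         varDiff = varDiff)
}

#' Operating cutoff by the maximum Youden index
#'
#' Scans all observed scores as candidate cutoffs (classification rule:
#' positive when `score >= cutoff`) and returns the cutoff maximising
#' `sensitivity + specificity - 1`; ties resolve to the lowest cutoff.
#'
#' @param scores,labels as in [rocAuc()].
#' @return list: `cutoff`, `youden`.
#' @export
youdenCutoff <- function(scores, labels) {
    labels <- as.integer(labels)
    cand <- sort(unique(scores))
    J <- vapply(cand, function(ct) {
        sens <- mean(scores[labels == 1] >= ct)
        spec <- mean(scores[labels == 0] < ct)
        sens + spec - 1
    }, 0)
    best <- which(J == max(J))[1]
    list(cutoff = cand[best], youden = J[best])
}

#' Confusion-matrix metrics at a cutoff
#'
#' Classification rule: positive when `score >= cutoff` (inclusive).
#' Metrics with a zero denominator are returned as `NA` with attribute
#' `undefined` naming them.
#'
#' @param scores,labels as in [rocAuc()].
#' @param cutoff finite decision threshold.
#' @return list of class `ThresholdMetrics`: `cutoff`, `tp`, `fp`, `tn`,
#'   `fn`, `accuracy`, `sensitivity`, `specificity`, `ppv`, `npv`.
#' @export
thresholdMetrics <- function(scores, labels, cutoff) {
    if (!is.finite(cutoff)) stop("cutoff must be finite")
    labels <- as.integer(labels)
    pred <- as.integer(scores >= cutoff)
    tp <- sum(pred == 1 & labels == 1); fp <- sum(pred == 1 & labels == 0)
    tn <- sum(pred == 0 & labels == 0); fn <- sum(pred == 0 & labels == 1)
    safe <- function(num, den) if (den == 0) NA_real_ else num / den
    out <- list(cutoff = cutoff, tp = tp, fp = fp, tn = tn, fn = fn,
                accuracy = (tp + tn) / length(labels),
                sensitivity = safe(tp, tp + fn),
                specificity = safe(tn, tn + fp),
                ppv = safe(tp, tp + fp), npv = safe(tn, tn + fn))
    und <- names(out)[vapply(out, function(x) length(x) == 1 && is.na(x),
                             FALSE)]
    if (length(und)) attr(out, "undefined") <- und
    class(out) <- "ThresholdMetrics"
    out
}

#' Calibration curve with logistic recalibration
#'
#' Equal-frequency binning of the scores against observed event rates, plus
#' the logistic-recalibration slope and intercept (logit of the score as
#' the only covariate).  Degenerate bins (identical boundaries) are merged
#' with a warning.
#'
#' @param scores probabilities in `[0, 1]`.
#' @param labels 0/1 outcome.
#' @param nBins target number of bins (n must be at least `nBins`).
#' @return list: `bins` (data.frame meanScore / observedRate / n),
#'   `slope`, `intercept`.
#' @export
calibrationCurve <- function(scores, labels, nBins = 10) {
    labels <- as.integer(labels)
    n <- length(scores)
    if (n < nBins) stop("need at least nBins observations")
    br <- unique(quantile(scores, seq(0, 1, length.out = nBins + 1),
                          type = 7))
    if (length(br) < nBins + 1)
        warning("degenerate score bins merged")
    if (length(br) == 1) br <- c(br - 1e-9, br + 1e-9)
    bin <- cut(scores, br, include.lowest = TRUE)
    bins <- data.frame(
        meanScore = as.numeric(tapply(scores, bin, mean)),
        observedRate = as.numeric(tapply(labels, bin, mean)),
        n = as.numeric(table(bin)))
    bins <- bins[bins$n > 0, ]
    eps <- 1e-8
    lp <- qlogis(pmin(1 - eps, pmax(eps, scores)))
    fit <- suppressWarnings(glm(labels ~ lp, family = binomial()))
    list(bins = bins, slope = unname(coef(fit)[2]),
         intercept = unname(coef(fit)[1]))
}

#' Decision-curve analysis
#'
#' Net benefit of the model, of treat-all and of treat-none across
#' threshold probabilities:
#' `NB(pt) = TP/n - FP/n * pt / (1 - pt)` with classification at
#' `score >= pt`.  Thresholds at or above 1 are excluded.
#'
#' @param scores probabilities.
#' @param labels 0/1 outcome.
#' @param thresholds threshold probabilities in (0, 1).
#' @return data.frame: threshold, netBenefit, treatAll, treatNone.
#' @export
decisionCurve <- function(scores, labels,
                          thresholds = seq(0.01, 0.99, by = 0.01)) {
    labels <- as.integer(labels)
    thresholds <- thresholds[thresholds > 0 & thresholds < 1]
    n <- length(labels)
    prev <- mean(labels)
    rows <- vapply(thresholds, function(pt) {
        tp <- sum(scores >= pt & labels == 1)
        fp <- sum(scores >= pt & labels == 0)
        w <- pt / (1 - pt)
        c(tp / n - fp / n * w, prev - (1 - prev) * w)
    }, c(0, 0))
    data.frame(threshold = thresholds, netBenefit = rows[1, ],
               treatAll = rows[2, ], treatNone = 0)
}
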