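#' Kaplan-Meier survival curve
#'
#' Product-limit estimator (via [survival::survfit()]) with Greenwood
#' standard errors; events precede censoring at tied times, the standard
#' convention.
#'
#' @param time follow-up times (months, >= 0).
#' @param event 1 = event observed, 0 = censored.
#' @return list of class `SurvivalCurve`: `time`, `nRisk`, `nEvent`,
#'   `surv`, `stdErr`, and the underlying `fit`.
#' @seealso [survivalAt()], [logrankTest()]
#' @export
kmEstimate <- function(time, event) {
    if (any(time < 0)) stop("survival times must be non-negative")
    fit <- survival::survfit(survival::Surv(time, event) ~ 1)
    out <- list(time = fit$time, nRisk = fit$n.risk, nEvent = fit$n.event,
                surv = fit$surv, stdErr = fit$std.err, fit = fit)
    class(out) <- "SurvivalCurve"
    out
}

#' Survival probability at a time point
#'
#' Value of the Kaplan-Meier step function at `t` (3-year rates use
#' `t = 36` months).  Before the first event the estimate is 1.
#'
#' @param curve a [kmEstimate()] result.
#' @param t time point (same units as the curve).
#' @return Survival probability at `t`.
#' @export
survivalAt <- function(curve, t = 36) {
    idx <- which(curve$time <= t)
    if (length(idx) == 0) return(1)
    ev <- idx[curve$nEvent[idx] > 0]
    if (length(ev) == 0) return(1)
    curve$surv[max(ev)]
}

#' Two-group log-rank test
#'
#' Standard 1-df log-rank statistic (observed minus expected events with
#' hypergeometric variance, via [survival::survdiff()]).  When no events
#' occur at all the test is undefined and `p = 1` is returned with a
#' warning.
#'
#' @param time,event as in [kmEstimate()].
#' @param group two-level group labels.
#' @return list: `chisq`, `p`, `obs`, `exp` (per-group observed and
#'   expected events).
#' @export
logrankTest <- function(time, event, group) {
    group <- factor(group)
    if (nlevels(droplevels(group)) != 2)
        stop("exactly two nonempty groups are required")
    if (sum(event) == 0) {
        warning("no events observed; log-rank undefined")
        return(list(chisq = 0, p = 1,
                    obs = tapply(event, group, sum),
                    exp = tapply(event, group, sum)))
    }
    sd <- survival::survdiff(survival::Surv(time, event) ~ group)
    list(chisq = sd$chisq, p = pchisq(sd$chisq, 1, lower.tail = FALSE),
         obs = sd$obs, exp = sd$exp)
}

#' Stratify patients into risk groups at a score cutoff
#'
#' High risk when `score >= cutoff` (inclusive, matching the
#' classification rule of [thresholdMetrics()]).
#'
#' @param scores radiomics or hybrid model scores.
#' @param cutoff finite threshold (e.g. the training Youden cutoff).
#' @return factor with levels `low`, `high`.
#' @export
stratifyRisk <- function(scores, cutoff) {
    if (!is.finite(cutoff)) stop("cutoff must be finite")
    factor(ifelse(scores >= cutoff, "high", "low"),
           levels = c("low", "high"))
}
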