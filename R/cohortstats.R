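# Survival curves and tests, rank-based multi-group tests, mutation
# enrichment and effect-size screens used to characterize the clusters.

#' Kaplan-Meier product-limit estimator
#'
#' @param times non-negative follow-up times (days)
#' @param events 0 = censored, 1 = event
#' @return data.frame with columns \code{time}, \code{nRisk}, \code{nEvent},
#'   \code{surv} (non-increasing step function starting at 1)
#' @export
kaplanMeier <- function(times, events) {
    if (any(times < 0)) stop("negative follow-up time")
    if (!all(events %in% c(0, 1))) stop("events must be 0/1")
    fit <- survival::survfit(survival::Surv(times, events) ~ 1)
    data.frame(time = fit$time, nRisk = fit$n.risk, nEvent = fit$n.event,
               surv = fit$surv)
}

#' k-group log-rank test
#'
#' @param times,events as in [kaplanMeier()]
#' @param groups group labels (>= 2 non-empty groups)
#' @return list with \code{chi2}, \code{df} (k - 1) and \code{p}
#' @export
logrankTest <- function(times, events, groups) {
    groups <- as.factor(groups)
    if (any(table(groups) == 0) || nlevels(groups) < 2)
        stop("need >= 2 non-empty groups")
    sd <- survival::survdiff(survival::Surv(times, events) ~ groups)
    df <- nlevels(groups) - 1
    list(chi2 = sd$chisq, df = df,
         p = stats::pchisq(sd$chisq, df = df, lower.tail = FALSE))
}

#' Kruskal-Wallis omnibus test
#'
#' Tie-corrected H statistic with a chi-square p-value (delegates to
#' \code{stats::kruskal.test}); all-equal values yield H = 0, p = 1.
#'
#' @param values numeric vector
#' @param groups group labels
#' @return list with \code{H} and \code{p}
#' @export
kruskalWallis <- function(values, groups) {
    groups <- as.factor(groups)
    if (any(table(groups) == 0)) stop("empty group")
    if (length(unique(values)) == 1) return(list(H = 0, p = 1))
    kt <- stats::kruskal.test(values, groups)
    list(H = unname(kt$statistic), p = kt$p.value)
}

#' Dunn's post hoc pairwise comparisons
#'
#' Pairwise z statistics from rank means with the standard tie-corrected
#' variance, two-sided normal p-values, adjusted across pairs.
#'
#' @param values numeric vector
#' @param groups group labels
#' @param adjust p-adjustment method (default \code{"BH"})
#' @return data.frame with columns \code{groupA}, \code{groupB}, \code{z},
#'   \code{p}, \code{pAdjusted}
#' @references Dunn (1964) Technometrics 6:241-252.
#' @export
dunnPosthoc <- function(values, groups, adjust = "BH") {
    groups <- as.factor(groups)
    if (any(table(groups) == 0)) stop("empty group")
    N <- length(values)
    r <- rank(values, ties.method = "average")
    rbar <- tapply(r, groups, mean)
    ns <- tapply(r, groups, length)
    ties <- table(values)
    tieCorr <- sum(ties^3 - ties) / (12 * (N - 1))
    lv <- levels(groups)
    pairs <- utils::combn(lv, 2)
    z <- apply(pairs, 2, function(ab) {
        a <- ab[1]; b <- ab[2]
        se <- sqrt((N * (N + 1) / 12 - tieCorr) * (1 / ns[a] + 1 / ns[b]))
        (rbar[a] - rbar[b]) / se
    })
    p <- 2 * stats::pnorm(-abs(z))
    data.frame(groupA = pairs[1, ], groupB = pairs[2, ], z = as.numeric(z),
               p = p, pAdjusted = stats::p.adjust(p, method = adjust),
               stringsAsFactors = FALSE)
}

#' Fisher exact mutation enrichment in a focus cluster
#'
#' Per binary feature, builds the 2x2 table of (in-focus mutated, in-focus
#' wild-type, out-of-focus mutated, out-of-focus wild-type) and computes the
#' conventional two-sided Fisher exact p (sum of hypergeometric table
#' probabilities at most that of the observed table). Features constant
#' across all samples get p = 1 and are retained with a note.
#'
#' @param binaryMatrix 0/1 feature x sample matrix
#' @param labels per-sample cluster labels (aligned with columns)
#' @param focus the cluster id tested for enrichment
#' @param pMax keep features with p < pMax (strict; default 0.01). Use
#'   \code{pMax = Inf} to keep everything.
#' @return data.frame with the table counts \code{a}, \code{b}, \code{c},
#'   \code{d}, \code{oddsRatio} (sample odds ratio), \code{p},
#'   \code{enrichedInFocus} (odds ratio > 1) and \code{note}
#' @export
fisherEnrichment <- function(binaryMatrix, labels, focus, pMax = 0.01) {
    if (ncol(binaryMatrix) != length(labels))
        stop("labels must align with the sample columns")
    inFocus <- labels == focus
    if (!any(inFocus)) stop("focus cluster has no samples")
    rows <- lapply(rownames(binaryMatrix), function(f) {
        m <- binaryMatrix[f, ]
        a <- sum(m == 1 & inFocus); b <- sum(m == 0 & inFocus)
        cc <- sum(m == 1 & !inFocus); d <- sum(m == 0 & !inFocus)
        constant <- (a + cc == 0) || (b + d == 0)
        p <- if (constant) 1 else
            stats::fisher.test(matrix(c(a, b, cc, d), 2, byrow = TRUE))$p.value
        or <- (a * d) / (b * cc)
        data.frame(feature = f, a = a, b = b, c = cc, d = d, oddsRatio = or,
                   p = p, enrichedInFocus = is.finite(or) && or > 1 ||
                       (b == 0 && a > 0),
                   note = if (constant) "constant feature" else "",
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    out[out$p < pMax | out$note != "", , drop = FALSE]
}

#' One-way ANOVA effect-size screen
#'
#' Per feature, the one-way ANOVA F statistic and p-value across groups,
#' plus an effect size: Cohen's f (default, \code{sqrt(eta2 / (1 - eta2))}),
#' eta-squared, or the maximum pairwise Cohen's d. Selection uses strict
#' thresholds: effect size > \code{esMin} and (if \code{pMax} is finite)
#' p < \code{pMax}. Features with zero within-group variance but distinct
#' means have infinite effect size and are flagged.
#'
#' @param valuesMatrix feature x sample matrix (expression or activity)
#' @param labels per-sample group labels (>= 2 groups)
#' @param esMin effect-size threshold (default 0.5)
#' @param pMax p-value threshold; \code{Inf} disables the p criterion
#' @param esType \code{"cohen_f"}, \code{"eta2"} or \code{"max_d"}
#' @return data.frame with \code{feature}, \code{F}, \code{p},
#'   \code{effectSize}, \code{selected}, \code{flagged}
#' @export
anovaEffectScreen <- function(valuesMatrix, labels, esMin = 0.5, pMax = Inf,
                              esType = c("cohen_f", "eta2", "max_d")) {
    esType <- match.arg(esType)
    labels <- as.factor(labels)
    if (nlevels(labels) < 2) stop("need >= 2 groups")
    ns <- table(labels)
    N <- length(labels)
    k <- nlevels(labels)
    G <- stats::model.matrix(~ labels - 1)
    gm <- valuesMatrix %*% G %*% diag(1 / as.numeric(ns))  # group means
    colnames(gm) <- levels(labels)
    grand <- rowMeans(valuesMatrix)
    ssB <- as.numeric((gm - grand)^2 %*% as.numeric(ns))
    ssT <- rowSums((valuesMatrix - grand)^2)
    ssW <- pmax(ssT - ssB, 0)
    Fstat <- (ssB / (k - 1)) / (ssW / (N - k))
    p <- stats::pf(Fstat, k - 1, N - k, lower.tail = FALSE)
    eta2 <- ifelse(ssT > 0, ssB / ssT, 0)
    es <- switch(esType,
        eta2 = eta2,
        cohen_f = sqrt(eta2 / pmax(1 - eta2, .Machine$double.eps)),
        max_d = {
            sdPool <- sqrt(ssW / (N - k))
            apply(gm, 1, function(m) diff(range(m))) / sdPool
        })
    flagged <- ssW == 0 & ssB > 0
    es[flagged] <- Inf
    selected <- es > esMin & (!is.finite(pMax) | p < pMax)
    selected[is.na(selected)] <- FALSE
    data.frame(feature = rownames(valuesMatrix), F = Fstat, p = p,
               effectSize = es, selected = selected, flagged = flagged,
               row.names = NULL, stringsAsFactors = FALSE)
}
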