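# Two-group differential expression on counts and the consistency-based
# preselection of classifier gene candidates.

#' Two-group differential expression on CPM
#'
#' \code{log2FC = log2((meanCPM_B + pseudo) / (meanCPM_A + pseudo))}; the
#' default p-value is a two-sided Welch t-test on \code{log2(CPM + pseudo)}
#' per feature, with BH adjustment. This is a deliberately simple moderated-
#' free test: differential expression is used downstream only to rank genes
#' and pre-filter classifier candidates, and the Welch test has a
#' well-calibrated type-I error on negative binomial counts at the group
#' sizes involved. \code{method = "nb"} instead takes p-values from the
#' negative binomial exact test (edgeR's classic pipeline, quantile-adjusted
#' conditional likelihood dispersion), for users wanting a count-model test;
#' the fold-change definition is unchanged.
#'
#' @param counts integer count matrix (all samples)
#' @param samplesA,samplesB disjoint non-empty sample id vectors; each group
#'   needs >= 2 samples
#' @param pseudo pseudo-count on the CPM scale (default 1)
#' @param method \code{"welch"} (default) or \code{"nb"} (requires edgeR)
#' @return data.frame with columns \code{feature}, \code{log2FC}, \code{p},
#'   \code{q}
#' @export
differentialExpression <- function(counts, samplesA, samplesB, pseudo = 1,
                                   method = c("welch", "nb")) {
    method <- match.arg(method)
    if (!length(samplesA) || !length(samplesB)) stop("empty group")
    if (length(intersect(samplesA, samplesB))) stop("groups must be disjoint")
    if (length(samplesA) < 2 || length(samplesB) < 2)
        stop("each group needs >= 2 samples (variance undefined otherwise)")
    cpm <- cpmNormalize(counts[, c(samplesA, samplesB), drop = FALSE])
    A <- log2(cpm[, samplesA, drop = FALSE] + pseudo)
    B <- log2(cpm[, samplesB, drop = FALSE] + pseudo)
    log2FC <- log2(rowMeans(cpm[, samplesB, drop = FALSE]) + pseudo) -
        log2(rowMeans(cpm[, samplesA, drop = FALSE]) + pseudo)
    if (method == "welch") {
        nA <- ncol(A); nB <- ncol(B)
        vA <- matrixStats::rowVars(A); vB <- matrixStats::rowVars(B)
        se2 <- vA / nA + vB / nB
        tstat <- (rowMeans(B) - rowMeans(A)) / sqrt(se2)
        df <- se2^2 / ((vA / nA)^2 / (nA - 1) + (vB / nB)^2 / (nB - 1))
        p <- 2 * stats::pt(-abs(tstat), df = df)
        p[se2 == 0] <- 1    # constant feature in both groups
    } else {
        if (!requireNamespace("edgeR", quietly = TRUE))
            stop("method = 'nb' requires the edgeR package")
        grp <- factor(rep(c("A", "B"), c(length(samplesA), length(samplesB))))
        y <- edgeR::DGEList(counts = counts[, c(samplesA, samplesB)],
                            group = grp)
        y <- edgeR::estimateDisp(y)
        p <- edgeR::exactTest(y, pair = c("A", "B"))$table$PValue
    }
    data.frame(feature = rownames(counts), log2FC = log2FC, p = p,
               q = stats::p.adjust(p, method = "BH"),
               row.names = NULL, stringsAsFactors = FALSE)
}

#' Rank features by log2 fold change
#'
#' Descending by \code{log2FC}; ties broken lexicographically by feature id
#' so the ranking is deterministic.
#'
#' @param deg a table from [differentialExpression()]
#' @return named numeric vector of scores, ordered for [gseaPreranked()]
#' @export
rankByLogFC <- function(deg) {
    o <- order(-deg$log2FC, deg$feature)
    stats::setNames(deg$log2FC[o], deg$feature[o])
}

#' Consistently monotone differentially expressed genes
#'
#' Classifier candidate preselection: genes upregulated (fold change
#' > \code{upFc} and q < \code{qMax}) or downregulated (fold change
#' < \code{downFc} and q < \code{qMax}) in BOTH supplied comparisons
#' (cluster 3 vs 2 and cluster 2 vs 1), i.e. genes changing monotonically
#' across the three clusters. Thresholds are on the natural fold-change
#' scale and strict.
#'
#' @param deg32,deg21 tables from [differentialExpression()] over the same
#'   feature universe
#' @param upFc,downFc fold-change thresholds (defaults 1.5 and 0.7)
#' @param qMax FDR threshold (default 1e-4)
#' @return list with character vectors \code{up} and \code{down}
#' @export
consistentDegSelection <- function(deg32, deg21, upFc = 1.5, downFc = 0.7,
                                   qMax = 1e-4) {
    if (!identical(sort(deg32$feature), sort(deg21$feature)))
        stop("the two tables must cover the same feature universe")
    deg21 <- deg21[match(deg32$feature, deg21$feature), ]
    upLog <- log2(upFc); downLog <- log2(downFc)
    up <- deg32$feature[deg32$log2FC > upLog & deg32$q < qMax &
                        deg21$log2FC > upLog & deg21$q < qMax]
    down <- deg32$feature[deg32$log2FC < downLog & deg32$q < qMax &
                          deg21$log2FC < downLog & deg21$q < qMax]
    list(up = up, down = down)
}
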