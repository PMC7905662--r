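# Rank-based per-sample scoring: ssGSEA (glycolysis and immune infiltration
# scores), aREA transcription-factor activity, and the relative
# concentration index for subcellular localization. All scores depend on
# expression only through within-sample ranks, so they are invariant under
# any strictly monotone transform of a sample's values (CPM vs log CPM is
# immaterial).

#' Single-sample GSEA enrichment score
#'
#' Per sample, features are ranked by expression (descending; ties receive
#' average ranks) and the score is the integrated difference between the
#' weighted empirical CDF of in-set features (weights \code{rank^alpha})
#' and the unweighted empirical CDF of out-of-set features, summed over the
#' whole ranked list. With \code{normalize = TRUE} (the convention of the
#' single-sample GSEA ecosystem) all scores of the call are divided by the
#' range (max - min) of the scores, which makes them comparable across
#' samples of one cohort but not across independently normalized cohorts.
#'
#' @param expr expression matrix (CPM or log2 CPM; samples in columns).
#'   Scores are rank-based, so the scale does not matter.
#' @param geneSet character vector of feature ids
#' @param weightExponent rank-weighting exponent alpha (default 0.25; 0.75
#'   recovers the original single-sample GSEA weighting)
#' @param normalize divide scores by their overall range (default TRUE)
#' @return named numeric vector, one score per sample
#' @references Barbie et al. (2009) Nature 462:108-112 (single-sample GSEA);
#'   Hanzelmann, Castelo & Guinney (2013) BMC Bioinformatics 14:7.
#' @export
ssgseaScore <- function(expr, geneSet, weightExponent = 0.25,
                        normalize = TRUE) {
    universe <- rownames(expr)
    inSet <- universe %in% geneSet
    m <- sum(inSet)
    if (m < 2) stop("gene set has fewer than 2 members in the expression universe")
    if (m == length(universe)) stop("gene set equals the universe (empty complement)")
    scores <- apply(expr, 2, function(x) .ssgseaOne(x, inSet, weightExponent))
    names(scores) <- colnames(expr)
    if (normalize) {
        rng <- diff(range(scores))
        if (rng > 0) scores <- scores / rng
    }
    scores
}

#' @noRd
.ssgseaOne <- function(x, inSet, alpha) {
    n <- length(x)
    r <- rank(x, ties.method = "average")
    ord <- order(x, decreasing = TRUE)     # deterministic: ties by index
    hit <- inSet[ord]
    w <- ifelse(hit, r[ord]^alpha, 0)
    pIn <- cumsum(w) / sum(w)
    pOut <- cumsum(!hit) / (n - sum(inSet))
    sum(pIn - pOut)
}

#' Immune cell infiltration scores
#'
#' One ssGSEA score per immune cell type, computed from its marker gene set
#' with shared settings; range normalization (when requested) is applied
#' jointly across the whole cell-type-by-sample score matrix so cell types
#' remain comparable.
#'
#' @param expr expression matrix (samples in columns)
#' @param markerSets named list of marker gene sets (one per cell type)
#' @inheritParams ssgseaScore
#' @return numeric matrix, cell types in rows, samples in columns
#' @export
immuneInfiltrationScores <- function(expr, markerSets, weightExponent = 0.25,
                                     normalize = TRUE) {
    if (!length(markerSets))
        return(matrix(numeric(0), 0, ncol(expr),
                      dimnames = list(NULL, colnames(expr))))
    rows <- lapply(names(markerSets), function(ct) {
        tryCatch(ssgseaScore(expr, markerSets[[ct]],
                             weightExponent = weightExponent,
                             normalize = FALSE),
                 error = function(e) stop("cell type '", ct, "': ",
                                          conditionMessage(e), call. = FALSE))
    })
    out <- do.call(rbind, rows)
    rownames(out) <- names(markerSets)
    if (normalize) {
        rng <- diff(range(out))
        if (rng > 0) out <- out / rng
    }
    out
}

#' aREA transcription-factor activity scores
#'
#' Analytic rank-based enrichment: within each sample, feature ranks are
#' mapped to standard-normal quantiles \code{qnorm(rank/(n+1))}; the
#' activity of a regulon with m targets is the mode-signed sum of its
#' targets' quantiles divided by \code{sqrt(m)} - approximately standard
#' normal under the null of exchangeable ranks. One-tailed, mode weights
#' only (no interaction-confidence weighting).
#'
#' @param expr expression matrix (samples in columns)
#' @param regulons data.frame with columns \code{tf}, \code{target},
#'   \code{mode} (+1/-1), as from [readRegulons()] or [generateRegulons()]
#' @param minTargets regulons with fewer present targets are skipped with a
#'   warning (default 5)
#' @return numeric matrix, TFs in rows, samples in columns
#' @references Alvarez et al. (2016) Nature Genetics 48:838-847 (VIPER/aREA).
#' @export
areaTFActivity <- function(expr, regulons, minTargets = 5) {
    n <- nrow(expr)
    q <- apply(expr, 2, function(x) stats::qnorm(rank(x, ties.method = "average") / (n + 1)))
    rownames(q) <- rownames(expr)
    tfs <- unique(regulons$tf)
    rows <- list()
    for (tf in tfs) {
        sub <- regulons[regulons$tf == tf & regulons$target %in% rownames(expr), ]
        if (nrow(sub) < minTargets) {
            warning("regulon '", tf, "' has < ", minTargets,
                    " present targets; skipped")
            next
        }
        rows[[tf]] <- colSums(q[sub$target, , drop = FALSE] * sub$mode) /
            sqrt(nrow(sub))
    }
    out <- do.call(rbind, rows)
    if (is.null(out)) out <- matrix(numeric(0), 0, ncol(expr))
    colnames(out) <- colnames(expr)
    out
}

#' Relative concentration index (RCI)
#'
#' Log2 ratio of a transcript's mean cytoplasmic to mean nuclear
#' concentration per unit mass of RNA (CPM), with a pseudo-count keeping the
#' index finite for compartment-absent transcripts. Positive values indicate
#' cytoplasmic bias, negative values nuclear bias.
#'
#' @param cyt,nuc CPM matrices (features x samples) for the cytoplasmic and
#'   nuclear compartments; must share the feature axis
#' @param pseudo pseudo-count in CPM units (default 1)
#' @return named numeric vector, one RCI per feature
#' @export
rci <- function(cyt, nuc, pseudo = 1) {
    if (is.null(dim(cyt))) cyt <- matrix(cyt, dimnames = list(names(cyt), NULL))
    if (is.null(dim(nuc))) nuc <- matrix(nuc, dimnames = list(names(nuc), NULL))
    if (!identical(rownames(cyt), rownames(nuc)))
        stop("cytoplasmic and nuclear matrices must share features")
    mc <- rowMeans(cyt)
    mn <- rowMeans(nuc)
    log2((mc + pseudo) / (mn + pseudo))
}
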