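# Preranked GSEA with a gene-label permutation null, sign-matched NES and
# the sign-stratified NES-ratio FDR of the original GSEA method.

# Running-sum maximum-deviation enrichment score, O(m) given the sorted
# in-set positions. Hits increment by |score|^weight normalized over the
# in-set total; misses decrement uniformly. Returns the running-sum value
# of largest magnitude (ties broken toward the positive extremum).
#' @noRd
.gseaES <- function(absw, positions, nTotal) {
    m <- length(positions)
    w <- absw[positions]
    W <- sum(w)
    hitCum <- if (W > 0) cumsum(w) / W else seq_len(m) / m
    missRate <- 1 / (nTotal - m)
    idx <- seq_len(m)
    peaks <- hitCum - (positions - idx) * missRate            # just after hit i
    troughs <- c(0, utils::head(hitCum, -1)) -
        (positions - idx) * missRate                          # just before hit i
    hi <- max(peaks)
    lo <- min(troughs, 0)
    if (hi >= -lo) hi else lo
}

#' Preranked gene set enrichment analysis
#'
#' Computes the weighted Kolmogorov-Smirnov-like running-sum enrichment
#' score (ES) for each gene set on a ranked list, a gene-label permutation
#' null (set membership randomly re-drawn \code{nPerm} times), the
#' normalized enrichment score NES = ES / mean(|null ES| of matching sign),
#' a one-sided nominal p within sign, and FDR q-values by the
#' sign-stratified NES-ratio procedure: for a positive-NES set, q is the
#' fraction of pooled null NES at least as large, divided by the fraction
#' of observed NES at least as large (and symmetrically for negative NES),
#' clipped to [0, 1].
#'
#' @param rankedScores named numeric vector of per-gene scores (e.g. from
#'   [rankByLogFC()]); re-sorted descending internally with deterministic
#'   name tie-breaks
#' @param geneSets named list of gene sets; sets with fewer than 2 members
#'   in the ranked universe are skipped with a warning
#' @param weight exponent on |score| for hit increments (default 1, the
#'   classic weighted statistic; 0 gives the unweighted KS statistic)
#' @param nPerm permutations (default 10000)
#' @param seed RNG seed; identical seeds give identical p and q
#' @return data.frame with columns \code{set}, \code{size}, \code{ES},
#'   \code{NES}, \code{p}, \code{q}, \code{nPerm}
#' @references Subramanian et al. (2005) PNAS 102:15545-15550.
#' @export
gseaPreranked <- function(rankedScores, geneSets, weight = 1, nPerm = 10000,
                          seed = 1) {
    o <- order(-rankedScores, names(rankedScores))
    s <- rankedScores[o]
    universe <- names(s)
    N <- length(s)
    absw <- abs(s)^weight
    keep <- vapply(geneSets, function(gs) sum(universe %in% gs) >= 2,
                   logical(1))
    if (any(!keep))
        warning("skipped set(s) with < 2 members in the universe: ",
                paste(names(geneSets)[!keep], collapse = ", "))
    geneSets <- geneSets[keep]
    if (!length(geneSets))
        return(data.frame(set = character(0), size = integer(0),
                          ES = numeric(0), NES = numeric(0), p = numeric(0),
                          q = numeric(0), nPerm = integer(0)))
    res <- lapply(seq_along(geneSets), function(i) {
        pos <- sort(which(universe %in% geneSets[[i]]))
        m <- length(pos)
        es <- .gseaES(absw, pos, N)
        null <- withSeed(deriveSeed(seed, i), {
            vapply(seq_len(nPerm), function(b)
                .gseaES(absw, sort(sample.int(N, m)), N), numeric(1))
        })
        sameSign <- if (es >= 0) null >= 0 else null < 0
        nSame <- sum(sameSign)
        meanAbs <- if (nSame > 0) mean(abs(null[sameSign])) else NA_real_
        nes <- if (!is.na(meanAbs) && meanAbs > 0) es / meanAbs else NA_real_
        p <- (1 + sum(sameSign & abs(null) >= abs(es))) / (1 + nSame)
        nullNES <- if (!is.na(meanAbs) && meanAbs > 0)
            null[sameSign] / meanAbs else numeric(0)
        list(set = names(geneSets)[i], size = m, ES = es, NES = nes, p = p,
             nullNES = nullNES)
    })
    obsNES <- vapply(res, function(r) r$NES, numeric(1))
    nullPos <- unlist(lapply(res, function(r) r$nullNES[r$nullNES >= 0]))
    nullNeg <- unlist(lapply(res, function(r) r$nullNES[r$nullNES < 0]))
    q <- vapply(seq_along(res), function(i) {
        nes <- obsNES[i]
        if (is.na(nes)) return(NA_real_)
        if (nes >= 0) {
            nullFrac <- if (length(nullPos)) mean(nullPos >= nes) else 0
            obsFrac <- mean(obsNES >= nes, na.rm = TRUE)
        } else {
            nullFrac <- if (length(nullNeg)) mean(nullNeg <= nes) else 0
            obsFrac <- mean(obsNES <= nes, na.rm = TRUE)
        }
        min(1, nullFrac / max(obsFrac, .Machine$double.eps))
    }, numeric(1))
    data.frame(set = vapply(res, `[[`, character(1), "set"),
               size = vapply(res, `[[`, integer(1), "size"),
               ES = vapply(res, `[[`, numeric(1), "ES"),
               NES = obsNES, p = vapply(res, `[[`, numeric(1), "p"), q = q,
               nPerm = nPerm, row.names = NULL, stringsAsFactors = FALSE)
}
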