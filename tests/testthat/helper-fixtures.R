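# Shared fixtures and small independent oracles used across the suite.

# Adjusted Rand index (independent of any package code)
adjustedRand <- function(a, b) {
    t <- table(a, b)
    n <- sum(t)
    si <- sum(choose(rowSums(t), 2))
    sj <- sum(choose(colSums(t), 2))
    sij <- sum(choose(t, 2))
    e <- si * sj / choose(n, 2)
    (sij - e) / ((si + sj) / 2 - e)
}

# A small default cohort most tests can share
smallConfig <- function(seed = 1, ...) {
    args <- utils::modifyList(
        list(nSamples = 60, nCodingGenes = 400L, nLncRNAs = 60L,
             nPosLnc = 8L, nNegLnc = 8L, nMutationFeatures = 10L,
             nTFs = 10L, nImmuneSets = 3L, seed = seed),
        list(...))
    do.call(cohortConfig, args)
}

# Brute-force running-sum GSEA enrichment score (independent oracle).
# Same tie rule as the implementation: when the positive and negative
# extrema tie in magnitude, the positive one wins; floating-point ties
# within 1e-9 are treated as ties.
bruteGseaES <- function(sortedScores, hit, weight) {
    inc <- ifelse(hit, abs(sortedScores)^weight, 0)
    inc <- inc / sum(inc)
    dec <- ifelse(hit, 0, 1 / sum(!hit))
    rs <- cumsum(inc - dec)
    hi <- max(rs, 0)
    lo <- min(rs, 0)
    if (hi >= -lo - 1e-9) hi else lo
}

# Exhaustive two-sided Fisher p by hypergeometric enumeration
bruteFisherP <- function(a, b, c, d) {
    m <- a + b
    n <- c + d
    k <- a + c
    lo <- max(0, k - n)
    hi <- min(k, m)
    probs <- stats::dhyper(lo:hi, m, n, k)
    pObs <- stats::dhyper(a, m, n, k)
    sum(probs[probs <= pObs * (1 + 1e-7)])
}

# Step-up BH by the literal definition (independent of p.adjust)
bruteBH <- function(p) {
    n <- length(p)
    o <- order(p)
    q <- p[o] * n / seq_len(n)
    q <- rev(cummin(rev(q)))
    pmin(1, q)[order(o)]
}
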