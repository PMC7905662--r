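# CPM normalization and the expression filter applied before any scoring.

#' Counts-per-million normalization
#'
#' \code{value = count / library_size * 1e6} per sample. The returned matrix
#' carries a \code{"scale"} attribute (\code{"cpm"}) so downstream scorers
#' can check what they were given.
#'
#' @param counts non-negative integer matrix, samples in columns
#' @return numeric matrix of CPM values, \code{attr(, "scale") == "cpm"}
#' @export
cpmNormalize <- function(counts) {
    lib <- colSums(counts)
    if (any(lib == 0))
        stop("sample(s) with zero library size: ",
             paste(colnames(counts)[lib == 0], collapse = ", "))
    out <- sweep(counts, 2, lib, "/") * 1e6
    attr(out, "scale") <- "cpm"
    out
}

#' log2(CPM + 1) transform
#'
#' @param cpm a CPM matrix (from [cpmNormalize()])
#' @param pseudo pseudo-count added before the log
#' @return numeric matrix, \code{attr(, "scale") == "log2cpm"}
#' @export
log2cpm <- function(cpm, pseudo = 1) {
    out <- log2(cpm + pseudo)
    attr(out, "scale") <- "log2cpm"
    out
}

#' Expression filter: detectably expressed features
#'
#' A feature is retained iff its count exceeds \code{minCount} (strictly) in
#' strictly more than \code{minFraction} of the samples. The same rule is
#' applied to lncRNAs and to glycolysis-set genes before scoring.
#'
#' @param counts integer count matrix
#' @param minCount count threshold (default 10, strict \code{>})
#' @param minFraction sample fraction threshold (default 0.9, strict
#'   \code{>})
#' @return character vector of retained feature ids
#' @export
expressionFilter <- function(counts, minCount = 10, minFraction = 0.9) {
    if (!nrow(counts) || !ncol(counts)) stop("empty count matrix")
    if (minCount <= 0 || minFraction < 0)
        stop("thresholds must be positive (minCount) and non-negative (minFraction)")
    frac <- rowMeans(counts > minCount)
    rownames(counts)[frac > minFraction]
}
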