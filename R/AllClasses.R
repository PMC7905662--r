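#' @import methods
#' @importFrom S4Vectors DataFrame metadata
#' @import SummarizedExperiment
NULL

#' GlycoCohort: a cohort bundle for glycolysis-lncRNA stratification
#'
#' Extends \link[SummarizedExperiment]{SummarizedExperiment} with the
#' auxiliary per-sample data the stratification pipeline consumes. The
#' \code{"counts"} assay holds raw integer counts for coding genes and
#' lncRNAs together; \code{rowData(x)$featureClass} labels each feature
#' \code{"coding"} or \code{"lncRNA"}; \code{colData} carries the clinical
#' survival table (\code{time} in days, \code{event} in \{0,1\}). Mutation,
#' copy-number and methylation matrices live on their own feature axes but
#' must share the sample axis with the counts.
#'
#' For synthetic cohorts the \code{truth} slot records the planted ground
#' truth (cluster labels, latent glycolytic activity, planted lncRNAs with
#' signed target correlations, the enriched mutation feature and the active
#' regulators), so downstream stages can be tested for parameter recovery.
#'
#' @slot mutations binary feature x sample integer matrix of nonsilent
#'   mutation calls (1 = mutated).
#' @slot cnv real feature x sample matrix of copy-number scores.
#' @slot methylation real feature x sample matrix of beta values in [0, 1].
#' @slot geneSets named list of character vectors (gene set collection);
#'   includes the glycolysis set plus decoy, immune-marker and checkpoint
#'   sets for synthetic cohorts.
#' @slot regulons data.frame with columns \code{tf}, \code{target},
#'   \code{mode} (+1/-1).
#' @slot truth list of planted ground truth (may be empty for real data).
#'
#' @seealso [generateCohort()] which constructs synthetic cohorts,
#'   [runPipeline()] which consumes them.
#' @export
setClass("GlycoCohort",
    contains = "SummarizedExperiment",
    representation(
        mutations   = "matrix",
        cnv         = "matrix",
        methylation = "matrix",
        geneSets    = "list",
        regulons    = "data.frame",
        truth       = "list"
    ),
    prototype(
        mutations   = matrix(integer(0), 0, 0),
        cnv         = matrix(numeric(0), 0, 0),
        methylation = matrix(numeric(0), 0, 0),
        geneSets    = list(),
        regulons    = data.frame(tf = character(0), target = character(0),
                                 mode = integer(0)),
        truth       = list()
    )
)

setValidity("GlycoCohort", function(object) {
    msg <- character(0)
    cn <- colnames(object)
    if (!"counts" %in% assayNames(object))
        msg <- c(msg, "assay 'counts' is required")
    else {
        cts <- assay(object, "counts")
        if (any(cts < 0) || any(cts != round(cts)))
            msg <- c(msg, "counts must be non-negative integers")
    }
    if (is.null(rowData(object)$featureClass))
        msg <- c(msg, "rowData must contain 'featureClass'")
    else if (!all(rowData(object)$featureClass %in% c("coding", "lncRNA")))
        msg <- c(msg, "featureClass values must be 'coding' or 'lncRNA'")
    for (nm in c("mutations", "cnv", "methylation")) {
        m <- slot(object, nm)
        if (ncol(m) > 0 && !identical(colnames(m), cn))
            msg <- c(msg, sprintf("'%s' samples do not match counts samples", nm))
    }
    if (ncol(object@methylation) > 0) {
        b <- object@methylation[!is.na(object@methylation)]
        if (length(b) && (min(b) < 0 || max(b) > 1))
            msg <- c(msg, "methylation beta values must lie in [0, 1]")
    }
    if (ncol(object@mutations) > 0 &&
        !all(object@mutations %in% c(0L, 1L)))
        msg <- c(msg, "mutation calls must be binary")
    if (length(object@geneSets) &&
        (is.null(names(object@geneSets)) || anyDuplicated(names(object@geneSets))))
        msg <- c(msg, "gene sets must have unique names")
    if (length(object@truth) && !is.null(object@truth$cluster)) {
        k <- object@truth$nClusters
        if (!is.null(k) && !all(object@truth$cluster %in% seq_len(k)))
            msg <- c(msg, "truth cluster labels must take values 1..nClusters")
    }
    if (length(msg)) msg else TRUE
})

#' ConsensusResult: consensus clustering output for one cluster count
#'
#' Holds the sample-by-sample consensus matrix (fraction of feature-resampled
#' iterations in which two samples were co-assigned by PAM), the final labels
#' from hierarchically clustering 1 - consensus, and the resampling settings.
#'
#' @slot k integer cluster count.
#' @slot consensusMatrix symmetric sample x sample matrix in [0, 1], unit
#'   diagonal.
#' @slot labels integer per-sample cluster label in 1..k.
#' @slot nIterations number of resampling iterations.
#' @slot featureFraction fraction of features drawn per iteration.
#' @export
setClass("ConsensusResult",
    representation(
        k               = "integer",
        consensusMatrix = "matrix",
        labels          = "integer",
        nIterations     = "integer",
        featureFraction = "numeric"
    )
)

setValidity("ConsensusResult", function(object) {
    msg <- character(0)
    cm <- object@consensusMatrix
    if (nrow(cm) != ncol(cm)) msg <- c(msg, "consensus matrix must be square")
    else {
        if (max(abs(cm - t(cm))) > 1e-12)
            msg <- c(msg, "consensus matrix must be symmetric")
        if (any(cm < -1e-12) || any(cm > 1 + 1e-12))
            msg <- c(msg, "consensus entries must lie in [0, 1]")
        if (any(abs(diag(cm) - 1) > 1e-12))
            msg <- c(msg, "consensus diagonal must equal 1")
    }
    if (length(object@labels) != nrow(cm))
        msg <- c(msg, "one label per sample required")
    if (!all(sort(unique(object@labels)) == seq_len(object@k)))
        msg <- c(msg, "labels must cover 1..k")
    if (length(msg)) msg else TRUE
})

#' GenomicClassifier: lasso multinomial cluster classifier
#'
#' A fitted L1-penalized multinomial logistic model that transfers cluster
#' labels to external expression data, together with the pooled quantile
#' reference used to project new samples onto the training distribution.
#'
#' @slot features character vector of model features (training universe).
#' @slot coefficients feature x class coefficient matrix at the chosen
#'   penalty.
#' @slot intercepts per-class intercepts.
#' @slot classes class labels (cluster ids as character).
#' @slot lambda penalty at which the model was refit.
#' @slot center,scale feature standardization applied before fitting.
#' @slot quantileReference mean sorted expression profile of the training
#'   data (numeric(0) when quantile normalization was not used).
#' @slot cvCurve data.frame with columns \code{lambda}, \code{cvm} (mean
#'   cross-validated multinomial deviance), \code{cvsd}, \code{nonzero}.
#' @export
setClass("GenomicClassifier",
    representation(
        features          = "character",
        coefficients      = "matrix",
        intercepts        = "numeric",
        classes           = "character",
        lambda            = "numeric",
        center            = "numeric",
        scale             = "numeric",
        quantileReference = "numeric",
        cvCurve           = "data.frame"
    )
)

setValidity("GenomicClassifier", function(object) {
    msg <- character(0)
    if (nrow(object@coefficients) != length(object@features))
        msg <- c(msg, "one coefficient row per feature required")
    if (ncol(object@coefficients) != length(object@classes))
        msg <- c(msg, "one coefficient column per class required")
    if (length(object@intercepts) != length(object@classes))
        msg <- c(msg, "one intercept per class required")
    if (length(msg)) msg else TRUE
})

#' @describeIn GlycoCohort compact display
#' @param object a \code{GlycoCohort}
#' @export
setMethod("show", "GlycoCohort", function(object) {
    callNextMethod()
    fc <- rowData(object)$featureClass
    cat(sprintf("features: %d coding, %d lncRNA\n",
                sum(fc == "coding"), sum(fc == "lncRNA")))
    cat(sprintf("mutations: %d features; cnv: %d; methylation: %d\n",
                nrow(object@mutations), nrow(object@cnv),
                nrow(object@methylation)))
    cat(sprintf("geneSets(%d): %s\n", length(object@geneSets),
                paste(utils::head(names(object@geneSets), 4), collapse = ", ")))
    if (length(object@truth))
        cat(sprintf("truth: planted, %d clusters\n", object@truth$nClusters))
})

#' @describeIn ConsensusResult compact display
#' @param object a \code{ConsensusResult}
#' @export
setMethod("show", "ConsensusResult", function(object) {
    cat(sprintf("ConsensusResult: k=%d, %d samples, %d iterations (feature fraction %.2f)\n",
                object@k, nrow(object@consensusMatrix), object@nIterations,
                object@featureFraction))
    cat("cluster sizes:", paste(tabulate(object@labels, object@k), collapse = " "), "\n")
})

#' @describeIn GenomicClassifier compact display
#' @param object a \code{GenomicClassifier}
#' @export
setMethod("show", "GenomicClassifier", function(object) {
    nz <- signatureFeatures(object)
    cat(sprintf("GenomicClassifier: %d classes, %d features (%d in signature), lambda=%.4g\n",
                length(object@classes), length(object@features), length(nz),
                object@lambda))
})

# ---- accessors ---------------------------------------------------------

#' Accessors for GlycoCohort slots
#'
#' @param x a \code{GlycoCohort}
#' @return \code{mutationCalls}: binary mutation matrix; \code{cnvScores},
#'   \code{methylationBetas}: covariate matrices; \code{geneSets}: named list
#'   of gene sets; \code{regulons}: tf/target/mode data.frame;
#'   \code{cohortTruth}: list of planted ground truth;
#'   \code{clinicalData}: data.frame with \code{sample}, \code{time},
#'   \code{event}; \code{featureClass}: per-feature class labels.
#' @name cohort-accessors
NULL

#' @rdname cohort-accessors
#' @export
mutationCalls <- function(x) x@mutations

#' @rdname cohort-accessors
#' @export
cnvScores <- function(x) x@cnv

#' @rdname cohort-accessors
#' @export
methylationBetas <- function(x) x@methylation

#' @rdname cohort-accessors
#' @export
geneSets <- function(x) x@geneSets

#' @rdname cohort-accessors
#' @export
regulons <- function(x) x@regulons

#' @rdname cohort-accessors
#' @export
cohortTruth <- function(x) x@truth

#' @rdname cohort-accessors
#' @export
featureClass <- function(x) {
    fc <- rowData(x)$featureClass
    names(fc) <- rownames(x)
    fc
}

#' @rdname cohort-accessors
#' @export
clinicalData <- function(x) {
    cd <- as.data.frame(colData(x))
    data.frame(sample = colnames(x), time = cd$time, event = cd$event,
               stringsAsFactors = FALSE)
}

#' Consensus-result accessors
#'
#' @param x a \code{ConsensusResult}
#' @return \code{consensusMatrix}: the sample co-assignment matrix;
#'   \code{consensusLabels}: named integer labels;
#'   \code{consensusCDF}: the empirical CDF of upper-triangle consensus
#'   values evaluated on a grid, as a two-column data.frame.
#' @name consensus-accessors
NULL

#' @rdname consensus-accessors
#' @export
consensusMatrix <- function(x) x@consensusMatrix

#' @rdname consensus-accessors
#' @export
consensusLabels <- function(x) {
    lab <- x@labels
    names(lab) <- rownames(x@consensusMatrix)
    lab
}

#' @rdname consensus-accessors
#' @param grid evaluation grid on [0, 1]
#' @export
consensusCDF <- function(x, grid = seq(0, 1, by = 0.01)) {
    v <- x@consensusMatrix[upper.tri(x@consensusMatrix)]
    data.frame(consensus = grid, cdf = stats::ecdf(v)(grid))
}

#' Features with a nonzero coefficient in any class
#'
#' @param x a \code{GenomicClassifier}
#' @return character vector, the classifier gene signature
#' @export
signatureFeatures <- function(x) {
    x@features[rowSums(abs(x@coefficients) > 1e-8) > 0]
}
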