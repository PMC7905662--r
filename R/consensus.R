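# Feature-resampled consensus clustering with PAM, model selection by the
# consensus-CDF delta-area rule, and Ward hierarchical grouping of immune
# infiltration scores.

#' Partitioning around medoids
#'
#' Thin wrapper over \code{cluster::pam} (BUILD + SWAP to convergence on a
#' precomputed distance matrix), returning medoid ids and 1..k labels. PAM
#' on a fixed distance matrix is deterministic; the \code{seed} argument is
#' accepted for interface symmetry with the resampling caller.
#'
#' @param dist a \code{dist} object or symmetric distance matrix with zero
#'   diagonal
#' @param k number of clusters, 2 <= k < n
#' @param seed unused (PAM is deterministic); kept for call-site symmetry
#' @return list with \code{medoids} (indices or names) and \code{labels}
#'   (integer vector in 1..k)
#' @export
pamCluster <- function(dist, k, seed = NULL) {
    if (!inherits(dist, "dist")) dist <- stats::as.dist(dist)
    n <- attr(dist, "Size")
    if (k >= n) stop("k must be smaller than the number of samples")
    if (k < 2) stop("k must be at least 2")
    fit <- cluster::pam(dist, k = k, diss = TRUE, do.swap = TRUE,
                        cluster.only = FALSE, keep.diss = FALSE)
    list(medoids = fit$id.med, labels = as.integer(fit$clustering))
}

#' Sample-sample distances on an expression submatrix
#'
#' Euclidean distances are computed in the subspace of the leading
#' principal components of the submatrix (rank-truncated distance): with a
#' modest number of informative features, the full-rank Euclidean distance
#' between a sample and a medoid is dominated by the medoid's own
#' measurement noise, and truncating to the leading components removes most
#' of it while keeping the co-expression structure the clustering is after.
#' @noRd
.sampleDist <- function(z, metric, nPCs = 10) {
    if (metric == "pearson") {
        stats::as.dist(1 - stats::cor(z))
    } else {
        if (nPCs > 0 && nPCs < min(dim(z))) {
            sc <- stats::prcomp(t(z), center = TRUE, scale. = FALSE)$x
            stats::dist(sc[, seq_len(nPCs), drop = FALSE])
        } else {
            stats::dist(t(z))
        }
    }
}

#' Feature-resampled consensus clustering
#'
#' For each candidate k, repeats PAM clustering \code{nIter} times, each
#' time on a random subset of \code{ceiling(featureFraction * nFeatures)}
#' features (drawn without replacement); all samples are present in every
#' iteration, so the consensus entry for a sample pair is simply its
#' co-assignment count divided by \code{nIter}. Final labels come from
#' average-linkage hierarchical clustering of \code{1 - consensus} cut at
#' k. Features are z-scored before distance computation so positively and
#' negatively correlated lncRNAs contribute symmetrically.
#'
#' The default sample-sample metric is Euclidean distance on the z-scored
#' features; \code{metric = "pearson"} (1 - Pearson correlation, the
#' convention of much of the consensus-clustering ecosystem) is selectable.
#' See the package vignette for why Euclidean is the default here: when the
#' clustered features all reflect a single latent activity axis, samples
#' with intermediate activity have profiles close to the origin and
#' correlation distance cannot group them, whereas Euclidean distance
#' separates the clusters along the axis.
#'
#' @param expr expression matrix restricted to the selected features
#'   (features x samples), typically log2 CPM
#' @param kRange consecutive candidate cluster counts, within [2, n - 1]
#' @param nIter resampling iterations (default 1000)
#' @param featureFraction fraction of features per iteration, in (0, 1]
#'   (default 0.95)
#' @param metric \code{"euclidean"} (default) or \code{"pearson"}
#' @param nPCs for the Euclidean metric, the number of leading principal
#'   components of the resampled submatrix in which distances are computed.
#'   The default \code{"auto"} uses k - 1 components (the subspace a
#'   k-group mean structure can occupy, as in spectral clustering); an
#'   integer fixes the count, and 0 uses the full feature space. See the
#'   vignette for the rationale of this rank truncation.
#' @param scaleFeatures z-score each feature first (default TRUE)
#' @param seed RNG seed for the feature resampling; identical seeds give
#'   bit-identical consensus matrices
#' @return named list of [ConsensusResult-class], one per k
#' @export
consensusCluster <- function(expr, kRange = 2:5, nIter = 1000,
                             featureFraction = 0.95,
                             metric = c("euclidean", "pearson"),
                             nPCs = "auto", scaleFeatures = TRUE, seed = 1) {
    metric <- match.arg(metric)
    if (nrow(expr) < 2) stop("need at least 2 features")
    n <- ncol(expr)
    if (any(kRange < 2) || any(kRange >= n))
        stop("kRange must lie within [2, n - 1]")
    if (featureFraction <= 0 || featureFraction > 1)
        stop("featureFraction must lie in (0, 1]")
    z <- if (scaleFeatures) {
        zs <- t(scale(t(expr)))
        zs[!is.finite(zs)] <- 0     # constant features carry no signal
        zs
    } else expr
    nSub <- ceiling(featureFraction * nrow(z))
    results <- list()
    for (k in kRange) {
        kPCs <- if (identical(nPCs, "auto")) k - 1L else as.integer(nPCs)
        consensus <- withSeed(deriveSeed(seed, k), {
            cm <- matrix(0, n, n)
            for (it in seq_len(nIter)) {
                keep <- sample.int(nrow(z), nSub)
                lab <- pamCluster(.sampleDist(z[keep, , drop = FALSE],
                                              metric, kPCs), k)$labels
                cm <- cm + outer(lab, lab, "==")
            }
            cm / nIter
        })
        dimnames(consensus) <- list(colnames(expr), colnames(expr))
        hc <- stats::hclust(stats::as.dist(1 - consensus), method = "average")
        labels <- as.integer(stats::cutree(hc, k = k))
        res <- new("ConsensusResult", k = as.integer(k),
                   consensusMatrix = consensus, labels = labels,
                   nIterations = as.integer(nIter),
                   featureFraction = featureFraction)
        validObject(res)
        results[[paste0("k", k)]] <- res
    }
    results
}

#' Consensus CDF area and delta-area model selection
#'
#' The area under the empirical CDF of the upper-triangle consensus values
#' is computed per k; the relative delta area is
#' \code{(A_k - A_{k-1}) / A_{k-1}} for k beyond the smallest, and
#' \code{A_kmin} for the smallest k. The suggested k is the largest k whose
#' relative delta area is at least \code{elbow} (i.e. the last k that still
#' buys an appreciable increase in consensus); when no k beyond the minimum
#' qualifies the minimum is suggested. The full delta table is always
#' returned - the suggestion is advisory, as the elbow is conventionally
#' judged by eye.
#'
#' @param results list of [ConsensusResult-class] for consecutive k (>= 3
#'   values)
#' @param elbow relative delta-area threshold for "no appreciable increase"
#'   (default 0.1)
#' @return list with \code{area} (named per-k CDF areas), \code{deltaArea}
#'   (named relative increases) and \code{suggestedK}
#' @export
consensusDeltaArea <- function(results, elbow = 0.1) {
    ks <- vapply(results, function(r) r@k, integer(1))
    o <- order(ks)
    ks <- ks[o]; results <- results[o]
    if (length(ks) < 3) stop("need results for at least 3 consecutive k")
    if (any(diff(ks) != 1)) stop("kRange must be consecutive")
    area <- vapply(results, function(r) {
        v <- sort(r@consensusMatrix[upper.tri(r@consensusMatrix)])
        cdf <- stats::ecdf(v)
        knots <- sort(unique(c(0, v, 1)))
        sum(diff(knots) * cdf(utils::head(knots, -1)))
    }, numeric(1))
    names(area) <- paste0("k", ks)
    delta <- c(area[1], diff(area) / utils::head(area, -1))
    names(delta) <- names(area)
    appreciable <- delta[-1] >= elbow
    suggestedK <- if (any(appreciable))
        ks[-1][max(which(appreciable))] else ks[1]
    list(area = area, deltaArea = delta, suggestedK = suggestedK)
}

#' Ward hierarchical grouping of immune infiltration scores
#'
#' Agglomerative clustering of samples with Euclidean distance and Ward's
#' linkage (\code{ward.D2}), tree cut at \code{nGroups}. The group with the
#' higher mean score is labeled \code{"high"} infiltration, the other(s)
#' \code{"low"} (for \code{nGroups = 2}).
#'
#' @param scores cell-type x sample score matrix
#' @param nGroups number of groups to cut (default 2)
#' @return list with \code{group} (integer labels), \code{infiltration}
#'   (character \code{"high"}/\code{"low"} labels when \code{nGroups == 2})
#'   and \code{groupMeans}
#' @export
hierarchicalWard <- function(scores, nGroups = 2) {
    if (ncol(scores) < 2) stop("need at least 2 samples")
    if (all(apply(scores, 1, stats::var) == 0))
        warning("constant score matrix; split is arbitrary but deterministic")
    hc <- stats::hclust(stats::dist(t(scores)), method = "ward.D2")
    group <- stats::cutree(hc, k = nGroups)
    gm <- tapply(colMeans(scores), group, mean)
    infiltration <- NULL
    if (nGroups == 2) {
        hi <- as.integer(names(gm)[which.max(gm)])
        infiltration <- ifelse(group == hi, "high", "low")
        names(infiltration) <- colnames(scores)
    }
    list(group = stats::setNames(as.integer(group), colnames(scores)),
         infiltration = infiltration, groupMeans = gm)
}
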