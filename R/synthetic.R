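# Synthetic cohort generator. Emulates the statistical structure of a bulk
# RNA-Seq tumor cohort scored for glycolytic activity: a per-sample latent
# glycolysis activity drawn per cluster, a glycolysis gene set whose
# log-expression scales with that activity, lncRNAs planted with positive
# and negative correlation to it, exponential survival with cluster-specific
# hazard, one mutation feature enriched in the high-activity cluster, and
# copy-number/methylation covariates partially confounded with expression.
# Counts are negative binomial on a per-gene log2-CPM mean scale with a
# shared dispersion and log-normal library sizes, so CPM normalization is
# non-trivial. Identical seeds give bit-identical bundles.

#' Run an expression with a private RNG state
#' @noRd
withSeed <- function(seed, expr) {
    if (exists(".Random.seed", envir = globalenv())) {
        old <- get(".Random.seed", envir = globalenv())
        on.exit(assign(".Random.seed", old, envir = globalenv()))
    } else {
        on.exit(if (exists(".Random.seed", envir = globalenv()))
            rm(".Random.seed", envir = globalenv()))
    }
    set.seed(seed)
    expr
}

#' Derive a per-component seed from the master seed (Lehmer step), kept
#' below 2^31 so it is a valid R integer seed.
#' @noRd
deriveSeed <- function(seed, k) {
    as.integer(((as.numeric(seed) %% 2147483647) * 48271 +
                as.numeric(k)) %% 2147483647)
}

#' Configuration for a synthetic cohort
#'
#' Bundles every knob of the synthetic generator with validated defaults.
#' The defaults define the reference study conditions used throughout the
#' test-suite: 150 samples in 3 equal clusters, latent glycolytic activity
#' Gaussian per cluster with means \code{clusterShift * (cluster - 2)} and
#' within-cluster standard deviation \code{withinClusterSd}, 40 planted
#' lncRNAs (20 positive, 20 negative) at target correlation 0.6 with the
#' latent activity, negative binomial counts at dispersion 0.1, per-cluster
#' hazard ratios (1, 1.5, 3) and one mutation feature at odds 8 in the
#' high-activity cluster.
#'
#' @param nSamples,nCodingGenes,nLncRNAs cohort dimensions
#' @param nClusters number of planted clusters
#' @param clusterProportions simplex vector of cluster sizes
#' @param glycolysisSetSize size of the planted glycolysis gene set
#' @param nPosLnc,nNegLnc numbers of lncRNAs planted with positive/negative
#'   correlation to the latent glycolysis activity
#' @param targetCorrelation target Pearson correlation (on log2 CPM) of the
#'   planted lncRNAs with the latent activity, in (0, 1)
#' @param clusterShift spacing of the latent activity cluster means (also
#'   the mean log2-expression shift of glycolysis genes across clusters, up
#'   to the \code{glycolysisLoading} factor)
#' @param withinClusterSd standard deviation of the latent activity within
#'   a cluster
#' @param glycolysisLoading log2-CPM change of a glycolysis gene per unit of
#'   latent activity
#' @param nbDispersion shared negative binomial dispersion (NB variance =
#'   mu + dispersion * mu^2)
#' @param survivalHazardRatios per-cluster hazard ratios (length
#'   \code{nClusters})
#' @param baselineHazard baseline exponential hazard per day
#' @param censoringRate expected fraction of administratively censored
#'   samples, in [0, 1)
#' @param mutationEnrichmentOdds odds multiplier of the designated mutation
#'   feature in the highest-activity cluster (>= 1)
#' @param nMutationFeatures,mutationBackgroundRate mutation matrix shape and
#'   background mutation probability
#' @param nDecoySets number of size-matched decoy gene sets
#' @param nImmuneSets,immuneSetSize immune marker blocks (disjoint)
#' @param immuneShift log2 up-shift of immune marker genes in the
#'   highest-activity cluster (a high-infiltration hot-tumor structure)
#' @param nCheckpointGenes,checkpointShift immune checkpoint gene block and
#'   its log2 up-shift in the highest-activity cluster
#' @param nTFs,targetsPerTF,nActiveTFs,tfEffect regulon structure: the first
#'   \code{nActiveTFs} TFs are active, i.e. their targets' log2 means move
#'   by \code{mode * tfEffect} per unit of latent activity
#' @param nCovariateGenes number of coding genes with planted copy-number
#'   and methylation covariates confounded with their expression
#' @param libSizeMeanLog,libSizeSdLog log-normal library size parameters
#' @param nCompartmentSamples paired cytoplasmic/nuclear libraries for the
#'   compartment generator
#' @param nuclearFraction fraction of lncRNAs that are nuclear-biased
#'   (expected relative concentration index < 0) in the compartment
#'   generator
#' @param seed master RNG seed (integer)
#' @return a validated list of class \code{"glycoCohortConfig"}
#' @seealso [generateCohort()], [nullCohortConfig()]
#' @export
cohortConfig <- function(nSamples = 150L,
                         nCodingGenes = 2000L,
                         nLncRNAs = 120L,
                         nClusters = 3L,
                         clusterProportions = rep(1 / nClusters, nClusters),
                         glycolysisSetSize = 50L,
                         nPosLnc = 20L,
                         nNegLnc = 20L,
                         targetCorrelation = 0.6,
                         clusterShift = 1.5,
                         withinClusterSd = 0.2,
                         glycolysisLoading = 0.4,
                         nbDispersion = 0.1,
                         survivalHazardRatios = c(1, 1.5, 3)[seq_len(nClusters)],
                         baselineHazard = log(2) / 1000,
                         censoringRate = 0.3,
                         mutationEnrichmentOdds = 8,
                         nMutationFeatures = 30L,
                         mutationBackgroundRate = 0.15,
                         nDecoySets = 5L,
                         nImmuneSets = 5L,
                         immuneSetSize = 10L,
                         immuneShift = 0.8,
                         nCheckpointGenes = 10L,
                         checkpointShift = 1,
                         nTFs = 40L,
                         targetsPerTF = 10L,
                         nActiveTFs = 4L,
                         tfEffect = 0.4,
                         nCovariateGenes = 40L,
                         libSizeMeanLog = log(1e6),
                         libSizeSdLog = 0.3,
                         nCompartmentSamples = 15L,
                         nuclearFraction = 0.7,
                         seed = 1L) {
    cfg <- as.list(environment())
    intPos <- c("nSamples", "nCodingGenes", "nLncRNAs", "nClusters",
                "glycolysisSetSize", "nMutationFeatures", "nTFs",
                "targetsPerTF", "nCompartmentSamples")
    for (f in intPos)
        if (length(cfg[[f]]) != 1 || is.na(cfg[[f]]) || cfg[[f]] < 1)
            stop("configuration error: '", f, "' must be a positive integer")
    if (abs(sum(clusterProportions) - 1) > 1e-9)
        stop("configuration error: clusterProportions must sum to 1")
    if (any(clusterProportions <= 0))
        stop("configuration error: clusterProportions must be positive")
    if (length(clusterProportions) != nClusters)
        stop("configuration error: one proportion per cluster required")
    if (nPosLnc + nNegLnc > nLncRNAs)
        stop("configuration error: nPosLnc + nNegLnc must be <= nLncRNAs")
    if (glycolysisSetSize > nCodingGenes)
        stop("configuration error: glycolysisSetSize must be <= nCodingGenes")
    if (targetCorrelation <= 0 || targetCorrelation >= 1)
        stop("configuration error: targetCorrelation must lie in (0, 1)")
    if (clusterShift < 0) stop("configuration error: clusterShift must be >= 0")
    if (nbDispersion <= 0) stop("configuration error: nbDispersion must be > 0")
    if (length(survivalHazardRatios) != nClusters ||
        any(survivalHazardRatios <= 0))
        stop("configuration error: one positive hazard ratio per cluster")
    if (censoringRate < 0 || censoringRate >= 1)
        stop("configuration error: censoringRate must lie in [0, 1)")
    if (mutationEnrichmentOdds < 1)
        stop("configuration error: mutationEnrichmentOdds must be >= 1")
    if (targetsPerTF < 5)
        stop("configuration error: regulons need >= 5 targets per TF")
    if (nuclearFraction < 0 || nuclearFraction > 1)
        stop("configuration error: nuclearFraction must lie in [0, 1]")
    nPlanted <- glycolysisSetSize + nImmuneSets * immuneSetSize +
        nCheckpointGenes + nTFs * targetsPerTF
    if (nPlanted > nCodingGenes)
        stop("configuration error: planted coding blocks (", nPlanted,
             ") exceed nCodingGenes")
    cfg$seed <- as.integer(seed)
    structure(cfg, class = "glycoCohortConfig")
}

#' Null study conditions: no planted structure
#'
#' All effect parameters at their neutral values (no cluster shift, equal
#' hazards, no planted lncRNA correlations, no mutation enrichment, inactive
#' regulators). Used for type-I-error and false-discovery calibration.
#'
#' @param ... overrides passed to [cohortConfig()]
#' @return a \code{"glycoCohortConfig"}
#' @export
nullCohortConfig <- function(...) {
    args <- utils::modifyList(
        list(clusterShift = 0, nPosLnc = 0L, nNegLnc = 0L,
             survivalHazardRatios = c(1, 1, 1), mutationEnrichmentOdds = 1,
             tfEffect = 0, immuneShift = 0, checkpointShift = 0),
        list(...))
    do.call(cohortConfig, args)
}

#' @export
print.glycoCohortConfig <- function(x, ...) {
    cat("glycoCohortConfig:", x$nSamples, "samples,", x$nCodingGenes,
        "coding genes,", x$nLncRNAs, "lncRNAs,", x$nClusters, "clusters\n")
    cat(sprintf("  planted lncRNAs: %d+/%d- at r=%.2f; clusterShift=%.2f; seed=%d\n",
                x$nPosLnc, x$nNegLnc, x$targetCorrelation, x$clusterShift,
                x$seed))
    invisible(x)
}

# Deterministic feature/sample naming and coding-gene block layout
#' @noRd
cohortLayout <- function(config) {
    pcg <- sprintf("PCG%04d", seq_len(config$nCodingGenes))
    lnc <- sprintf("LNC%04d", seq_len(config$nLncRNAs))
    i <- 0L
    take <- function(n) { out <- pcg[i + seq_len(n)]; i <<- i + n; out }
    glyco <- take(config$glycolysisSetSize)
    immune <- lapply(seq_len(config$nImmuneSets),
                     function(j) take(config$immuneSetSize))
    cellTypes <- c("T.cells.CD8", "T.cells.CD4", "NK.cells", "B.cells",
                   "Macrophages", "Dendritic.cells", "Neutrophils",
                   "Mast.cells")
    names(immune) <- if (config$nImmuneSets <= length(cellTypes))
        cellTypes[seq_len(config$nImmuneSets)]
    else sprintf("Immune%02d", seq_len(config$nImmuneSets))
    checkpoint <- take(config$nCheckpointGenes)
    tfTargets <- lapply(seq_len(config$nTFs),
                        function(j) take(config$targetsPerTF))
    names(tfTargets) <- sprintf("TF%02d", seq_len(config$nTFs))
    posLnc <- lnc[seq_len(config$nPosLnc)]
    negLnc <- lnc[config$nPosLnc + seq_len(config$nNegLnc)]
    list(pcg = pcg, lnc = lnc, samples = sprintf("S%04d", seq_len(config$nSamples)),
         glyco = glyco, immune = immune, checkpoint = checkpoint,
         tfTargets = tfTargets, posLnc = posLnc, negLnc = negLnc,
         mut = sprintf("MUT%03d", seq_len(config$nMutationFeatures)))
}

#' Generate the gene-set collection of a synthetic cohort
#'
#' Returns the planted \code{GLYCOLYSIS} set, \code{nDecoySets} size-matched
#' decoy sets drawn uniformly from the coding universe, the disjoint immune
#' marker blocks and the \code{CHECKPOINT} gene list. Deterministic given
#' the config seed, and identical to the collection embedded in
#' [generateCohort()] output for the same config.
#'
#' @param config a [cohortConfig()]
#' @return named list of character vectors
#' @export
generateGeneSets <- function(config) {
    stopifnot(inherits(config, "glycoCohortConfig"))
    lay <- cohortLayout(config)
    if (config$glycolysisSetSize > config$nCodingGenes)
        stop("requested set size exceeds universe")
    sets <- withSeed(deriveSeed(config$seed, 1L), {
        decoys <- lapply(seq_len(config$nDecoySets), function(j)
            sample(lay$pcg, config$glycolysisSetSize))
        names(decoys) <- sprintf("DECOY_%02d", seq_len(config$nDecoySets))
        decoys
    })
    c(list(GLYCOLYSIS = lay$glyco), sets, lay$immune,
      list(CHECKPOINT = lay$checkpoint))
}

#' Generate the regulon collection of a synthetic cohort
#'
#' Each TF has \code{targetsPerTF} coding targets with signed regulation
#' modes (+1 with probability 0.7). The first \code{nActiveTFs} TFs are
#' planted active: their targets' expression in [generateCohort()] moves by
#' \code{mode * tfEffect} per unit of latent glycolysis activity, so active
#' TFs score higher in the high-activity cluster.
#'
#' @param config a [cohortConfig()]
#' @return data.frame with columns \code{tf}, \code{target}, \code{mode};
#'   the active TF ids are attached as \code{attr(, "activeTFs")}
#' @export
generateRegulons <- function(config) {
    stopifnot(inherits(config, "glycoCohortConfig"))
    lay <- cohortLayout(config)
    modes <- withSeed(deriveSeed(config$seed, 2L),
        lapply(seq_len(config$nTFs), function(j)
            sample(c(1L, -1L), config$targetsPerTF, replace = TRUE,
                   prob = c(0.7, 0.3))))
    reg <- data.frame(
        tf = rep(names(lay$tfTargets), lengths(lay$tfTargets)),
        target = unlist(lay$tfTargets, use.names = FALSE),
        mode = unlist(modes),
        stringsAsFactors = FALSE)
    attr(reg, "activeTFs") <- names(lay$tfTargets)[seq_len(config$nActiveTFs)]
    reg
}

#' Generate a synthetic cohort with planted ground truth
#'
#' Draws per-sample latent glycolytic activity Gaussian per cluster (means
#' ordered by cluster index), builds a log2-CPM mean matrix in which
#' glycolysis genes, planted lncRNAs, active-TF targets and immune blocks
#' load on that activity (or on the high-activity cluster), and samples
#' negative binomial counts with log-normal library sizes. Survival times
#' are exponential with per-cluster hazard and administrative uniform
#' censoring; one designated mutation feature is enriched in the
#' highest-activity cluster at the configured odds.
#'
#' The mixing weight of a planted lncRNA is solved analytically so that its
#' Pearson correlation with the latent activity on the observed log2-CPM
#' scale hits \code{targetCorrelation}: the negative binomial measurement
#' noise on the log2 scale is approximated by the delta method as
#' \code{(1/mu + dispersion) / log(2)^2} at the gene's baseline mean.
#'
#' @param config a [cohortConfig()]
#' @return a [GlycoCohort-class]
#' @examples
#' ch <- generateCohort(cohortConfig(nSamples = 60, seed = 7))
#' ch
#' @export
generateCohort <- function(config) {
    stopifnot(inherits(config, "glycoCohortConfig"))
    lay <- cohortLayout(config)
    n <- config$nSamples
    K <- config$nClusters
    features <- c(lay$pcg, lay$lnc)
    p <- length(features)

    gsets <- generateGeneSets(config)
    reg <- generateRegulons(config)
    activeTFs <- attr(reg, "activeTFs")

    out <- withSeed(deriveSeed(config$seed, 3L), {
        cluster <- sample(rep(seq_len(K),
                              times = drop(stats::rmultinom(1, n, config$clusterProportions))))
        mu_c <- config$clusterShift * (seq_len(K) - (K + 1) / 2)
        g <- stats::rnorm(n, mean = mu_c[cluster], sd = config$withinClusterSd)

        # baseline log2-CPM per feature; planted features kept well above
        # the expression filter threshold
        base <- stats::setNames(stats::runif(p, 1, 9), features)
        expressed <- c(lay$glyco, unlist(lay$immune, use.names = FALSE),
                       lay$checkpoint, unlist(lay$tfTargets, use.names = FALSE))
        base[expressed] <- stats::runif(length(expressed), 5, 9)
        base[c(lay$posLnc, lay$negLnc)] <-
            stats::runif(config$nPosLnc + config$nNegLnc, 7, 9)

        M <- matrix(base, nrow = p, ncol = n, dimnames = list(features, lay$samples))
        gRow <- matrix(g, nrow = 1)

        # glycolysis genes scale with latent activity
        glycoLoad <- stats::runif(length(lay$glyco),
                                  0.75 * config$glycolysisLoading,
                                  1.25 * config$glycolysisLoading)
        M[lay$glyco, ] <- M[lay$glyco, ] + glycoLoad %*% gRow

        # active-TF targets move with activity according to their mode
        if (config$tfEffect > 0 && length(activeTFs)) {
            act <- reg[reg$tf %in% activeTFs, ]
            M[act$target, ] <- M[act$target, ] +
                (act$mode * config$tfEffect) %*% gRow
        }

        # immune markers and checkpoints up in the highest-activity cluster
        hot <- as.numeric(cluster == K)
        immuneGenes <- unlist(lay$immune, use.names = FALSE)
        M[immuneGenes, ] <- M[immuneGenes, ] +
            matrix(config$immuneShift, length(immuneGenes), 1) %*% rbind(hot)
        M[lay$checkpoint, ] <- M[lay$checkpoint, ] +
            matrix(config$checkpointShift, length(lay$checkpoint), 1) %*% rbind(hot)

        # planted lncRNAs: analytic mixing weight for the target
        # correlation. CPM normalization divides by the realized library
        # composition, which itself drifts with g (glycolysis/TF/immune
        # blocks all rise with activity), so the fitted slope of log2 total
        # intensity on g is added back to the planted rows and the residual
        # composition fluctuation joins the measurement-noise budget.
        sdG <- stats::sd(g)
        planted <- c(lay$posLnc, lay$negLnc)
        if (length(planted) && sdG > 0) {
            compLog2 <- log2(colSums(2^M))
            cHat <- stats::cov(compLog2, g) / stats::var(g)
            sdComp <- stats::sd(compLog2 - cHat * g)
            rho <- config$targetCorrelation
            muCount <- 2^base[planted]     # approx counts at library 1e6
            sdNoise <- sqrt((1 / muCount + config$nbDispersion) / log(2)^2 +
                            sdComp^2)
            w <- rho * sdNoise / (sdG * sqrt(1 - rho^2))
            w[planted %in% lay$negLnc] <- -w[planted %in% lay$negLnc]
            M[planted, ] <- M[planted, ] + (w + cHat) %*% gRow
        }

        # copy-number and methylation covariates confounded with expression
        nCov <- min(config$nCovariateGenes, config$nCodingGenes)
        covGenes <- lay$pcg[seq_len(nCov)]
        cnv <- matrix(stats::rnorm(nCov * n, 0, 0.5), nCov, n,
                      dimnames = list(paste0("CNV_", covGenes), lay$samples))
        methBase <- stats::runif(nCov, 0.2, 0.8)
        meth <- stats::plogis(matrix(stats::qlogis(methBase), nCov, n) +
                              matrix(stats::rnorm(nCov * n, 0, 0.5), nCov, n))
        dimnames(meth) <- list(paste0("METH_", covGenes), lay$samples)
        M[covGenes, ] <- M[covGenes, ] + 0.6 * cnv -
            0.8 * (meth - rowMeans(meth))

        # negative binomial counts with log-normal library sizes
        libSize <- stats::rlnorm(n, config$libSizeMeanLog, config$libSizeSdLog)
        mu <- 2^M * matrix(libSize / 1e6, p, n, byrow = TRUE)
        counts <- matrix(stats::rnbinom(p * n, mu = mu,
                                        size = 1 / config$nbDispersion),
                         p, n, dimnames = dimnames(M))

        # survival: exponential with per-cluster hazard, administrative
        # uniform censoring calibrated to the configured censoring rate
        rate <- config$baselineHazard * config$survivalHazardRatios[cluster]
        tEvent <- stats::rexp(n, rate)
        if (config$censoringRate > 0) {
            lam <- config$baselineHazard * config$survivalHazardRatios
            pi_c <- config$clusterProportions
            censFrac <- function(cmax)
                sum(pi_c * (1 - exp(-lam * cmax)) / (lam * cmax)) -
                    config$censoringRate
            cmax <- stats::uniroot(censFrac, c(1e-3, 1e9), tol = 1e-6)$root
            cTime <- stats::runif(n, 0, cmax)
        } else cTime <- rep(Inf, n)
        time <- pmin(tEvent, cTime)
        event <- as.integer(tEvent <= cTime)

        # binary mutations; MUT001 enriched in the highest-activity cluster
        pBg <- config$mutationBackgroundRate
        pm <- matrix(pBg, config$nMutationFeatures, n)
        pm[1, cluster == K] <- stats::plogis(stats::qlogis(pBg) +
                                             log(config$mutationEnrichmentOdds))
        mut <- matrix(stats::rbinom(length(pm), 1, pm),
                      nrow(pm), n, dimnames = list(lay$mut, lay$samples))

        list(counts = counts, cluster = cluster, g = g, time = time,
             event = event, mut = mut, cnv = cnv, meth = meth)
    })

    planted <- data.frame(
        feature = c(lay$posLnc, lay$negLnc),
        sign = rep(c(1L, -1L), c(config$nPosLnc, config$nNegLnc)),
        targetCorrelation = rep(c(config$targetCorrelation,
                                  -config$targetCorrelation),
                                c(config$nPosLnc, config$nNegLnc)),
        stringsAsFactors = FALSE)

    se <- SummarizedExperiment(
        assays = list(counts = out$counts),
        rowData = DataFrame(featureClass = rep(c("coding", "lncRNA"),
                                               c(config$nCodingGenes,
                                                 config$nLncRNAs))),
        colData = DataFrame(time = out$time, event = out$event,
                            row.names = lay$samples))
    new("GlycoCohort", se,
        mutations = out$mut, cnv = out$cnv, methylation = out$meth,
        geneSets = gsets, regulons = reg,
        truth = list(nClusters = K, cluster = stats::setNames(out$cluster, lay$samples),
                     latentActivity = stats::setNames(out$g, lay$samples),
                     plantedLnc = planted, enrichedMutation = lay$mut[1],
                     activeTFs = activeTFs, glycolysisGenes = lay$glyco,
                     config = config))
}

#' Generate paired cytoplasmic/nuclear expression for localization analysis
#'
#' A configured fraction of lncRNAs is nuclear-biased (their expected
#' relative concentration index is negative), the rest cytoplasm-biased.
#' Both compartments share the feature axis and are sampled as negative
#' binomial counts.
#'
#' @param config a [cohortConfig()]
#' @return list with integer count matrices \code{cytoplasm} and
#'   \code{nucleus} (compartment-balanced coding anchor transcripts
#'   followed by the lncRNAs) plus \code{truth}, a data.frame with the
#'   planted bias per lncRNA (\code{nuclear} logical, \code{delta} log2
#'   magnitude)
#' @export
generateCompartmentExpression <- function(config) {
    stopifnot(inherits(config, "glycoCohortConfig"))
    lay <- cohortLayout(config)
    nl <- config$nLncRNAs
    # compartment-balanced coding transcripts anchor the per-unit-mass
    # normalization: without them, a bias shared by every lncRNA would be
    # absorbed into the compartment totals and cancel out of the index
    nAnchor <- min(config$nCodingGenes, 200L)
    feats <- c(lay$pcg[seq_len(nAnchor)], lay$lnc)
    nf <- length(feats)
    ns <- config$nCompartmentSamples
    withSeed(deriveSeed(config$seed, 4L), {
        nNuc <- round(config$nuclearFraction * nl)
        nuclear <- seq_len(nl) <= nNuc
        base <- stats::runif(nf, 4, 9)
        delta <- c(rep(0, nAnchor),
                   stats::runif(nl, 0.8, 2.5) * ifelse(nuclear, 1, -1))
        cytMean <- base - delta / 2
        nucMean <- base + delta / 2
        draw <- function(logMean) {
            mu <- 2^matrix(logMean, nf, ns) *
                matrix(stats::rlnorm(ns, config$libSizeMeanLog,
                                     config$libSizeSdLog) / 1e6,
                       nf, ns, byrow = TRUE)
            matrix(stats::rnbinom(nf * ns, mu = mu,
                                  size = 1 / config$nbDispersion),
                   nf, ns, dimnames = list(feats, sprintf("CL%02d", seq_len(ns))))
        }
        cyt <- draw(cytMean)
        nuc <- draw(nucMean)
        list(cytoplasm = cyt, nucleus = nuc,
             truth = data.frame(feature = lay$lnc, nuclear = nuclear,
                                delta = abs(delta[nAnchor + seq_len(nl)]),
                                stringsAsFactors = FALSE))
    })
}

#' Write a synthetic cohort to a directory of plain-text files
#'
#' Counts (TSV with feature class column), clinical table, mutation matrix,
#' covariate matrices, gene sets (GMT), regulons and truth labels.
#'
#' @param cohort a [GlycoCohort-class]
#' @param dir output directory (created if needed)
#' @return the directory path, invisibly
#' @export
writeCohort <- function(cohort, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    cts <- assay(cohort, "counts")
    attr(cts, "featureClass") <- featureClass(cohort)
    writeCounts(cts, file.path(dir, "counts.tsv"))
    utils::write.table(clinicalData(cohort), file.path(dir, "clinical.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    mm <- mutationCalls(cohort)
    utils::write.table(data.frame(feature = rownames(mm), mm,
                                  check.names = FALSE),
                       file.path(dir, "mutations.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    for (nm in c("cnv", "methylation")) {
        m <- slot(cohort, nm)
        utils::write.table(data.frame(feature = rownames(m), m,
                                      check.names = FALSE),
                           file.path(dir, paste0(nm, ".tsv")),
                           sep = "\t", quote = FALSE, row.names = FALSE)
    }
    writeGMT(geneSets(cohort), file.path(dir, "gene_sets.gmt"))
    utils::write.table(regulons(cohort), file.path(dir, "regulons.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    tr <- cohortTruth(cohort)
    if (length(tr))
        utils::write.table(data.frame(sample = names(tr$cluster),
                                      cluster = tr$cluster,
                                      latentActivity = tr$latentActivity),
                           file.path(dir, "truth.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(dir)
}
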