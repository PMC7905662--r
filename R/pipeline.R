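# End-to-end orchestration: filter -> CPM -> glycolysis ssGSEA -> lncRNA
# selection -> consensus clustering -> cluster characterization (survival,
# scores, mutations, DEG/GSEA, TF activity, immune infiltration,
# checkpoints) -> partial-correlation linkage -> optional genomic
# classifier. Cluster indices are canonicalized by ascending median
# glycolysis score, so cluster 1 is always the low-glycolysis group and
# cluster k the high-glycolysis group.

#' Pipeline configuration
#'
#' Bundles every stage threshold with its default. The defaults are the
#' thresholds of the published workflow this pipeline operationalizes:
#' expression filter count > 10 in > 90% of samples, lncRNA selection
#' |r| > 0.3 at FDR < 0.05, 1000 consensus iterations at feature fraction
#' 0.95, consistent DEG selection at FC > 1.5 / < 0.7 with FDR < 1e-4,
#' GSEA with 1e4 permutations at FDR < 0.01, Fisher p < 0.01, ANOVA effect
#' size > 0.5 (with p < 0.01 for checkpoints), regression |coefficient| >
#' 0.3 at FDR < 1e-6, 10 cross-validation folds.
#'
#' @param minCount,minFraction expression filter thresholds
#' @param rMin,qMax lncRNA selection thresholds
#' @param k cluster count used for the downstream characterization
#'   (default 3); the full delta-area table over \code{kRange} is always
#'   computed and reported
#' @param kRange candidate k values for the consensus CDF/delta-area scan
#' @param nIter,featureFraction,metric consensus clustering settings
#' @param elbow delta-area threshold for the advisory suggested k
#' @param upFc,downFc,degQ consistent DEG selection thresholds
#' @param gseaQ,gseaNperm,gseaWeight preranked GSEA settings
#' @param fisherP mutation enrichment p threshold
#' @param esMin ANOVA effect-size threshold (TF activities and checkpoints)
#' @param checkpointP ANOVA p threshold for the checkpoint screen
#' @param regCoefMin,regQ covariate-adjusted association thresholds
#' @param nFolds classifier cross-validation folds
#' @param weightExponent ssGSEA rank-weight exponent
#' @param nLinkLnc number of top selected lncRNAs taken through the
#'   partial-correlation linkage stage
#' @param seed global seed; per-stage seeds are derived from it by a fixed
#'   counter scheme so stages are independently reproducible
#' @return list of class \code{"glycoPipelineConfig"}
#' @export
pipelineConfig <- function(minCount = 10, minFraction = 0.9, rMin = 0.3,
                           qMax = 0.05, k = 3L, kRange = 2:5, nIter = 1000,
                           featureFraction = 0.95,
                           metric = c("euclidean", "pearson"), elbow = 0.1,
                           upFc = 1.5, downFc = 0.7, degQ = 1e-4,
                           gseaQ = 0.01, gseaNperm = 10000, gseaWeight = 1,
                           fisherP = 0.01, esMin = 0.5, checkpointP = 0.01,
                           regCoefMin = 0.3, regQ = 1e-6, nFolds = 10,
                           weightExponent = 0.25, nLinkLnc = 5L, seed = 1L) {
    metric <- match.arg(metric)
    cfg <- as.list(environment())
    stopifnot(minCount > 0, minFraction >= 0, minFraction < 1, rMin >= 0,
              qMax > 0, qMax <= 1, k >= 2, all(kRange >= 2), nIter > 0,
              featureFraction > 0, featureFraction <= 1, upFc > 1,
              downFc < 1, downFc > 0, degQ > 0, gseaQ > 0, gseaNperm > 0,
              fisherP > 0, esMin >= 0, regCoefMin >= 0, regQ > 0,
              nFolds >= 2)
    cfg$seed <- as.integer(seed)
    structure(cfg, class = "glycoPipelineConfig")
}

#' @noRd
.stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
        stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
             call. = FALSE))
}

#' Relabel cluster ids by ascending median score
#'
#' @param labels integer cluster labels
#' @param score per-sample score aligned with \code{labels}
#' @return integer labels with cluster 1 = lowest median score
#' @export
canonicalizeClusters <- function(labels, score) {
    med <- tapply(score, labels, stats::median)
    newId <- rank(med, ties.method = "first")
    out <- as.integer(newId[as.character(labels)])
    names(out) <- names(labels)
    out
}

#' Run the full stratification pipeline on a cohort
#'
#' Executes every stage in order on a [GlycoCohort-class] and returns all
#' stage outputs in one list. When \code{outDir} is given, each result is
#' also written as TSV together with a machine-readable run manifest
#' (configuration, seed and the MD5 content hash of every file); a failed
#' stage leaves the partial outputs plus a \code{FAILED} marker naming the
#' stage.
#'
#' @param cohort a [GlycoCohort-class]
#' @param config a [pipelineConfig()]
#' @param outDir optional output directory
#' @param fitClassifier also train the genomic classifier on the consistent
#'   DEG candidates (default TRUE)
#' @return list of stage outputs (see the vignette for a walk-through)
#' @export
runPipeline <- function(cohort, config = pipelineConfig(), outDir = NULL,
                        fitClassifier = TRUE) {
    if (!is.null(outDir))
        dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    res <- list(config = config)
    on.exit({
        if (!is.null(outDir) && !isTRUE(res$completed))
            writeLines(res$failedStage %||% "unknown",
                       file.path(outDir, "FAILED"))
    })

    counts <- assay(cohort, "counts")
    fclass <- featureClass(cohort)
    gsets <- geneSets(cohort)

    res$failedStage <- "filter"
    retained <- .stage("filter", expressionFilter(counts, config$minCount,
                                                  config$minFraction))
    res$retainedFeatures <- retained

    res$failedStage <- "cpm"
    expr <- .stage("cpm", log2cpm(cpmNormalize(counts)))
    exprF <- expr[retained, , drop = FALSE]

    res$failedStage <- "glycolysis_score"
    res$glycolysisScore <- .stage("glycolysis_score",
        ssgseaScore(exprF, gsets$GLYCOLYSIS,
                    weightExponent = config$weightExponent))

    res$failedStage <- "association"
    lncRetained <- intersect(retained, names(fclass)[fclass == "lncRNA"])
    assoc <- .stage("association",
        pearsonWithFDR(res$glycolysisScore, exprF, lncRetained))
    res$association <- assoc
    res$selected <- selectGlycolysisLncRNAs(assoc, config$rMin, config$qMax)

    res$failedStage <- "consensus"
    clusterFeatures <- res$selected$feature
    res$selectionFallback <- length(clusterFeatures) < 2
    if (res$selectionFallback) clusterFeatures <- lncRetained
    cons <- .stage("consensus",
        consensusCluster(exprF[clusterFeatures, , drop = FALSE],
                         kRange = config$kRange, nIter = config$nIter,
                         featureFraction = config$featureFraction,
                         metric = config$metric,
                         seed = deriveSeed(config$seed, 21L)))
    res$consensus <- cons
    res$deltaArea <- consensusDeltaArea(cons, elbow = config$elbow)
    rawLabels <- consensusLabels(cons[[paste0("k", config$k)]])

    res$failedStage <- "canonicalize"
    res$cluster <- canonicalizeClusters(rawLabels, res$glycolysisScore)
    K <- config$k
    bySample <- split(names(res$cluster), res$cluster)

    res$failedStage <- "survival"
    clin <- clinicalData(cohort)
    clin <- clin[match(names(res$cluster), clin$sample), ]
    res$logrank <- .stage("survival",
        logrankTest(clin$time, clin$event, res$cluster))
    res$km <- lapply(bySample, function(ss) {
        i <- match(ss, clin$sample)
        kaplanMeier(clin$time[i], clin$event[i])
    })
    res$scoreTest <- list(
        kruskal = kruskalWallis(res$glycolysisScore, res$cluster),
        dunn = dunnPosthoc(res$glycolysisScore, res$cluster))

    res$failedStage <- "mutation_enrichment"
    mut <- mutationCalls(cohort)
    if (nrow(mut)) {
        res$mutationEnrichment <- .stage("mutation_enrichment", list(
            focusHigh = fisherEnrichment(mut, res$cluster, K,
                                         pMax = config$fisherP),
            focusLow = fisherEnrichment(mut, res$cluster, 1,
                                        pMax = config$fisherP)))
    }

    res$failedStage <- "deg"
    cts <- counts[retained, , drop = FALSE]
    res$deg <- .stage("deg", list(
        c3v1 = differentialExpression(cts, bySample[["1"]], bySample[[as.character(K)]]),
        c3v2 = differentialExpression(cts, bySample[["2"]], bySample[[as.character(K)]]),
        c2v1 = differentialExpression(cts, bySample[["1"]], bySample[["2"]])))

    res$failedStage <- "gsea"
    pathSets <- gsets[!grepl("^CHECKPOINT$", names(gsets))]
    res$gsea <- .stage("gsea",
        gseaPreranked(rankByLogFC(res$deg$c3v1), pathSets,
                      weight = config$gseaWeight, nPerm = config$gseaNperm,
                      seed = deriveSeed(config$seed, 22L)))
    res$gseaSignificant <- res$gsea$set[!is.na(res$gsea$q) &
                                        res$gsea$q < config$gseaQ]

    res$failedStage <- "tf_activity"
    reg <- regulons(cohort)
    if (nrow(reg)) {
        act <- .stage("tf_activity",
            suppressWarnings(areaTFActivity(exprF, reg)))
        res$tfActivity <- act
        res$tfScreen <- anovaEffectScreen(act, res$cluster,
                                          esMin = config$esMin)
    }

    res$failedStage <- "immune"
    markerSets <- gsets[!grepl("^(GLYCOLYSIS|DECOY_|CHECKPOINT)", names(gsets))]
    if (length(markerSets)) {
        imm <- .stage("immune", immuneInfiltrationScores(
            exprF, markerSets, weightExponent = config$weightExponent))
        res$immuneScores <- imm
        res$immuneGroups <- hierarchicalWard(imm)
        ckGenes <- intersect(gsets$CHECKPOINT, rownames(exprF))
        if (length(ckGenes) >= 2)
            res$checkpointScreen <- anovaEffectScreen(
                exprF[ckGenes, , drop = FALSE], res$cluster,
                esMin = config$esMin, pMax = config$checkpointP)
    }

    res$failedStage <- "linkage"
    posGenes <- .stage("linkage", {
        coding <- intersect(retained, names(fclass)[fclass == "coding"])
        gassoc <- pearsonWithFDR(res$glycolysisScore, exprF, coding)
        gassoc$feature[!is.na(gassoc$r) & gassoc$r > 0 & gassoc$q < 0.05]
    })
    res$positiveGenes <- posGenes
    if (nrow(res$selected) && length(posGenes) >= 2) {
        topLnc <- res$selected$feature[
            order(-abs(res$selected$r))][seq_len(min(config$nLinkLnc,
                                                     nrow(res$selected)))]
        res$linkage <- lapply(stats::setNames(topLnc, topLnc), function(l)
            partialCorrelationShift(res$glycolysisScore,
                                    exprF[posGenes, , drop = FALSE],
                                    exprF[l, ]))
    }

    if (fitClassifier) {
        res$failedStage <- "classifier"
        sel <- consistentDegSelection(res$deg$c3v2, res$deg$c2v1,
                                      upFc = config$upFc,
                                      downFc = config$downFc,
                                      qMax = config$degQ)
        res$degConsistent <- sel
        candidates <- c(sel$up, sel$down)
        if (length(candidates) >= 2 &&
            all(table(res$cluster) >= config$nFolds)) {
            qn <- quantileNormalize(exprF[candidates, , drop = FALSE])
            Xtrain <- t(qn$matrices[[1]])
            res$classifier <- .stage("classifier",
                fitLassoMultinomialCV(Xtrain, res$cluster,
                                      nFolds = config$nFolds,
                                      seed = deriveSeed(config$seed, 23L),
                                      quantileReference = qn$reference))
            pred <- predictCluster(res$classifier, Xtrain, normalize = FALSE)
            res$trainingAccuracy <- mean(pred$labels ==
                                         as.character(res$cluster))
        }
    }

    res$failedStage <- NULL
    res$completed <- TRUE
    if (!is.null(outDir)) res$manifest <- .writeRunOutputs(res, cohort, outDir)
    res
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
.writeRunOutputs <- function(res, cohort, outDir) {
    wt <- function(df, name) {
        utils::write.table(df, file.path(outDir, name), sep = "\t",
                           quote = FALSE, row.names = FALSE)
        name
    }
    files <- character(0)
    files <- c(files, wt(data.frame(sample = names(res$glycolysisScore),
                                    glycolysisScore = res$glycolysisScore,
                                    cluster = res$cluster[names(res$glycolysisScore)]),
                         "scores.tsv"))
    files <- c(files, wt(res$association, "association.tsv"))
    files <- c(files, wt(res$selected, "selected_lncRNAs.tsv"))
    files <- c(files, wt(data.frame(k = sub("^k", "", names(res$deltaArea$area)),
                                    area = res$deltaArea$area,
                                    deltaArea = res$deltaArea$deltaArea),
                         "delta_area.tsv"))
    files <- c(files, wt(data.frame(chi2 = res$logrank$chi2,
                                    df = res$logrank$df, p = res$logrank$p),
                         "logrank.tsv"))
    files <- c(files, wt(res$scoreTest$dunn, "dunn.tsv"))
    if (!is.null(res$mutationEnrichment)) {
        files <- c(files, wt(res$mutationEnrichment$focusHigh,
                             "mutation_enrichment_high.tsv"))
        files <- c(files, wt(res$mutationEnrichment$focusLow,
                             "mutation_enrichment_low.tsv"))
    }
    for (nm in names(res$deg))
        files <- c(files, wt(res$deg[[nm]], paste0("deg_", nm, ".tsv")))
    files <- c(files, wt(res$gsea, "gsea.tsv"))
    if (!is.null(res$tfScreen)) files <- c(files, wt(res$tfScreen, "tf_screen.tsv"))
    if (!is.null(res$immuneGroups))
        files <- c(files, wt(data.frame(sample = names(res$immuneGroups$group),
                                        group = res$immuneGroups$group,
                                        infiltration = res$immuneGroups$infiltration),
                             "immune_groups.tsv"))
    if (!is.null(res$checkpointScreen))
        files <- c(files, wt(res$checkpointScreen, "checkpoint_screen.tsv"))
    if (!is.null(res$linkage)) {
        link <- data.frame(
            lncRNA = names(res$linkage),
            ksD = vapply(res$linkage, `[[`, numeric(1), "D"),
            ksP = vapply(res$linkage, `[[`, numeric(1), "p"),
            meanRaw = vapply(res$linkage, function(l) mean(l$raw), numeric(1)),
            meanAdjusted = vapply(res$linkage, function(l) mean(l$adjusted),
                                  numeric(1)))
        files <- c(files, wt(link, "linkage.tsv"))
    }
    if (!is.null(res$classifier)) {
        sig <- signatureFeatures(res$classifier)
        files <- c(files, wt(data.frame(feature = sig), "classifier_signature.tsv"))
    }
    hashes <- tools::md5sum(file.path(outDir, files))
    names(hashes) <- files
    manifest <- list(config = unclass(res$config), seed = res$config$seed,
                     files = as.list(hashes))
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    manifest
}

#' Summarize a pipeline run directory
#'
#' Reads the manifest and stage outputs of a [runPipeline()] directory and
#' builds a cross-stage summary table: cluster sizes, median glycolysis
#' score per cluster, selected lncRNA counts by sign, significantly
#' enriched sets and TFs, classifier signature size. Missing stage outputs
#' are listed as absent rather than raising an error, and regeneration is
#' idempotent.
#'
#' @param runDir a directory written by [runPipeline()]
#' @return data.frame with columns \code{stage}, \code{status},
#'   \code{summary}
#' @export
makeReport <- function(runDir) {
    manifestPath <- file.path(runDir, "manifest.json")
    if (!file.exists(manifestPath)) stop("no manifest.json in ", runDir)
    rows <- list()
    add <- function(stage, file, summarize) {
        path <- file.path(runDir, file)
        if (!file.exists(path)) {
            rows[[length(rows) + 1]] <<- data.frame(
                stage = stage, status = "absent", summary = "")
        } else {
            tab <- utils::read.delim(path, stringsAsFactors = FALSE)
            rows[[length(rows) + 1]] <<- data.frame(
                stage = stage, status = "present", summary = summarize(tab))
        }
    }
    add("scores", "scores.tsv", function(t) {
        sizes <- table(t$cluster)
        med <- tapply(t$glycolysisScore, t$cluster, stats::median)
        sprintf("clusters %s; median glycolysis score %s",
                paste(sprintf("%s:n=%d", names(sizes), sizes), collapse = ", "),
                paste(sprintf("%s:%.3f", names(med), med), collapse = ", "))
    })
    add("selection", "selected_lncRNAs.tsv", function(t)
        sprintf("%d selected (%d positive, %d negative)", nrow(t),
                sum(t$sign > 0), sum(t$sign < 0)))
    add("delta_area", "delta_area.tsv", function(t)
        paste(sprintf("k=%s: area %.3f", t$k, t$area), collapse = "; "))
    add("survival", "logrank.tsv", function(t)
        sprintf("log-rank chi2=%.2f (df=%d), p=%.3g", t$chi2, t$df, t$p))
    add("mutations", "mutation_enrichment_high.tsv", function(t)
        if (nrow(t)) sprintf("%d enriched in the high cluster (top: %s)",
                             sum(t$enrichedInFocus),
                             t$feature[which.min(t$p)]) else "none")
    add("gsea", "gsea.tsv", function(t)
        sprintf("%d/%d sets at FDR < 0.01 (top NES: %s)",
                sum(t$q < 0.01, na.rm = TRUE), nrow(t),
                t$set[which.max(t$NES)]))
    add("tf_screen", "tf_screen.tsv", function(t)
        sprintf("%d/%d TFs above effect-size threshold", sum(t$selected),
                nrow(t)))
    add("immune", "immune_groups.tsv", function(t)
        sprintf("high infiltration n=%d, low n=%d",
                sum(t$infiltration == "high"), sum(t$infiltration == "low")))
    add("checkpoints", "checkpoint_screen.tsv", function(t)
        sprintf("%d/%d checkpoints selected", sum(t$selected), nrow(t)))
    add("linkage", "linkage.tsv", function(t)
        sprintf("strongest mediator %s (KS p=%.3g)",
                t$lncRNA[which.min(t$ksP)], min(t$ksP)))
    add("classifier", "classifier_signature.tsv", function(t)
        sprintf("signature of %d genes", nrow(t)))
    do.call(rbind, rows)
}
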