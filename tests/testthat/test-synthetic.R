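test_that("identical seeds give bit-identical bundles", {
    cfg <- smallConfig(seed = 11)
    a <- generateCohort(cfg)
    b <- generateCohort(cfg)
    expect_identical(SummarizedExperiment::assay(a, "counts"),
                     SummarizedExperiment::assay(b, "counts"))
    expect_identical(clinicalData(a), clinicalData(b))
    expect_identical(mutationCalls(a), mutationCalls(b))
    expect_identical(cohortTruth(a)$latentActivity,
                     cohortTruth(b)$latentActivity)
    expect_identical(generateCompartmentExpression(cfg),
                     generateCompartmentExpression(cfg))
    d <- generateCohort(smallConfig(seed = 12))
    expect_false(identical(SummarizedExperiment::assay(a, "counts"),
                           SummarizedExperiment::assay(d, "counts")))
})

test_that("invalid configurations raise configuration errors", {
    expect_error(cohortConfig(nSamples = 0), "positive")
    expect_error(cohortConfig(clusterProportions = c(0.5, 0.4, 0.2)),
                 "sum to 1")
    expect_error(cohortConfig(nPosLnc = 100, nNegLnc = 100, nLncRNAs = 120),
                 "nPosLnc")
    expect_error(cohortConfig(glycolysisSetSize = 1000, nCodingGenes = 600),
                 "glycolysisSetSize")
    expect_error(cohortConfig(targetCorrelation = 1.2), "targetCorrelation")
    expect_error(cohortConfig(censoringRate = 1), "censoringRate")
    expect_error(cohortConfig(targetsPerTF = 3), "5 targets")
})

test_that("planted lncRNAs hit the target correlation within 0.1", {
    # per-feature band at n = 1000, where the sampling noise of a single
    # correlation (sd ~ 0.02) is small against the 0.1 tolerance
    cfg <- cohortConfig(nSamples = 1000, seed = 21, targetCorrelation = 0.6)
    ch <- generateCohort(cfg)
    expr <- log2cpm(cpmNormalize(SummarizedExperiment::assay(ch, "counts")))
    g <- cohortTruth(ch)$latentActivity
    pl <- cohortTruth(ch)$plantedLnc
    rs <- vapply(pl$feature, function(f) stats::cor(expr[f, ], g), numeric(1))
    expect_true(all(rs[pl$sign == 1] > 0.5 & rs[pl$sign == 1] < 0.7))
    expect_true(all(rs[pl$sign == -1] < -0.5 & rs[pl$sign == -1] > -0.7))
    # and the planted ensemble is centered on the target at n = 300
    ch3 <- generateCohort(cohortConfig(nSamples = 300, seed = 22))
    expr3 <- log2cpm(cpmNormalize(SummarizedExperiment::assay(ch3, "counts")))
    g3 <- cohortTruth(ch3)$latentActivity
    pl3 <- cohortTruth(ch3)$plantedLnc
    rs3 <- vapply(pl3$feature, function(f) stats::cor(expr3[f, ], g3),
                  numeric(1))
    expect_lt(abs(mean(rs3[pl3$sign == 1]) - 0.6), 0.05)
    expect_lt(abs(mean(rs3[pl3$sign == -1]) + 0.6), 0.05)
})

test_that("cluster structure, survival and mutations follow the config", {
    cfg <- cohortConfig(seed = 31)
    ch <- generateCohort(cfg)
    tr <- cohortTruth(ch)
    g <- tr$latentActivity
    # latent activity means ordered by cluster index
    means <- tapply(g, tr$cluster, mean)
    expect_true(all(diff(means) > 0))
    # designated mutation enriched in the highest-activity cluster
    mut <- mutationCalls(ch)[tr$enrichedMutation, ]
    rateHigh <- mean(mut[tr$cluster == 3])
    rateRest <- mean(mut[tr$cluster != 3])
    expect_gt(rateHigh, rateRest)
    # censoring near the configured rate
    expect_lt(abs(mean(clinicalData(ch)$event == 0) - cfg$censoringRate), 0.15)
    validObject(ch)
})

test_that("null configuration plants no structure", {
    ch <- generateCohort(nullCohortConfig(nSamples = 80, seed = 41))
    tr <- cohortTruth(ch)
    expect_equal(nrow(tr$plantedLnc), 0)
    means <- tapply(tr$latentActivity, tr$cluster, mean)
    expect_lt(diff(range(means)), 0.2)
})

test_that("gene sets: sizes, determinism, and decoy overlap expectation", {
    cfg <- cohortConfig(seed = 51, nDecoySets = 40L)
    gs <- generateGeneSets(cfg)
    expect_identical(gs, generateGeneSets(cfg))
    decoys <- gs[grepl("^DECOY", names(gs))]
    expect_true(all(lengths(decoys) == length(gs$GLYCOLYSIS)))
    # expected overlap of a uniform decoy with the glycolysis set is
    # hypergeometric: size^2 / universe
    ov <- vapply(decoys, function(d) length(intersect(d, gs$GLYCOLYSIS)),
                 numeric(1))
    expected <- cfg$glycolysisSetSize^2 / cfg$nCodingGenes
    se <- sqrt(expected * (1 - cfg$glycolysisSetSize / cfg$nCodingGenes) /
               length(decoys))
    expect_lt(abs(mean(ov) - expected), 4 * se + 0.5)
})

test_that("regulons: structure and planted activity shifts", {
    cfg <- cohortConfig(seed = 61)
    reg <- generateRegulons(cfg)
    expect_equal(nrow(reg), cfg$nTFs * cfg$targetsPerTF)
    expect_true(all(table(reg$tf) == cfg$targetsPerTF))
    expect_true(all(reg$mode %in% c(-1L, 1L)))
    ch <- generateCohort(cfg)
    expr <- log2cpm(cpmNormalize(SummarizedExperiment::assay(ch, "counts")))
    tr <- cohortTruth(ch)
    act <- attr(reg, "activeTFs")
    # active TF: mode-weighted target expression higher in cluster 3 than 1
    for (tf in act) {
        sub <- reg[reg$tf == tf, ]
        sig <- colSums(expr[sub$target, ] * sub$mode)
        expect_gt(mean(sig[tr$cluster == 3]), mean(sig[tr$cluster == 1]))
    }
    # positive-mode targets of an active TF move up with activity
    sub <- reg[reg$tf == act[1] & reg$mode == 1, ]
    if (nrow(sub) >= 2) {
        m3 <- mean(expr[sub$target, tr$cluster == 3])
        m1 <- mean(expr[sub$target, tr$cluster == 1])
        expect_gt(m3, m1)
    }
})

test_that("inactive TFs show no systematic activity shift at n = 300", {
    cfg <- cohortConfig(nSamples = 300, seed = 71)
    ch <- generateCohort(cfg)
    cts <- SummarizedExperiment::assay(ch, "counts")
    # activity is scored on the filtered matrix, as in the pipeline
    expr <- log2cpm(cpmNormalize(cts))[expressionFilter(cts), ]
    reg <- regulons(ch)
    tr <- cohortTruth(ch)
    act <- areaTFActivity(expr, reg)
    inactive <- setdiff(rownames(act), tr$activeTFs)
    smd <- vapply(inactive, function(tf) {
        sig <- act[tf, ]
        (mean(sig[tr$cluster == 3]) - mean(sig[tr$cluster == 1])) /
            stats::sd(sig)
    }, numeric(1))
    expect_lt(stats::median(abs(smd)), 0.2)
    # and the planted-active TFs dominate the activity difference
    smdActive <- vapply(tr$activeTFs, function(tf) {
        sig <- act[tf, ]
        (mean(sig[tr$cluster == 3]) - mean(sig[tr$cluster == 1])) /
            stats::sd(sig)
    }, numeric(1))
    expect_gt(min(abs(smdActive)), max(abs(smd)))
})

test_that("compartment generator plants the nuclear-bias fraction", {
    cfg <- cohortConfig(nLncRNAs = 400L, nPosLnc = 0L, nNegLnc = 0L,
                        seed = 81, nuclearFraction = 0.7)
    cmp <- generateCompartmentExpression(cfg)
    expect_identical(rownames(cmp$cytoplasm), rownames(cmp$nucleus))
    r <- rci(cpmNormalize(cmp$cytoplasm), cpmNormalize(cmp$nucleus))
    r <- r[cmp$truth$feature]
    expect_lt(abs(mean(r < 0) - 0.7), 0.05)
    # fully nuclear-biased configuration forces negative RCI throughout
    cfgAll <- cohortConfig(nLncRNAs = 100L, nPosLnc = 0L, nNegLnc = 0L,
                           seed = 82, nuclearFraction = 1)
    cmpAll <- generateCompartmentExpression(cfgAll)
    rAll <- rci(cpmNormalize(cmpAll$cytoplasm), cpmNormalize(cmpAll$nucleus))
    rAll <- rAll[cmpAll$truth$feature]
    expect_gt(mean(rAll < 0), 0.95)
})

test_that("planted-effect monotonicity: bigger shift, bigger score gap", {
    gaps <- vapply(c(0, 0.75, 1.5), function(shift) {
        mean(vapply(1:3, function(seed) {
            ch <- generateCohort(smallConfig(seed = seed,
                                             clusterShift = shift))
            expr <- log2cpm(cpmNormalize(
                SummarizedExperiment::assay(ch, "counts")))
            sc <- ssgseaScore(expr, geneSets(ch)$GLYCOLYSIS)
            tr <- cohortTruth(ch)$cluster
            mean(sc[tr == 3]) - mean(sc[tr == 1])
        }, numeric(1)))
    }, numeric(1))
    expect_true(all(diff(gaps) > -0.01))
    expect_gt(gaps[3], gaps[1])
})
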