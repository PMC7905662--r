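test_that("Pearson association recovers exact and null relations", {
    set.seed(1)
    n <- 40
    score <- rnorm(n)
    expr <- rbind(exact = score,
                  noise = rnorm(n),
                  flat = rep(1, n))
    colnames(expr) <- paste0("s", 1:n)
    names(score) <- colnames(expr)
    expect_message(tab <- pearsonWithFDR(score, expr), "zero-variance")
    expect_equal(tab$r[tab$feature == "exact"], 1)
    expect_lt(tab$p[tab$feature == "exact"], 1e-12)
    expect_true(is.na(tab$r[tab$feature == "flat"]))
    expect_true(is.na(tab$q[tab$feature == "flat"]))
    expect_error(pearsonWithFDR(score[1:3], expr[, 1:3]), "4")
})

test_that("BH adjustment matches the hand step-up and brute force", {
    # p = (0.01, 0.02, 0.03): step-up gives q = 0.03 for all three
    expect_equal(stats::p.adjust(c(0.01, 0.02, 0.03), "BH"), rep(0.03, 3))
    set.seed(2)
    for (i in 1:20) {
        p <- runif(sample(3:8, 1))
        expect_equal(stats::p.adjust(p, "BH"), bruteBH(p))
    }
})

test_that("permuted scores yield essentially no q < 0.05 discoveries", {
    set.seed(3)
    n <- 60
    expr <- matrix(rnorm(n * 200), 200, n,
                   dimnames = list(paste0("f", 1:200), paste0("s", 1:n)))
    hits <- vapply(1:20, function(i) {
        score <- stats::setNames(rnorm(n), colnames(expr))
        sum(pearsonWithFDR(score, expr)$q < 0.05, na.rm = TRUE)
    }, numeric(1))
    expect_lt(mean(hits > 0), 0.2)
})

test_that("selection applies strict |r| and q thresholds with sign", {
    tab <- data.frame(feature = c("a", "b", "c", "d"),
                      r = c(0.3, 0.31, -0.5, 0.6),
                      p = c(0.001, 0.001, 0.001, 0.2),
                      q = c(0.01, 0.01, 0.01, 0.3), n = 50)
    sel <- selectGlycolysisLncRNAs(tab)
    expect_setequal(sel$feature, c("b", "c"))   # r = 0.3 exactly is excluded
    expect_equal(sel$sign[sel$feature == "c"], -1)
})

test_that("planted lncRNAs are selected with high sensitivity at n = 300", {
    sens <- vapply(1:3, function(seed) {
        ch <- generateCohort(cohortConfig(nSamples = 300, seed = seed,
                                          targetCorrelation = 0.6))
        cts <- SummarizedExperiment::assay(ch, "counts")
        ret <- expressionFilter(cts)
        expr <- log2cpm(cpmNormalize(cts))[ret, ]
        fc <- featureClass(ch)
        sc <- ssgseaScore(expr, geneSets(ch)$GLYCOLYSIS)
        tab <- pearsonWithFDR(sc, expr,
                              intersect(ret, names(fc)[fc == "lncRNA"]))
        sel <- selectGlycolysisLncRNAs(tab)
        mean(cohortTruth(ch)$plantedLnc$feature %in% sel$feature)
    }, numeric(1))
    expect_gte(mean(sens), 0.95)
})

test_that("first-order partial correlation matches its closed form", {
    expect_equal(partialCorrelation(rxy = 0.5, rxz = 0, ryz = 0), 0.5)
    expect_equal(partialCorrelation(rxy = 0.12, rxz = 0.4, ryz = 0.3), 0,
                 tolerance = 1e-12)
    expect_error(partialCorrelation(rxy = 0.5, rxz = 1, ryz = 0.2),
                 "degenerate")
})

test_that("partial correlation equals the residual-regression oracle", {
    set.seed(4)
    worst <- 0
    for (i in 1:100) {
        z <- rnorm(50)
        x <- 0.6 * z + rnorm(50)
        y <- -0.4 * z + rnorm(50)
        pc <- partialCorrelation(x = x, y = y, z = z)
        oracle <- stats::cor(stats::resid(stats::lm(x ~ z)),
                             stats::resid(stats::lm(y ~ z)))
        worst <- max(worst, abs(pc - oracle))
        expect_true(abs(pc) <= 1)
    }
    expect_lt(worst, 1e-10)
})

test_that("two-sample KS statistic behaves as the sup-ECDF distance", {
    a <- c(0.1, 0.5, 0.9)
    expect_equal(ksTwoSample(a, a)$D, 0)
    expect_equal(ksTwoSample(runif(20), runif(20) + 2)$D, 1)
    expect_error(ksTwoSample(numeric(0), a), "empty")
})

test_that("conditioning on an independent lncRNA leaves correlations alone", {
    set.seed(5)
    n <- 100
    score <- rnorm(n)
    genes <- matrix(rep(score, each = 50), 50, n, byrow = FALSE) * 0.5 +
        matrix(rnorm(50 * n), 50, n)
    rownames(genes) <- paste0("g", 1:50)
    z <- rnorm(n)
    out <- partialCorrelationShift(score, genes, z)
    expect_lt(max(abs(out$raw - out$adjusted)), 0.1)
    expect_gt(out$p, 0.05)
    # conditioning on the score itself is degenerate
    expect_error(partialCorrelationShift(score, genes, score), "degenerate")
})

test_that("a mediating lncRNA shifts the adjusted distribution toward zero", {
    set.seed(6)
    n <- 150
    nGenes <- 200
    z <- rnorm(n)
    score <- 0.9 * z + 0.45 * rnorm(n)
    genes <- matrix(0.8 * rep(z, each = nGenes), nGenes, n) +
        matrix(rnorm(nGenes * n, sd = 0.6), nGenes, n)
    rownames(genes) <- paste0("g", 1:nGenes)
    out <- partialCorrelationShift(score, genes, z)
    expect_lt(mean(out$adjusted), mean(out$raw))
    expect_lt(out$p, 0.01)
})

test_that("covariate-adjusted association recovers planted structure", {
    set.seed(7)
    n <- 120
    lnc <- rnorm(n)
    cnv <- rnorm(n)
    meth <- rnorm(n)
    genes <- rbind(pure = lnc,
                   cnvOnly = cnv + 0.01 * rnorm(n),
                   nogo = rnorm(n))
    colnames(genes) <- paste0("s", 1:n)
    out <- multivariateAdjustedAssociation(genes, lnc, cnv, meth)
    expect_gt(out$coefficient[out$feature == "pure"], 0.95)
    expect_lt(abs(out$coefficient[out$feature == "cnvOnly"]), 0.15)
    expect_lt(abs(out$coefficient[out$feature == "nogo"]), 0.3)
    expect_true(out$selected[out$feature == "pure"])
    expect_false(out$selected[out$feature == "cnvOnly"])
})

test_that("adjustment shrinks confounded correlations over seeds", {
    shrunk <- vapply(1:10, function(seed) {
        set.seed(seed)
        n <- 80
        cnv <- rnorm(n)
        gene <- cnv + rnorm(n)
        lnc <- cnv + rnorm(n)
        raw <- stats::cor(gene, lnc)
        out <- multivariateAdjustedAssociation(
            matrix(gene, 1, n, dimnames = list("g", NULL)), lnc, cnv,
            rnorm(n))
        abs(out$coefficient) < abs(raw)
    }, logical(1))
    expect_gte(mean(shrunk), 0.9)
})

test_that("collinear covariates are rejected with the offending pair named", {
    set.seed(8)
    n <- 50
    lnc <- rnorm(n)
    genes <- matrix(rnorm(n), 1, n, dimnames = list("g", NULL))
    expect_error(multivariateAdjustedAssociation(genes, lnc, lnc, rnorm(n)),
                 "collinear.*(lncRNA|cnv).*(lncRNA|cnv)")
})
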