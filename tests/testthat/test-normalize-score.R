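test_that("CPM normalization is forced arithmetic with unit column sums", {
    m <- matrix(c(5L, 5L, 2L, 8L), 2, 2,
                dimnames = list(c("g1", "g2"), c("s1", "s2")))
    cpm <- cpmNormalize(m)
    expect_equal(cpm[, "s1"], c(g1 = 5e5, g2 = 5e5))
    expect_equal(unname(colSums(cpm)), c(1e6, 1e6))
    # scale invariance: doubling a sample's counts leaves its CPM unchanged
    m2 <- m
    m2[, 1] <- m2[, 1] * 2L
    expect_equal(cpmNormalize(m2)[, 1], cpm[, 1])
    expect_identical(attr(cpm, "scale"), "cpm")
    m0 <- m
    m0[, 2] <- 0L
    expect_error(cpmNormalize(m0), "s2")
})

test_that("expression filter applies strict thresholds", {
    counts <- rbind(
        keep = c(rep(11L, 95), rep(0L, 5)),     # >10 in 95% of samples
        boundary = rep(10L, 100),               # exactly 10 everywhere
        lowfrac = c(rep(50L, 90), rep(0L, 10))) # >10 in exactly 90%
    colnames(counts) <- paste0("s", 1:100)
    kept <- expressionFilter(counts, minCount = 10, minFraction = 0.9)
    expect_identical(kept, "keep")
    # minFraction = 0 keeps anything exceeding the count threshold somewhere
    expect_setequal(expressionFilter(counts, 10, 0), c("keep", "lowfrac"))
    expect_error(expressionFilter(counts[0, , drop = FALSE]), "empty")
})

test_that("ssGSEA matches the exhaustive running-sum oracle", {
    # 5-feature universe, unweighted: enumerate the integrated ECDF
    # difference by hand for every possible singleton/pair position
    x <- c(a = 50, b = 40, c = 30, d = 20, e = 10)
    expr <- cbind(s1 = x)
    bruteSS <- function(inSet, alpha, ranks) {
        ord <- order(-x)
        hit <- inSet[ord]
        w <- ifelse(hit, ranks[ord]^alpha, 0)
        sum(cumsum(w) / sum(w) - cumsum(!hit) / sum(!hit))
    }
    ranks <- rank(x)
    for (set in list(c("a", "b"), c("a", "e"), c("d", "e"), c("b", "c", "d"))) {
        inSet <- names(x) %in% set
        for (alpha in c(0, 0.25, 0.75))
            expect_equal(
                unname(ssgseaScore(expr, set, weightExponent = alpha,
                                   normalize = FALSE)),
                bruteSS(inSet, alpha, ranks))
    }
    # top singleton-plus-one at alpha 0 equals the hand value 2.5
    expect_equal(unname(ssgseaScore(expr, c("a", "missing", "b"),
                                    weightExponent = 0, normalize = FALSE)),
                 sum(c(0.5, 1, 1, 1, 1) - c(0, 0, 1/3, 2/3, 1)))
})

test_that("ssGSEA is rank-based and position-monotone", {
    set.seed(5)
    expr <- matrix(rexp(200, 1 / 50), 20, 10,
                   dimnames = list(paste0("g", 1:20), paste0("s", 1:10)))
    gs <- c("g1", "g5", "g9")
    base <- ssgseaScore(expr, gs, normalize = FALSE)
    # invariant under any strictly monotone transform of a sample's values
    expect_equal(ssgseaScore(log2(expr + 1), gs, normalize = FALSE), base)
    expect_equal(ssgseaScore(expr^3, gs, normalize = FALSE), base)
    # identical columns give identical scores
    dup <- expr[, c(1, 1)]
    colnames(dup) <- c("a", "b")
    sdup <- ssgseaScore(dup, gs, normalize = FALSE)
    expect_equal(sdup[["a"]], sdup[["b"]])
    # a set at the top of every ranking beats the same-size set at the bottom
    ordExpr <- matrix(rep(seq(100, 5, length.out = 20), 10), 20, 10,
                      dimnames = dimnames(expr))
    top <- ssgseaScore(ordExpr, c("g1", "g2", "g3"), normalize = FALSE)
    bottom <- ssgseaScore(ordExpr, c("g18", "g19", "g20"), normalize = FALSE)
    expect_true(all(top > bottom))
    # error paths
    expect_error(ssgseaScore(expr, "g1"), "fewer than 2")
    expect_error(ssgseaScore(expr, rownames(expr)), "universe")
})

test_that("immune infiltration scores are consistent ssGSEA scores", {
    set.seed(6)
    expr <- matrix(rexp(300), 30, 10,
                   dimnames = list(paste0("g", 1:30), paste0("s", 1:10)))
    gs <- paste0("g", 1:5)
    imm <- immuneInfiltrationScores(expr, list(CT = gs), normalize = FALSE)
    expect_equal(imm["CT", ], ssgseaScore(expr, gs, normalize = FALSE))
    expect_equal(nrow(immuneInfiltrationScores(expr, list())), 0)
    expect_error(immuneInfiltrationScores(expr, list(bad = "g1")),
                 "cell type 'bad'")
})

test_that("planted marker blocks score higher in their own sample group", {
    set.seed(7)
    expr <- matrix(rnorm(40 * 30, 8, 1), 40, 30,
                   dimnames = list(paste0("g", 1:40), paste0("s", 1:30)))
    expr[1:8, 1:15] <- expr[1:8, 1:15] + 2      # block A up in group 1
    expr[9:16, 16:30] <- expr[9:16, 16:30] + 2  # block B up in group 2
    imm <- immuneInfiltrationScores(
        expr, list(A = paste0("g", 1:8), B = paste0("g", 9:16)))
    expect_gt(mean(imm["A", 1:15]), mean(imm["A", 16:30]))
    expect_gt(mean(imm["B", 16:30]), mean(imm["B", 1:15]))
})

test_that("aREA activity behaves as a standard-normal rank statistic", {
    set.seed(8)
    n <- 41
    expr <- matrix(rnorm(n * 6), n, 6,
                   dimnames = list(paste0("g", 1:n), paste0("s", 1:6)))
    reg <- data.frame(tf = "TF1", target = paste0("g", 1:8),
                      mode = rep(1L, 8))
    act <- areaTFActivity(expr, reg)
    # flipping all modes negates the activity exactly
    regNeg <- transform(reg, mode = -mode)
    expect_equal(areaTFActivity(expr, regNeg), -act)
    # targets all at the median rank give activity ~ 0
    exprMed <- expr
    exprMed[1:8, ] <- 0        # ties at a central plateau -> average ranks
    exprMed[9:24, ] <- 5
    exprMed[25:41, ] <- -5
    actMed <- areaTFActivity(exprMed, reg)
    expect_lt(max(abs(actMed)), 0.2)
    # regulons with < 5 present targets are skipped with a warning
    regSmall <- data.frame(tf = "TFx", target = paste0("g", 1:3),
                           mode = rep(1L, 3))
    expect_warning(out <- areaTFActivity(expr, rbind(reg, regSmall)),
                   "TFx")
    expect_identical(rownames(out), "TF1")
})

test_that("random regulons on permuted expression give null mean 0, var 1", {
    set.seed(9)
    n <- 200
    nPerm <- 1200
    expr <- matrix(rnorm(n * nPerm), n, nPerm)
    rownames(expr) <- paste0("g", 1:n)
    reg <- data.frame(tf = "TF1",
                      target = sample(rownames(expr), 20),
                      mode = sample(c(1L, -1L), 20, TRUE))
    act <- areaTFActivity(expr, reg)
    expect_lt(abs(mean(act)), 3 / sqrt(nPerm))
    expect_lt(abs(stats::var(as.numeric(act)) - 1), 0.15)
})

test_that("RCI is the signed log2 compartment ratio", {
    cyt <- matrix(c(8, 4), 2, 1, dimnames = list(c("l1", "l2"), NULL))
    nuc <- matrix(c(2, 4), 2, 1, dimnames = list(c("l1", "l2"), NULL))
    r <- rci(cyt, nuc, pseudo = 0)
    expect_equal(unname(r), c(2, 0))
    # swapping compartments negates the index
    expect_equal(rci(nuc, cyt, pseudo = 0), -r)
    expect_equal(unname(rci(cyt, cyt)), c(0, 0))
    bad <- nuc
    rownames(bad) <- c("l1", "lX")
    expect_error(rci(cyt, bad), "share features")
})
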