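test_that("differential expression: identities and forced arithmetic", {
    set.seed(1)
    counts <- matrix(rnbinom(40 * 12, mu = 100, size = 10), 40, 12,
                     dimnames = list(paste0("g", 1:40), paste0("s", 1:12)))
    A <- paste0("s", 1:6)
    B <- paste0("s", 7:12)
    # duplicated groups: log2FC identically zero
    dup <- cbind(counts[, A], counts[, A])
    colnames(dup) <- paste0("s", 1:12)
    degDup <- differentialExpression(dup, A, B)
    expect_true(all(degDup$log2FC == 0))
    # mean CPM 40 vs 10 with pseudo 0 gives log2FC exactly 2
    c2 <- rbind(target = c(rep(10L, 3), rep(40L, 3)),
                fill = rep(1e6L - c(rep(10L, 3), rep(40L, 3))))
    colnames(c2) <- paste0("s", 1:6)
    deg2 <- differentialExpression(c2, paste0("s", 1:3), paste0("s", 4:6),
                                   pseudo = 0)
    expect_equal(deg2$log2FC[deg2$feature == "target"], 2)
    expect_error(differentialExpression(counts, A[1], B), ">= 2 samples")
    expect_error(differentialExpression(counts, A, A), "disjoint")
})

test_that("Welch DEG p-values are calibrated on null NB counts", {
    set.seed(2)
    counts <- matrix(rnbinom(2000 * 40, mu = 200, size = 10), 2000, 40,
                     dimnames = list(paste0("g", 1:2000), paste0("s", 1:40)))
    deg <- differentialExpression(counts, paste0("s", 1:20),
                                  paste0("s", 21:40))
    expect_gt(mean(deg$p < 0.05), 0.03)
    expect_lt(mean(deg$p < 0.05), 0.07)
})

test_that("ranking by log2FC is deterministic with documented tie rule", {
    deg <- data.frame(feature = c("g1", "g2", "g3", "gB", "gA"),
                      log2FC = c(2, -1, 0, 0, 0), p = 0.5, q = 0.5)
    r <- rankByLogFC(deg)
    expect_identical(names(r), c("g1", "g3", "gA", "gB", "g2"))
    # reversing group labels reverses the ranking exactly
    set.seed(3)
    counts <- matrix(rnbinom(30 * 10, mu = 150, size = 8), 30, 10,
                     dimnames = list(paste0("g", 1:30), paste0("s", 1:10)))
    A <- paste0("s", 1:5); B <- paste0("s", 6:10)
    fwd <- differentialExpression(counts, A, B)
    rev <- differentialExpression(counts, B, A)
    expect_equal(fwd$log2FC, -rev$log2FC)
    expect_identical(names(rankByLogFC(fwd)),
                     base::rev(names(rankByLogFC(rev))))
})

test_that("GSEA ES equals the hand-enumerated running sum on 4 features", {
    s <- stats::setNames(c(4, 3, 2, 1), c("a", "b", "c", "d"))
    # set = top two features, unweighted: running sum is
    # (1/2, 1, 1/2, 0) -> maximum deviation ES = 1
    r <- gseaPreranked(s, list(S = c("a", "b")), weight = 0, nPerm = 50,
                       seed = 1)
    expect_equal(r$ES, 1)
    # bottom two features mirror it: running sum (-1/2, -1, -1/2, 0)
    rb <- gseaPreranked(s, list(S = c("c", "d")), weight = 0, nPerm = 50,
                        seed = 1)
    expect_equal(rb$ES, -1)
    # weighted case, set {a, c}: increments 4/6 then 2/6
    rw <- gseaPreranked(s, list(S = c("a", "c")), weight = 1, nPerm = 50,
                        seed = 1)
    expect_equal(rw$ES, max(4 / 6, 4 / 6 - 1 / 2 + 2 / 6))
})

test_that("GSEA ES matches the independent brute-force oracle exactly", {
    set.seed(4)
    for (i in 1:60) {
        N <- sample(6:20, 1)
        m <- sample(2:(N - 2), 1)
        s <- stats::setNames(rnorm(N), paste0("f", 1:N))
        gs <- sample(names(s), m)
        w <- sample(c(0, 1, 1.5), 1)
        r <- gseaPreranked(s, list(S = gs), weight = w, nPerm = 5, seed = i)
        so <- s[order(-s, names(s))]
        oracle <- bruteGseaES(so, names(so) %in% gs, w)
        if (abs(abs(r$ES) - abs(oracle)) < 1e-12 &&
            abs(r$ES - oracle) > 1e-12) {
            # exact magnitude tie between the two extrema: sign is a
            # documented tie-break, magnitude must still agree
            expect_equal(abs(r$ES), abs(oracle), tolerance = 1e-12)
        } else {
            expect_equal(r$ES, oracle, tolerance = 1e-12)
        }
    }
})

test_that("GSEA agrees with fgsea on the enrichment statistic", {
    skip_if_not_installed("fgsea")
    set.seed(5)
    s <- sort(stats::setNames(rnorm(50), paste0("f", 1:50)),
              decreasing = TRUE)
    gs <- list(S1 = paste0("f", c(1, 3, 5, 7, 11)),
               S2 = paste0("f", c(44, 46, 48, 50)))
    mine <- gseaPreranked(s, gs, weight = 1, nPerm = 10, seed = 1)
    ref <- vapply(gs, function(g)
        fgsea::calcGseaStat(s, which(names(s) %in% g)), numeric(1))
    expect_equal(mine$ES, unname(ref), tolerance = 1e-10)
})

test_that("GSEA is deterministic and nulls are calibrated", {
    set.seed(6)
    s <- stats::setNames(rnorm(120), paste0("f", 1:120))
    gs <- list(S = sample(names(s), 15))
    a <- gseaPreranked(s, gs, nPerm = 300, seed = 42)
    b <- gseaPreranked(s, gs, nPerm = 300, seed = 42)
    expect_identical(a, b)
    # decoy sets: |NES| centers near 1, permutation p is superuniform
    ps <- vapply(1:40, function(i) {
        set.seed(i)
        gsi <- list(S = sample(names(s), 12))
        r <- gseaPreranked(s, gsi, nPerm = 120, seed = i)
        c(r$NES, r$p)
    }, numeric(2))
    expect_lt(abs(mean(abs(ps[1, ])) - 1), 0.15)
    expect_lte(mean(ps[2, ] <= 0.05), 0.05 + 3 * sqrt(0.05 * 0.95 / 40))
    # small sets are skipped with a warning
    expect_warning(gseaPreranked(s, list(tiny = "f1"), nPerm = 10),
                   "skipped")
})

test_that("consistent DEG selection is a strict conjunction", {
    mk <- function(fc32, fc21, q = 1e-6) {
        data.frame(feature = paste0("g", seq_along(fc32)),
                   log2FC = log2(fc32), p = q, q = q)
    }
    d32 <- mk(c(2.0, 1.5, 2.0, 0.5, 0.65), c(1, 1, 1, 1, 1))
    d21 <- mk(c(1.8, 2.0, 1.0, 0.6, 0.69), c(1, 1, 1, 1, 1))
    sel <- consistentDegSelection(d32, d21)
    expect_identical(sel$up, "g1")        # g2 is at FC = 1.5 exactly in 3v2
    expect_identical(sel$down, c("g4", "g5"))
    # swapping the comparisons swaps nothing here but mismatched universes err
    expect_error(consistentDegSelection(d32, d21[1:3, ]), "universe")
})

test_that("DEG selection pipeline is label-equivariant", {
    set.seed(7)
    counts <- matrix(rnbinom(200 * 30, mu = 150, size = 5), 200, 30,
                     dimnames = list(paste0("g", 1:200), paste0("s", 1:30)))
    counts[1:10, 21:30] <- counts[1:10, 21:30] * 4L     # up in cluster 3
    g1 <- paste0("s", 1:10); g2 <- paste0("s", 11:20); g3 <- paste0("s", 21:30)
    selFwd <- consistentDegSelection(
        differentialExpression(counts, g2, g3),
        differentialExpression(counts, g1, g2), qMax = 0.01)
    selRev <- consistentDegSelection(
        differentialExpression(counts, g2, g1),
        differentialExpression(counts, g3, g2), qMax = 0.01)
    expect_identical(selFwd$up, selRev$down)
    expect_identical(selFwd$down, selRev$up)
})

test_that("planted monotone genes are selected with high sensitivity", {
    sens <- vapply(1:3, function(seed) {
        set.seed(seed)
        n <- 120
        cl <- rep(1:3, each = n / 3)
        counts <- matrix(rnbinom(300 * n, mu = 150, size = 10), 300, n,
                         dimnames = list(paste0("g", 1:300), paste0("s", 1:n)))
        # 20 genes doubling per cluster step
        planted <- paste0("g", 1:20)
        counts[planted, ] <- t(t(counts[planted, ]) * 2^(cl - 1))
        deg32 <- differentialExpression(counts, paste0("s", which(cl == 2)),
                                        paste0("s", which(cl == 3)))
        deg21 <- differentialExpression(counts, paste0("s", which(cl == 1)),
                                        paste0("s", which(cl == 2)))
        sel <- consistentDegSelection(deg32, deg21)
        mean(planted %in% sel$up)
    }, numeric(1))
    expect_gte(mean(sens), 0.9)
})

test_that("NB exact-test DEG variant runs when edgeR is available", {
    skip_if_not_installed("edgeR")
    set.seed(8)
    counts <- matrix(rnbinom(100 * 12, mu = 120, size = 8), 100, 12,
                     dimnames = list(paste0("g", 1:100), paste0("s", 1:12)))
    counts[1:5, 7:12] <- counts[1:5, 7:12] * 6L
    deg <- differentialExpression(counts, paste0("s", 1:6),
                                  paste0("s", 7:12), method = "nb")
    expect_true(all(deg$q[1:5] < 0.05))
})
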