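# Correlation-based selection of glycolysis-associated lncRNAs, the
# first-order partial correlation used to quantify lncRNA-glycolysis-gene
# linkage, and the covariate-adjusted regression screen.

#' Per-feature Pearson correlation with a sample score, with BH FDR
#'
#' Correlates every requested feature's expression with a per-sample score;
#' two-sided p-values from the t distribution with n - 2 degrees of
#' freedom; q-values by Benjamini-Hochberg across the tested features.
#' Zero-variance features get \code{r = NA}, are excluded from the BH
#' adjustment, and are reported with a message.
#'
#' @param score named numeric vector (one value per sample)
#' @param expr expression matrix (samples in columns) aligned with
#'   \code{score}
#' @param features feature ids to test (default: all rows of \code{expr})
#' @return data.frame with columns \code{feature}, \code{r}, \code{p},
#'   \code{q}, \code{n}
#' @export
pearsonWithFDR <- function(score, expr, features = rownames(expr)) {
    if (!all(features %in% rownames(expr)))
        stop("features missing from expression matrix")
    expr <- expr[features, , drop = FALSE]
    if (!is.null(names(score))) {
        if (!setequal(names(score), colnames(expr)))
            stop("score and expression samples do not match")
        score <- score[colnames(expr)]
    }
    n <- length(score)
    if (n < 4) stop("need at least 4 aligned samples")
    x <- sweep(expr, 1, rowMeans(expr))
    s <- score - mean(score)
    denom <- sqrt(rowSums(x^2) * sum(s^2))
    r <- as.vector(x %*% s) / denom
    r[!is.finite(r)] <- NA
    r <- pmin(1, pmax(-1, r))
    tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
    q <- rep(NA_real_, length(p))
    ok <- !is.na(r)
    q[ok] <- stats::p.adjust(p[ok], method = "BH")
    if (any(!ok))
        message(sum(!ok), " zero-variance feature(s) excluded from FDR adjustment")
    data.frame(feature = features, r = r, p = p, q = q, n = n,
               stringsAsFactors = FALSE)
}

#' Select glycolysis-associated lncRNAs
#'
#' Keeps features with \code{|r| > rMin} (strict) and \code{q < qMax}
#' (strict), carrying the correlation sign.
#'
#' @param table association table from [pearsonWithFDR()]
#' @param rMin absolute correlation threshold (default 0.3)
#' @param qMax FDR threshold (default 0.05)
#' @return data.frame with columns \code{feature}, \code{r}, \code{q},
#'   \code{sign}
#' @export
selectGlycolysisLncRNAs <- function(table, rMin = 0.3, qMax = 0.05) {
    keep <- !is.na(table$r) & abs(table$r) > rMin & !is.na(table$q) &
        table$q < qMax
    out <- table[keep, c("feature", "r", "q")]
    out$sign <- sign(out$r)
    rownames(out) <- NULL
    out
}

#' First-order partial correlation
#'
#' Correlation between x and y after removing the linear effect of a single
#' conditioning variable z:
#' \deqn{r_{xy.z} = (r_{xy} - r_{xz} r_{yz}) / \sqrt{(1 - r_{xz}^2)(1 - r_{yz}^2)}}
#' Either pass the three pairwise correlations, or pass raw vectors via
#' \code{x}, \code{y}, \code{z} and the correlations are computed. Equals
#' the Pearson correlation of the residuals of \code{x ~ z} and
#' \code{y ~ z}.
#'
#' @param rxy,rxz,ryz pairwise Pearson correlations
#' @param x,y,z optional raw vectors (aligned samples, n >= 4); when given
#'   they override the correlation arguments
#' @return the partial correlation, a real in [-1, 1]
#' @export
partialCorrelation <- function(rxy, rxz, ryz, x = NULL, y = NULL, z = NULL) {
    if (!is.null(x)) {
        if (length(unique(c(length(x), length(y), length(z)))) != 1)
            stop("x, y, z must be aligned on identical samples")
        if (length(x) < 4) stop("need n >= 4 samples")
        rxy <- stats::cor(x, y); rxz <- stats::cor(x, z); ryz <- stats::cor(y, z)
    }
    if (abs(rxz) > 1 - 1e-12 || abs(ryz) > 1 - 1e-12)
        stop("degenerate conditioning: |correlation with z| = 1")
    (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2))
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' D is the supremum distance between the two empirical CDFs; the p-value
#' uses the asymptotic Kolmogorov distribution (adequate at the gene-list
#' sizes involved; no exact small-sample tables).
#'
#' @param a,b numeric vectors (non-empty)
#' @return list with elements \code{D} and \code{p}
#' @export
ksTwoSample <- function(a, b) {
    if (!length(a) || !length(b)) stop("empty input")
    kt <- suppressWarnings(stats::ks.test(a, b, exact = FALSE))
    list(D = unname(kt$statistic), p = kt$p.value)
}

#' Shift of score-gene correlations after conditioning on one lncRNA
#'
#' For each gene (pre-restricted by the caller to those positively
#' associated with the score), computes the raw Pearson correlation between
#' the glycolysis score and the gene's expression and the first-order
#' partial correlation conditioned on the lncRNA, then compares the two
#' coefficient distributions with a two-sample Kolmogorov-Smirnov test. A
#' leftward shift of the adjusted distribution indicates that the lncRNA
#' mediates part of the score-gene coexpression.
#'
#' @param score named numeric score vector
#' @param geneExpr expression matrix of the genes to test (samples in
#'   columns)
#' @param lncExpr numeric vector, the conditioning lncRNA's expression
#' @return list with \code{raw} and \code{adjusted} named coefficient
#'   vectors, \code{D} and \code{p} from the KS comparison
#' @export
partialCorrelationShift <- function(score, geneExpr, lncExpr) {
    if (nrow(geneExpr) < 10)
        warning("fewer than 10 genes; KS comparison will have little power")
    if (!is.null(names(score)) && !is.null(colnames(geneExpr))) {
        geneExpr <- geneExpr[, names(score), drop = FALSE]
        if (!is.null(names(lncExpr))) lncExpr <- lncExpr[names(score)]
    }
    rxz <- stats::cor(score, lncExpr)
    if (abs(rxz) > 1 - 1e-12)
        stop("degenerate conditioning: |correlation with z| = 1")
    raw <- apply(geneExpr, 1, stats::cor, y = score)
    ryz <- apply(geneExpr, 1, stats::cor, y = lncExpr)
    if (any(abs(ryz) > 1 - 1e-12))
        stop("degenerate conditioning: |correlation with z| = 1")
    adjusted <- (raw - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2))
    ks <- ksTwoSample(raw, adjusted)
    list(raw = raw, adjusted = adjusted, D = ks$D, p = ks$p)
}

#' Covariate-adjusted gene-lncRNA association
#'
#' Fits \code{gene ~ lncRNA + cnv + methylation} by least squares per gene,
#' with every variable standardized to unit variance first, so the lncRNA
#' coefficient is a partial-correlation-scale quantity comparable to an
#' absolute-correlation threshold. p-values from the coefficient t-test; q
#' by BH across genes; selection by \code{|coef| > coefMin} and
#' \code{q < qMax}, both strict.
#'
#' @param geneExpr matrix of gene expression (genes x samples)
#' @param lncExpr numeric vector (the lncRNA)
#' @param cnvRow,methRow numeric covariate vectors aligned with samples
#' @param coefMin,qMax selection thresholds (defaults 0.3 and 1e-6)
#' @return data.frame with columns \code{feature}, \code{coefficient},
#'   \code{p}, \code{q}, \code{selected}
#' @export
multivariateAdjustedAssociation <- function(geneExpr, lncExpr, cnvRow,
                                            methRow, coefMin = 0.3,
                                            qMax = 1e-6) {
    n <- ncol(geneExpr)
    if (n <= 5) stop("need more than 5 samples")
    Z <- cbind(lncRNA = as.numeric(scale(lncExpr)),
               cnv = as.numeric(scale(cnvRow)),
               meth = as.numeric(scale(methRow)))
    X <- cbind(1, Z)
    kap <- kappa(X, exact = TRUE)
    if (!is.finite(kap) || kap > 1e8) {
        cm <- abs(stats::cor(Z))
        diag(cm) <- 0
        worst <- which(cm == max(cm), arr.ind = TRUE)[1, ]
        stop(sprintf("collinear covariates: %s and %s (condition number %.3g)",
                     colnames(Z)[worst[1]], colnames(Z)[worst[2]], kap))
    }
    Y <- t(scale(t(geneExpr)))          # standardize each gene
    XtXinv <- solve(crossprod(X))
    B <- XtXinv %*% crossprod(X, t(Y))  # 4 x genes
    res <- t(Y) - X %*% B
    df <- n - ncol(X)
    sigma2 <- colSums(res^2) / df
    seB <- sqrt(XtXinv[2, 2] * sigma2)
    coef <- B[2, ]
    tstat <- coef / seB
    p <- 2 * stats::pt(-abs(tstat), df = df)
    q <- stats::p.adjust(p, method = "BH")
    data.frame(feature = rownames(geneExpr), coefficient = coef, p = p,
               q = q, selected = abs(coef) > coefMin & q < qMax,
               row.names = NULL, stringsAsFactors = FALSE)
}
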