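# The genomic classifier: pooled-reference quantile normalization, the
# lasso multinomial logistic model (glmnet path + proximal-gradient
# refinement to a verified KKT tolerance) and label transfer to external
# expression data.

#' Pooled-reference quantile normalization
#'
#' Every sample's sorted values are replaced by the mean sorted profile
#' across all samples of all supplied matrices (samples in columns). Ties
#' (average ranks) are resolved by averaging the reference values of the
#' tied rank positions. The reference is returned so new samples can later
#' be projected onto the same distribution with [projectQuantiles()].
#'
#' @param ... matrices sharing the same feature rows (e.g. an RNA-Seq and a
#'   microarray cohort)
#' @return list with \code{matrices} (the normalized inputs, in order) and
#'   \code{reference} (the mean sorted profile)
#' @export
quantileNormalize <- function(...) {
    mats <- list(...)
    if (!length(mats)) stop("no matrices supplied")
    nf <- unique(vapply(mats, nrow, integer(1)))
    if (length(nf) != 1) stop("matrices must share the feature space")
    feats <- lapply(mats, rownames)
    if (!all(vapply(feats, identical, logical(1), feats[[1]])))
        stop("matrices must share the feature space")
    pooled <- do.call(cbind, mats)
    reference <- rowMeans(apply(pooled, 2, sort))
    out <- lapply(mats, projectQuantiles, reference = reference)
    list(matrices = out, reference = reference)
}

#' Project samples onto a quantile reference
#'
#' @param x matrix (features x samples)
#' @param reference sorted reference profile of length \code{nrow(x)}
#' @return matrix of the same shape with each column mapped onto the
#'   reference distribution
#' @export
projectQuantiles <- function(x, reference) {
    if (nrow(x) != length(reference))
        stop("reference length must equal the number of features")
    out <- apply(x, 2, function(col) {
        r <- rank(col, ties.method = "average")
        (reference[floor(r)] + reference[ceiling(r)]) / 2
    })
    dimnames(out) <- dimnames(x)
    out
}

#' @noRd
.softmaxProb <- function(eta) {
    eta <- eta - matrixStats::rowMaxs(eta)
    p <- exp(eta)
    p / rowSums(p)
}

# Mean negative multinomial log-likelihood (deviance / 2 / N)
#' @noRd
.multinomialLoss <- function(Xs, Y, beta, b0) {
    eta <- sweep(Xs %*% beta, 2, b0, "+")
    P <- .softmaxProb(eta)
    -mean(rowSums(Y * log(pmax(P, 1e-300))))
}

# Gradient of the loss wrt (beta, b0)
#' @noRd
.multinomialGrad <- function(Xs, Y, beta, b0) {
    eta <- sweep(Xs %*% beta, 2, b0, "+")
    P <- .softmaxProb(eta)
    list(G = crossprod(Xs, P - Y) / nrow(Xs), g0 = colMeans(P - Y))
}

# Max KKT residual of the L1-penalized problem at (beta, b0)
#' @noRd
.kktResidual <- function(Xs, Y, beta, b0, lambda) {
    gr <- .multinomialGrad(Xs, Y, beta, b0)
    zero <- beta == 0
    vZero <- if (any(zero)) max(abs(gr$G[zero]) - lambda, 0) else 0
    vNz <- if (any(!zero)) max(abs(gr$G[!zero] + lambda * sign(beta[!zero]))) else 0
    max(vZero, vNz, abs(gr$g0))
}

# FISTA refinement of a warm-started solution until the KKT residual drops
# below tol. The softmax loss gradient is Lipschitz with constant bounded
# by lambda_max(X'X) / (2N), which gives a safe fixed step size.
#' @noRd
.proximalPolish <- function(Xs, Y, beta, b0, lambda, tol = 1e-6,
                            maxIter = 20000L) {
    N <- nrow(Xs)
    L <- max(eigen(crossprod(Xs) / N, symmetric = TRUE,
                   only.values = TRUE)$values) / 2
    L <- max(L, 1e-8)
    soft <- function(x, t) sign(x) * pmax(abs(x) - t, 0)
    yb <- beta; yb0 <- b0; tAcc <- 1
    betaPrev <- beta; b0Prev <- b0
    for (it in seq_len(maxIter)) {
        gr <- .multinomialGrad(Xs, Y, yb, yb0)
        betaNew <- soft(yb - gr$G / L, lambda / L)
        b0New <- yb0 - gr$g0 / L
        tNew <- (1 + sqrt(1 + 4 * tAcc^2)) / 2
        yb <- betaNew + ((tAcc - 1) / tNew) * (betaNew - betaPrev)
        yb0 <- b0New + ((tAcc - 1) / tNew) * (b0New - b0Prev)
        betaPrev <- betaNew; b0Prev <- b0New; tAcc <- tNew
        if (it %% 10 == 0 &&
            .kktResidual(Xs, Y, betaNew, b0New, lambda) < tol)
            return(list(beta = betaNew, b0 = b0New, iterations = it,
                        converged = TRUE))
    }
    list(beta = betaPrev, b0 = b0Prev, iterations = maxIter,
         converged = .kktResidual(Xs, Y, betaPrev, b0Prev, lambda) < tol)
}

#' @noRd
.classIndicator <- function(labels) {
    f <- as.factor(labels)
    Y <- stats::model.matrix(~ f - 1)
    colnames(Y) <- levels(f)
    Y
}

#' Lasso multinomial path with verified KKT conditions
#'
#' Fits the L1-penalized multinomial logistic model over a decreasing
#' lambda path (glmnet coordinate descent, warm starts), then refines every
#' solution by proximal-gradient (FISTA) steps until the Karush-Kuhn-Tucker
#' residual - \code{|gradient_j| <= lambda} for zero coefficients,
#' \code{gradient_j + lambda sign(beta_j) = 0} for active ones - is below
#' \code{kktTol}. Features are standardized internally; coefficients are on
#' the standardized scale.
#'
#' @param X sample x feature matrix
#' @param labels per-sample class labels
#' @param lambdaGrid decreasing penalty grid; default 100 log-spaced values
#'   from the data-derived lambda_max (smallest lambda zeroing every
#'   feature) down by a factor 1e-4
#' @param kktTol KKT residual tolerance (default 1e-6)
#' @return list with \code{lambda}, per-lambda \code{beta} (feature x class
#'   matrices), \code{b0}, \code{nonzero} (features with any nonzero
#'   class coefficient), \code{kkt} (residuals), \code{loss}, and the
#'   standardization (\code{center}, \code{scale}, \code{classes})
#' @export
lassoMultinomialPath <- function(X, labels, lambdaGrid = NULL,
                                 kktTol = 1e-6) {
    Y <- .classIndicator(labels)
    center <- colMeans(X)
    scl <- apply(X, 2, stats::sd)
    scl[scl == 0] <- 1
    Xs <- sweep(sweep(X, 2, center), 2, scl, "/")
    N <- nrow(Xs)
    if (is.null(lambdaGrid)) {
        P0 <- matrix(colMeans(Y), N, ncol(Y), byrow = TRUE)
        lambdaMax <- max(abs(crossprod(Xs, Y - P0))) / N
        lambdaGrid <- exp(seq(log(lambdaMax), log(lambdaMax * 1e-4),
                              length.out = 100))
    }
    if (!length(lambdaGrid)) stop("lambdaGrid must be non-empty")
    lambdaGrid <- sort(lambdaGrid, decreasing = TRUE)
    glmGrid <- lambdaGrid[lambdaGrid > 0]
    fit <- suppressWarnings(
        glmnet::glmnet(Xs, factor(labels), family = "multinomial",
                       lambda = glmGrid, standardize = FALSE,
                       thresh = 1e-10, maxit = 1e6))
    betas <- vector("list", length(lambdaGrid))
    b0s <- vector("list", length(lambdaGrid))
    kkt <- numeric(length(lambdaGrid))
    loss <- numeric(length(lambdaGrid))
    prevBeta <- NULL; prevB0 <- NULL
    for (i in seq_along(lambdaGrid)) {
        lam <- lambdaGrid[i]
        if (lam > 0) {
            j <- which.min(abs(fit$lambda - lam))
            beta <- do.call(cbind, lapply(fit$beta, function(b)
                as.numeric(b[, j])))
            b0 <- as.numeric(fit$a0[, j])
        } else {
            beta <- if (is.null(prevBeta))
                matrix(0, ncol(Xs), ncol(Y)) else prevBeta
            b0 <- if (is.null(prevB0)) rep(0, ncol(Y)) else prevB0
        }
        # at lambda = 0 the loss gap to the optimum is second order in the
        # gradient, so polish to a much smaller residual there
        polTol <- if (lam == 0) min(kktTol, 1e-9) else kktTol
        pol <- .proximalPolish(Xs, Y, beta, b0, lam, tol = polTol,
                               maxIter = if (lam == 0) 200000L else 20000L)
        if (!pol$converged && .kktResidual(Xs, Y, pol$beta, pol$b0, lam) >
            kktTol)
            stop(sprintf("fit did not converge at lambda = %.4g (KKT residual %.3g)",
                         lam, .kktResidual(Xs, Y, pol$beta, pol$b0, lam)))
        betas[[i]] <- pol$beta; b0s[[i]] <- pol$b0
        prevBeta <- pol$beta; prevB0 <- pol$b0
        kkt[i] <- .kktResidual(Xs, Y, pol$beta, pol$b0, lam)
        loss[i] <- .multinomialLoss(Xs, Y, pol$beta, pol$b0)
    }
    nonzero <- vapply(betas, function(b)
        sum(rowSums(abs(b) > 1e-8) > 0), integer(1))
    list(lambda = lambdaGrid, beta = betas, b0 = b0s, nonzero = nonzero,
         kkt = kkt, loss = loss, center = center, scale = scl,
         classes = colnames(Y), features = colnames(X))
}

#' Fit the lasso multinomial genomic classifier with cross-validation
#'
#' Stratified k-fold cross-validation of the multinomial deviance over the
#' lambda path; the chosen lambda minimizes the mean cross-validated
#' deviance, and the model is refit on all data at that lambda (with KKT
#' verification). The classifier signature is the set of features with a
#' nonzero coefficient in any class.
#'
#' @inheritParams lassoMultinomialPath
#' @param nFolds cross-validation folds (default 10); every class must have
#'   at least \code{nFolds} members
#' @param seed RNG seed for the stratified fold assignment
#' @param quantileReference optional reference from [quantileNormalize()]
#'   (computed on the same feature set as \code{X}), stored so
#'   [predictCluster()] can project new samples
#' @return a [GenomicClassifier-class]
#' @export
fitLassoMultinomialCV <- function(X, labels, nFolds = 10, lambdaGrid = NULL,
                                  seed = 1, quantileReference = numeric(0),
                                  kktTol = 1e-6) {
    labels <- as.factor(labels)
    if (any(table(labels) < nFolds))
        stop("every class needs at least nFolds members")
    path <- lassoMultinomialPath(X, labels, lambdaGrid, kktTol = kktTol)
    foldid <- withSeed(deriveSeed(seed, 11L), {
        fid <- integer(length(labels))
        for (lv in levels(labels)) {
            idx <- sample(which(labels == lv))
            fid[idx] <- rep_len(seq_len(nFolds), length(idx))
        }
        fid
    })
    Xs <- sweep(sweep(X, 2, path$center), 2, path$scale, "/")
    cvGrid <- path$lambda[path$lambda > 0]
    cv <- glmnet::cv.glmnet(Xs, labels, family = "multinomial",
                            lambda = cvGrid, foldid = foldid,
                            type.measure = "deviance", standardize = FALSE,
                            thresh = 1e-10, maxit = 1e6)
    lambdaMin <- cv$lambda[which.min(cv$cvm)]
    i <- which.min(abs(path$lambda - lambdaMin))
    cvCurve <- data.frame(lambda = cv$lambda, cvm = cv$cvm, cvsd = cv$cvsd,
                          nonzero = path$nonzero[match(cv$lambda, path$lambda)])
    model <- new("GenomicClassifier",
                 features = colnames(X),
                 coefficients = {
                     b <- path$beta[[i]]
                     dimnames(b) <- list(colnames(X), path$classes)
                     b
                 },
                 intercepts = path$b0[[i]],
                 classes = path$classes,
                 lambda = path$lambda[i],
                 center = path$center,
                 scale = path$scale,
                 quantileReference = quantileReference,
                 cvCurve = cvCurve)
    validObject(model)
    model
}

#' Transfer cluster labels to new expression data
#'
#' Optionally projects each new sample's profile onto the classifier's
#' stored quantile reference (recommended when the new data come from a
#' different platform), then applies the fitted multinomial model. Ties in
#' the class probabilities resolve to the lowest class id.
#'
#' @param model a [GenomicClassifier-class]
#' @param XNew sample x feature matrix containing all model features
#' @param normalize project onto the stored quantile reference (default
#'   TRUE when a reference is stored)
#' @return list with \code{probabilities} (sample x class, rows sum to 1)
#'   and \code{labels} (character class ids)
#' @export
predictCluster <- function(model, XNew,
                           normalize = length(model@quantileReference) > 0) {
    missing <- setdiff(model@features, colnames(XNew))
    if (length(missing))
        stop("missing model feature(s): ", paste(missing, collapse = ", "))
    XNew <- XNew[, model@features, drop = FALSE]
    if (normalize) {
        if (!length(model@quantileReference))
            stop("model stores no quantile reference")
        XNew <- t(projectQuantiles(t(XNew), model@quantileReference))
    }
    Xs <- sweep(sweep(XNew, 2, model@center), 2, model@scale, "/")
    eta <- sweep(Xs %*% model@coefficients, 2, model@intercepts, "+")
    P <- .softmaxProb(eta)
    dimnames(P) <- list(rownames(XNew), model@classes)
    labels <- model@classes[apply(P, 1, which.max)]
    list(probabilities = P, labels = stats::setNames(labels, rownames(XNew)))
}
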