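## Soft-threshold operator.
.soft <- function(x, t) sign(x) * pmax(abs(x) - t, 0)

## Pooled within-class standard deviations, floored at median(sigma) * 1e-3
## so dropout-heavy genes cannot blow up the scaling.
.pooledWithinSd <- function(X, labels) {
    n <- nrow(X)
    classes <- sort(unique(labels))
    ss <- 0
    for (k in classes) {
        idx <- labels == k
        ck <- sweep(X[idx, , drop = FALSE], 2L,
                    colMeans(X[idx, , drop = FALSE]))
        ss <- ss + colSums(ck^2)
    }
    sig <- sqrt(ss / (n - length(classes)))
    floorVal <- stats::median(sig[sig > 0]) * 1e-3
    if (!is.finite(floorVal) || floorVal <= 0)
        stop("all features have zero within-class variance")
    pmax(sig, floorVal)
}

#' Fit a penalized linear discriminant model
#'
#' Fisher discriminant analysis with a lasso penalty, fitted directly on the
#' between-class covariance of within-class-standardized expression. With
#' cells as observations and classes A/B/C, features are first scaled by
#' pooled within-class standard deviations (floored; see Details); the
#' between-class matrix is
#' \eqn{\Sigma_b = n^{-1} \sum_k n_k (\bar x_k - \bar x)(\bar x_k - \bar x)'}
#' on the scaled data. Each discriminant vector maximizes
#' \eqn{\beta' \Sigma_b \beta - \lambda \|\beta\|_1} subject to
#' \eqn{\|\beta\|_2 \le 1}, solved by iterating a soft-threshold of
#' \eqn{\Sigma_b \beta} (at \eqn{\lambda/2}) followed by renormalization, a
#' majorize-maximize scheme whose objective never decreases. Later axes are
#' found after deflating \eqn{\Sigma_b} orthogonally to the earlier
#' discriminant vectors. At `lambda = 0` the axes coincide with the leading
#' eigenvectors of \eqn{\Sigma_b}. The sign of each axis is fixed so its
#' largest-magnitude loading is positive.
#'
#' @details The fit standardizes every feature by its pooled within-class
#' standard deviation, so it is applied to the normalized expression values
#' directly by default; `transform = "log10"` fits on log10(normalized + 1)
#' instead. \eqn{\Sigma_b} has rank at most K - 1, so it is held in
#' factored form and never densified; fits over thousands of genes are
#' cheap. If the penalty removes every coordinate of an axis, the axis is
#' recorded as degenerate (all-zero loadings) with a warning.
#'
#' @param x gene x cell matrix of normalized expression restricted to the
#'   gene universe of interest.
#' @param labels class label per cell (clades "A"/"B"/"C"; any labels work).
#' @param lambda lasso penalty, >= 0 (default 0.05).
#' @param nAxes number of discriminant axes (default 2 = K - 1 for three
#'   classes).
#' @param transform `"none"` (default: fit on normalized values) or
#'   `"log10"` (fit on log10(normalized + 1)).
#' @param tol relative-change convergence tolerance (default 1e-6).
#' @param maxIter maximum iterations per axis (default 500).
#' @return A [DiscriminantModel-class].
#' @seealso [predictClade()], [rankLoadings()], [sparseRefit()],
#'   [crossValidate()]
#' @export
fitPLDA <- function(x, labels, lambda = 0.05, nAxes = 2L,
                    transform = c("none", "log10"),
                    tol = 1e-6, maxIter = 500L) {
    transform <- match.arg(transform)
    if (lambda < 0) stop("lambda must be >= 0")
    X <- t(.applyTransform(as.matrix(x), transform))  # cells x genes
    if (is.null(colnames(X))) stop("x must carry gene names")
    labels <- as.character(labels)
    if (length(labels) != nrow(X))
        stop("one label per cell required")
    classes <- sort(unique(labels))
    if (length(classes) < 2L) stop("need at least 2 classes")
    tab <- table(labels)
    if (any(tab < 2L))
        stop("every class needs at least 2 cells; offending: ",
             paste(names(tab)[tab < 2L], collapse = ", "))
    n <- nrow(X); p <- ncol(X)

    sig <- .pooledWithinSd(X, labels)
    mu <- colMeans(X)
    Xs <- sweep(sweep(X, 2L, mu), 2L, sig, "/")
    ## Sigma_b = t(M) %*% M with M the sqrt(n_k/n)-weighted scaled class
    ## mean deviations (K x p)
    M <- do.call(rbind, lapply(classes, function(k) {
        idx <- labels == k
        sqrt(sum(idx) / n) * colMeans(Xs[idx, , drop = FALSE])
    }))

    V <- matrix(0, nrow = p, ncol = nAxes)
    traces <- vector("list", nAxes)
    converged <- logical(nAxes)
    degenerate <- integer(0)
    Mdef <- M
    for (a in seq_len(nAxes)) {
        if (a > 1L) {
            u <- V[, a - 1L]
            if (sum(u^2) > 0) {
                u <- u / sqrt(sum(u^2))
                Mdef <- Mdef - (Mdef %*% u) %*% t(u)
            }
        }
        sv <- svd(Mdef, nu = 0, nv = 1L)
        if (sv$d[1L] < 1e-12) {
            warning("axis ", a, " has no between-class variance left; ",
                    "degenerate axis")
            degenerate <- c(degenerate, a)
            traces[[a]] <- 0
            converged[a] <- TRUE
            next
        }
        beta <- sv$v[, 1L]
        obj <- numeric(0)
        for (it in seq_len(maxIter)) {
            sb <- drop(crossprod(Mdef, Mdef %*% beta))
            betaNew <- .soft(sb, lambda / 2)
            nrm <- sqrt(sum(betaNew^2))
            if (nrm == 0) {
                beta <- betaNew
                obj <- c(obj, 0)
                converged[a] <- TRUE
                break
            }
            betaNew <- betaNew / nrm
            sbNew <- drop(Mdef %*% betaNew)
            obj <- c(obj, sum(sbNew^2) - lambda * sum(abs(betaNew)))
            delta <- sqrt(sum((betaNew - beta)^2)) /
                max(sqrt(sum(beta^2)), 1e-12)
            beta <- betaNew
            if (delta < tol) {
                converged[a] <- TRUE
                break
            }
        }
        if (!converged[a])
            warning("axis ", a, " did not converge in ", maxIter,
                    " iterations (last relative change above tol); ",
                    "final objective ", signif(obj[length(obj)], 6))
        if (all(beta == 0)) {
            warning("penalty removed every loading on axis ", a,
                    "; degenerate axis")
            degenerate <- c(degenerate, a)
        } else {
            ## sign convention: largest-|loading| entry positive
            top <- which.max(abs(beta))
            if (beta[top] < 0) beta <- -beta
        }
        V[, a] <- beta
        traces[[a]] <- obj
    }

    Z <- Xs %*% V
    centroids <- do.call(rbind, lapply(classes, function(k)
        colMeans(Z[labels == k, , drop = FALSE])))

    new("DiscriminantModel",
        featureIds = colnames(X),
        classLabels = classes,
        lambda = lambda,
        withinScales = unname(sig),
        featureMeans = unname(mu),
        loadings = unname(V),
        classCentroids = unname(centroids),
        transform = transform,
        objectiveTrace = traces,
        converged = converged,
        degenerateAxes = degenerate)
}

#' Project cells into discriminant space
#'
#' @param model a [DiscriminantModel-class].
#' @param x gene x cell normalized expression covering the model's features.
#' @return Cell x axis matrix of discriminant coordinates.
#' @export
discriminantScores <- function(model, x) {
    x <- as.matrix(x)
    missing <- setdiff(model@featureIds, rownames(x))
    if (length(missing))
        stop("feature(s) absent from new data: ",
             paste(utils::head(missing, 5L), collapse = ", "),
             if (length(missing) > 5L) ", ...")
    X <- t(.applyTransform(x[model@featureIds, , drop = FALSE],
                           model@transform))
    Xs <- sweep(sweep(X, 2L, model@featureMeans), 2L,
                model@withinScales, "/")
    Z <- Xs %*% model@loadings
    rownames(Z) <- colnames(x)
    colnames(Z) <- paste0("V", seq_len(ncol(Z)))
    Z
}

#' Predict class labels with a fitted discriminant model
#'
#' Scales and projects new cells with the training parameters and assigns
#' each to the nearest class centroid in discriminant space (Euclidean
#' distance, uniform priors); exact ties are broken by class label order.
#'
#' @param model a [DiscriminantModel-class].
#' @param x gene x cell normalized expression covering the model's features.
#' @return Named character vector of predicted class labels.
#' @export
predictClade <- function(model, x) {
    Z <- discriminantScores(model, x)
    cen <- model@classCentroids
    d2 <- vapply(seq_len(nrow(cen)), function(k)
        rowSums(sweep(Z, 2L, cen[k, ])^2), numeric(nrow(Z)))
    d2 <- matrix(d2, nrow = nrow(Z))
    ## max.col(ties.method = "first") on negated distances respects the
    ## fixed class order for exact ties
    pick <- max.col(-d2, ties.method = "first")
    stats::setNames(model@classLabels[pick], rownames(Z))
}

#' Rank loadings and build a sparse gene panel
#'
#' Sorts each discriminant axis by absolute loading (ties broken by gene
#' id), takes the top `topK` nonzero-loading genes per axis and forms their
#' union, the reduced feature set used for the sparse refit.
#'
#' @param model a fitted [DiscriminantModel-class].
#' @param topK genes per axis (default 20, giving the familiar 40-gene
#'   union over two axes when the axes share no genes).
#' @return A [SparsePanel-class].
#' @export
rankLoadings <- function(model, topK = 20L) {
    topK <- as.integer(topK)
    V <- model@loadings
    perAxis <- vector("list", ncol(V))
    for (a in seq_len(ncol(V))) {
        lv <- abs(V[, a])
        nz <- which(lv > 0)
        if (!length(nz)) {
            warning("axis ", a, " has no nonzero loadings; ",
                    "it contributes nothing to the panel")
            perAxis[[a]] <- character()
            next
        }
        if (length(nz) < topK)
            warning("axis ", a, " has only ", length(nz),
                    " nonzero loadings (< topK = ", topK,
                    "); taking all of them")
        ord <- nz[order(-lv[nz], model@featureIds[nz])]
        perAxis[[a]] <- model@featureIds[utils::head(ord, topK)]
    }
    unionSet <- character(0)
    origin <- integer(0)
    for (a in seq_along(perAxis)) {
        newGenes <- setdiff(perAxis[[a]], unionSet)
        unionSet <- c(unionSet, newGenes)
        origin <- c(origin, rep(a, length(newGenes)))
    }
    new("SparsePanel", perAxis = perAxis, topK = topK,
        unionSet = unionSet, axisOfOrigin = origin)
}

#' Refit the discriminant model on a sparse panel
#'
#' Recomputes the penalized LDA on the reduced feature set of a
#' [SparsePanel-class] (or an explicit gene vector), with the same contract
#' as [fitPLDA()].
#'
#' @param x gene x cell normalized expression (must contain the panel).
#' @param labels class label per cell.
#' @param panel a [SparsePanel-class] or character vector of gene ids.
#' @param lambda lasso penalty (default 0.05, reusing the full-model
#'   penalty).
#' @param ... further arguments to [fitPLDA()].
#' @return A [DiscriminantModel-class] over the panel genes.
#' @export
sparseRefit <- function(x, labels, panel, lambda = 0.05, ...) {
    genes <- if (is(panel, "SparsePanel")) panelGenes(panel) else
        as.character(panel)
    missing <- setdiff(genes, rownames(x))
    if (length(missing))
        stop("panel gene(s) absent from x: ",
             paste(missing, collapse = ", "))
    fitPLDA(x[genes, , drop = FALSE], labels, lambda = lambda, ...)
}

## Stratified fold assignment: cells of each class are shuffled and dealt
## round-robin so every fold sees every class where possible.
.stratifiedFolds <- function(labels, nFolds, seed) {
    .withSeed(seed, {
        fold <- integer(length(labels))
        tab <- table(labels)
        if (any(tab < nFolds))
            warning("class(es) smaller than the fold count (",
                    paste(names(tab)[tab < nFolds], collapse = ", "),
                    "); stratification relaxed, some folds will miss them")
        offset <- 0L
        for (k in sort(unique(labels))) {
            idx <- which(labels == k)
            idx <- idx[sample.int(length(idx))]
            fold[idx] <- ((seq_along(idx) - 1L + offset) %% nFolds) + 1L
            offset <- offset + length(idx)
        }
        fold
    })
}

#' Stratified cross-validation of the sparse discriminant classifier
#'
#' Assigns cells to `nFolds` clade-stratified folds from `seed`. In each
#' fold the full penalized LDA, loading ranking and sparse refit are all
#' recomputed on the training cells only, and the refitted sparse model
#' predicts the held-out cells. When `lambdaGrid` is supplied, the whole
#' procedure is repeated per grid value and the accuracy curve returned,
#' for tuning the penalty.
#'
#' @param x gene x cell normalized expression restricted to the gene
#'   universe.
#' @param labels class label per cell.
#' @param lambda lasso penalty (default 0.05).
#' @param topK panel size per axis used inside each fold (default 20).
#' @param nFolds folds (default 6).
#' @param seed fold-assignment seed.
#' @param lambdaGrid optional numeric vector of penalties to profile.
#' @param ... further arguments to [fitPLDA()].
#' @return A [CVResult-class].
#' @export
crossValidate <- function(x, labels, lambda = 0.05, topK = 20L,
                          nFolds = 6L, seed = 1L, lambdaGrid = NULL, ...) {
    x <- as.matrix(x)
    labels <- as.character(labels)
    nFolds <- as.integer(nFolds)
    if (nFolds < 2L || nFolds > length(labels))
        stop("nFolds must lie in [2, number of cells]")
    fold <- .stratifiedFolds(labels, nFolds, seed)

    runOne <- function(lam) {
        correct <- logical(length(labels))
        perFold <- numeric(nFolds)
        for (f in seq_len(nFolds)) {
            test <- fold == f
            fit <- fitPLDA(x[, !test, drop = FALSE], labels[!test],
                           lambda = lam, ...)
            panel <- suppressWarnings(rankLoadings(fit, topK = topK))
            sparse <- if (length(panelGenes(panel)) >= 2L)
                sparseRefit(x[, !test, drop = FALSE], labels[!test],
                            panel, lambda = lam, ...)
            else fit
            pred <- predictClade(sparse, x[, test, drop = FALSE])
            correct[test] <- pred == labels[test]
            perFold[f] <- mean(pred == labels[test])
        }
        list(acc = mean(correct), perFold = perFold)
    }

    main <- runOne(lambda)
    grid <- numeric(0); gridAcc <- numeric(0)
    if (!is.null(lambdaGrid)) {
        grid <- as.numeric(lambdaGrid)
        gridAcc <- vapply(grid, function(l) runOne(l)$acc, numeric(1))
    }
    new("CVResult",
        nFolds = nFolds,
        foldAssignment = stats::setNames(fold, colnames(x)),
        perFoldAccuracy = main$perFold,
        accuracy = main$acc,
        seed = as.integer(seed),
        lambdaGrid = grid,
        gridAccuracy = gridAcc)
}
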