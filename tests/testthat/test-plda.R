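simpleThreeClass <- function(seed = 1, n = 30, p = 5) {
    set.seed(seed)
    lab <- rep(c("A", "B", "C"), length.out = n)
    x <- matrix(rlnorm(p * n, 2, 0.6), nrow = p,
                dimnames = list(paste0("g", seq_len(p)),
                                paste0("c", seq_len(n))))
    x[1, lab == "A"] <- x[1, lab == "A"] * 30
    x[2, lab == "C"] <- x[2, lab == "C"] * 25
    x[3, lab == "B"] <- x[3, lab == "B"] * 20
    list(x = x, lab = lab)
}

test_that("unpenalized discriminants match the dense eigensolver oracle", {
    for (s in 1:3) {
        for (p in c(3, 6)) {
            d <- simpleThreeClass(seed = s, p = p)
            fit <- fitPLDA(d$x, d$lab, lambda = 0)
            eig <- denseDiscriminantOracle(d$x, d$lab)
            V <- cladeLoadings(fit)
            expect_axis_equal(V[, 1], eig$vectors[, 1], tol = 1e-8)
            expect_axis_equal(V[, 2], eig$vectors[, 2], tol = 1e-8)
            ## at lambda = 0 no loading is forced to zero by thresholding
            expect_true(all(abs(V[, 1]) > 0))
        }
    }
})

test_that("overwhelming penalty yields an all-zero degenerate axis", {
    d <- simpleThreeClass()
    expect_warning(fit <- fitPLDA(d$x, d$lab, lambda = 1e6),
                   "degenerate")
    expect_true(all(cladeLoadings(fit) == 0))
    expect_true(1L %in% fit@degenerateAxes)
})

test_that("the penalized objective never decreases across iterations", {
    sim <- matureSim(seed = 33, nGenes = 400)
    x <- sim$norm[filterExpressed(sim$counts), ]
    for (lam in c(0, 0.05, 0.5)) {
        fit <- fitPLDA(x, sim$labels, lambda = lam)
        for (tr in fit@objectiveTrace) {
            if (length(tr) > 1L)
                expect_true(all(diff(tr) >= -1e-9))
        }
    }
})

test_that("nonzero loadings are non-increasing in lambda", {
    sim <- matureSim(seed = 34, nGenes = 400)
    x <- sim$norm[filterExpressed(sim$counts), ]
    grid <- c(0, 0.02, 0.1, 0.5, 2, 10)
    nz <- vapply(grid, function(l)
        sum(cladeLoadings(suppressWarnings(
            fitPLDA(x, sim$labels, lambda = l)))[, 1] != 0),
        numeric(1))
    expect_true(all(diff(nz) <= 0))
})

test_that("a sparsifying penalty concentrates loading mass on planted genes", {
    sim <- matureSim(seed = 35, nGenes = 1000, nPlanted = 13, log2fc = 3)
    x <- sim$norm[filterExpressed(sim$counts), ]
    ## a penalty on the steep part of the lasso path: most null features
    ## are zeroed and the surviving mass sits on the planted genes
    fit <- suppressWarnings(fitPLDA(x, sim$labels, lambda = 8))
    V <- cladeLoadings(fit)
    mass <- rowSums(abs(V))
    expect_lt(sum(mass > 0), nrow(x) / 10)
    frac <- sum(mass[names(mass) %in% sim$planted]) / sum(mass)
    expect_gte(frac, 0.8)
})

test_that("prediction recovers training labels and breaks ties by order", {
    d <- simpleThreeClass(seed = 4)
    fit <- fitPLDA(d$x, d$lab, lambda = 0)
    expect_equal(unname(predictClade(fit, d$x)), d$lab)
    ## a synthetic cell placed exactly at a centroid is assigned its class
    cen <- classCentroids(fit)
    V <- cladeLoadings(fit)
    ## invert the projection for a point at centroid B (least-norm preimage)
    zb <- cen["B", ]
    pre <- V %*% solve(crossprod(V), zb)
    xb <- pre * fit@withinScales + fit@featureMeans
    xnew <- matrix(xb, ncol = 1, dimnames = list(featureIds(fit), "q"))
    expect_equal(unname(predictClade(fit, xnew)), "B")
    expect_error(predictClade(fit, d$x[-1, , drop = FALSE]), "absent")
})

test_that("held-out accuracy is high on strong-signal simulations", {
    accs <- vapply(1:20, function(s) {
        sim <- matureSim(seed = 200 + s, nGenes = 400, nPlanted = 10,
                         log2fc = 4)
        x <- sim$norm[filterExpressed(sim$counts), ]
        suppressWarnings(
            cvAccuracy(crossValidate(x, sim$labels, nFolds = 6,
                                     seed = s)))
    }, numeric(1))
    expect_gte(mean(accs), 0.95)
})

test_that("loading ranking builds per-axis lists and their union", {
    d <- simpleThreeClass(seed = 6, p = 10)
    fit <- fitPLDA(d$x, d$lab, lambda = 0)
    panel <- rankLoadings(fit, topK = 3)
    expect_length(perAxisGenes(panel), 2L)
    expect_lte(length(panelGenes(panel)), 6L)
    expect_equal(panelGenes(panel),
                 unique(unlist(perAxisGenes(panel))))
    ## per-axis lists are sorted by |loading|
    V <- cladeLoadings(fit)
    for (a in 1:2) {
        g <- perAxisGenes(panel)[[a]]
        expect_true(all(diff(abs(V[g, a])) <= 1e-12))
    }
    ## requesting more genes than nonzero loadings warns
    fitBig <- suppressWarnings(fitPLDA(d$x, d$lab, lambda = 3))
    nz1 <- sum(cladeLoadings(fitBig)[, 1] != 0)
    if (nz1 > 0 && nz1 < 10)
        expect_warning(rankLoadings(fitBig, topK = 10), "nonzero")
})

test_that("sparse refit on all features reproduces the full fit", {
    d <- simpleThreeClass(seed = 7, p = 8)
    fit <- fitPLDA(d$x, d$lab, lambda = 0.05)
    refit <- sparseRefit(d$x, d$lab, rownames(d$x), lambda = 0.05)
    expect_equal(cladeLoadings(refit)[featureIds(fit), ],
                 cladeLoadings(fit))
    ## single-gene panel: one usable axis, the other degenerate
    expect_warning(one <- sparseRefit(d$x, d$lab, "g1", lambda = 0),
                   "degenerate|no between-class")
    expect_equal(length(featureIds(one)), 1L)
    expect_error(sparseRefit(d$x, d$lab, "nope"), "absent")
})

test_that("cross-validation bookkeeping: stratification and leave-one-out", {
    d <- simpleThreeClass(seed = 8, n = 18)
    cv <- crossValidate(d$x, d$lab, nFolds = 6, seed = 3)
    expect_equal(cv@nFolds, 6L)
    expect_length(foldAssignment(cv), 18L)
    ## stratified: every fold carries one cell of each class
    for (f in 1:6)
        expect_equal(sort(d$lab[foldAssignment(cv) == f]),
                     c("A", "B", "C"))
    ## leave-one-out on 6 cells (two classes): 6 folds of 1
    d6 <- simpleThreeClass(seed = 9, n = 6)
    lab6 <- rep(c("A", "B"), 3)
    expect_warning(cv6 <- crossValidate(d6$x, lab6, nFolds = 6,
                                        seed = 1, nAxes = 1L, topK = 2L),
                   "relaxed")
    expect_equal(unname(table(foldAssignment(cv6))), rep(1L, 6),
                 ignore_attr = TRUE)
    expect_error(crossValidate(d$x, d$lab, nFolds = 1), "nFolds")
})

test_that("fit rejects degenerate inputs", {
    d <- simpleThreeClass()
    expect_error(fitPLDA(d$x, d$lab[-1]), "one label per cell")
    expect_error(fitPLDA(d$x, rep("A", 30)), "2 classes")
    expect_error(fitPLDA(d$x, c("B", rep("A", 29))), "at least 2 cells")
    expect_error(fitPLDA(d$x, d$lab, lambda = -1), "lambda")
})
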