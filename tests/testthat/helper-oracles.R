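# Independent oracles and shared fixtures, built in code at test time.

# Exhaustive two-tailed Fisher p for a 2x2 table by direct hypergeometric
# enumeration: sum the probabilities (computed from binomial coefficients)
# of all tables with the observed margins that are no more probable than
# the observed one (relative tolerance for floating-point ties).
fisherOracle <- function(a, b, c, d) {
    r1 <- a + b; r2 <- c + d; c1 <- a + c; n <- a + b + c + d
    support <- max(0, c1 - r2):min(r1, c1)
    prob <- vapply(support, function(k)
        exp(lchoose(r1, k) + lchoose(r2, c1 - k) - lchoose(n, c1)),
        numeric(1))
    pObs <- prob[support == a]
    sum(prob[prob <= pObs * (1 + 1e-7)])
}

# Small simulated dataset restricted to mature OR-expressing cells, with
# normalized expression and truth, shared across tests.
matureSim <- function(seed = 1, nGenes = 600, nCellsPerClade = 10,
                      nPlanted = 10, log2fc = 4, orFrac = 0.95, ...) {
    spec <- SimSpec(nCellsPerClade = nCellsPerClade, nGenes = nGenes,
                    nPlantedMarkersPerClade = nPlanted,
                    plantedLog2Fc = log2fc,
                    predominantOrFraction = orFrac, seed = seed, ...)
    sce <- simulateCells(spec)
    rd <- SummarizedExperiment::rowData(sce)
    mat <- colnames(sce)[sce$stage == "mature_or"]
    counts <- SummarizedExperiment::assay(sce, "counts")[, mat]
    labels <- sce$true_clade[match(mat, colnames(sce))]
    norm <- normalizeCounts(counts)
    list(sce = sce, counts = counts, labels = labels, norm = norm,
         planted = rownames(rd)[!is.na(rd$planted_clade)],
         plantedClade = stats::setNames(
             rd$planted_clade[!is.na(rd$planted_clade)],
             rownames(rd)[!is.na(rd$planted_clade)]),
         orGenes = rownames(rd)[rd$is_or])
}

# Dense eigensolver oracle for the lambda = 0 discriminant directions:
# leading eigenvectors of the between-class matrix of
# within-class-standardized data.
denseDiscriminantOracle <- function(x, labels, transform = "none") {
    X <- t(if (transform == "log10") log10(x + 1) else x)
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
    sig <- pmax(sig, stats::median(sig[sig > 0]) * 1e-3)
    Xs <- sweep(sweep(X, 2L, colMeans(X)), 2L, sig, "/")
    M <- do.call(rbind, lapply(classes, function(k)
        sqrt(sum(labels == k) / n) *
            colMeans(Xs[labels == k, , drop = FALSE])))
    eigen(crossprod(M), symmetric = TRUE)
}

expect_axis_equal <- function(b, v, tol = 1e-8) {
    err <- min(sqrt(sum((b - v)^2)), sqrt(sum((b + v)^2)))
    expect_lt(err, tol)
}
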