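test_that("correlation blocks handle forced correlation structure", {
    cells <- paste0("c", 1:6)
    m <- rbind(a = c(1, 2, 3, 4, 5, 6),
               b = c(1, 2, 3, 4, 5, 6),
               anti = c(6, 5, 4, 3, 2, 1),
               flat = rep(2, 6))
    colnames(m) <- cells
    expect_warning(cb <- correlationBlocks(m, rownames(m),
                                           transform = "none"),
                   "flat")
    ## identical rows: correlation 1, merged first at height 0
    expect_equal(cb@corr["a", "b"], 1)
    expect_equal(min(cb@linkage$height), 0)
    expect_equal(sort(cb@linkage$merge[1, ]), c(-2, -1))
    ## anti-correlated pair
    expect_equal(cb@corr["a", "anti"], -1)
    expect_error(correlationBlocks(m[, 1:2], rownames(m)), "3 cells")
    expect_error(correlationBlocks(m, "nope"), "absent")
})

test_that("correlation is invariant under gene-wise affine rescaling", {
    sim <- matureSim(seed = 41, nGenes = 300)
    genes <- sim$planted[1:12]
    base <- correlationBlocks(sim$norm, genes, transform = "none")
    scaled <- sim$norm
    scaled[genes, ] <- sweep(sweep(scaled[genes, ], 1L,
                                   seq(2, 13), "*"), 1L, seq_len(12), "+")
    again <- correlationBlocks(scaled, genes, transform = "none")
    expect_equal(base@corr, again@corr, tolerance = 1e-12)
})

test_that("planted clade blocks cluster contiguously with positive concordance", {
    sim <- matureSim(seed = 42, nGenes = 500, nPlanted = 8, log2fc = 3)
    cb <- correlationBlocks(sim$norm, sim$planted, sim$plantedClade)
    expect_gt(concordance(cb), 0)
    runs <- rle(as.vector(sim$plantedClade[cb@geneIds]))
    expect_equal(length(runs$lengths), 3L)
})

test_that("bulk replicates project onto their clade of origin", {
    sim <- matureSim(seed = 43, nGenes = 500, nPlanted = 10, log2fc = 3)
    fit <- fitPLDA(sim$norm[filterExpressed(sim$counts), ], sim$labels,
                   lambda = 0.05)
    panel <- rankLoadings(fit, topK = 20)
    for (clade in c("A", "C")) {
        bulk <- simulateBulk(sim$sce, clade, nReplicates = 3, seed = 17)
        jsf <- jointSizeFactors(sim$counts, bulk)
        scN <- normalizeCounts(sim$counts, jsf$sc)
        bkN <- normalizeCounts(bulk, jsf$bulk)
        proj <- projectBulk(scN, bkN, panel, sim$labels)
        expect_equal(unname(bulkAssignment(proj)), rep(clade, 3))
    }
})

test_that("a replicate equal to the clade mean lands on its centroid", {
    sim <- matureSim(seed = 44, nGenes = 300)
    genes <- sim$planted
    aCells <- sim$labels == "A"
    bulk <- matrix(rowMeans(sim$norm[, aCells]), ncol = 1,
                   dimnames = list(rownames(sim$norm), "mean_rep"))
    proj <- projectBulk(sim$norm, bulk, genes, sim$labels,
                        transform = "none")
    expect_equal(unname(bulkAssignment(proj)), "A")
    ## with log transform the mean is no longer exact but stays nearest A
    proj2 <- projectBulk(sim$norm, bulk, genes, sim$labels)
    expect_equal(unname(bulkAssignment(proj2)), "A")
})

test_that("projection bookkeeping: dimensions, orthonormality, ordering", {
    sim <- matureSim(seed = 45, nGenes = 300)
    genes <- sim$planted[1:2]
    bulk <- sim$norm[, 1:3, drop = FALSE]
    colnames(bulk) <- paste0("rep", 1:3)
    proj <- projectBulk(sim$norm, bulk, genes, sim$labels)
    expect_equal(dim(proj@bulkCoords), c(3L, 2L))
    expect_true(all(is.finite(proj@bulkCoords)))
    ## rotation columns are orthonormal
    g <- crossprod(proj@pcLoadings)
    expect_equal(unname(g), diag(2), tolerance = 1e-10)
    ## explained variance is a decreasing fraction
    expect_true(all(diff(proj@explainedVariance) <= 1e-12))
    ## invariant to replicate ordering
    proj2 <- projectBulk(sim$norm, bulk[, 3:1], genes, sim$labels)
    expect_equal(unname(bulkAssignment(proj2)),
                 rev(unname(bulkAssignment(proj))))
    expect_error(projectBulk(sim$norm, bulk[-match(genes[1],
                                                   rownames(bulk)), ],
                             genes, sim$labels), "absent from the bulk")
})
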