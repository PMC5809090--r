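test_that("simulated dimensions and truth labels partition the cells", {
    spec <- SimSpec(nCellsPerClade = 10, nImmature = 5, nMatureNoOR = 0,
                    nGenes = 400, predominantOrFraction = 0.9, seed = 2)
    sce <- simulateCells(spec)
    expect_equal(ncol(sce), 35L)
    expect_equal(nrow(sce), 400L)
    expect_equal(unname(table(sce$stage)[c("mature_or", "immature")]),
                 c(30L, 5L), ignore_attr = TRUE)
    expect_equal(sum(table(sce$stage)), 35L)
    cnt <- SummarizedExperiment::assay(sce)
    expect_true(all(cnt >= 0))
    expect_true(is.integer(cnt))
    ## every mature_or cell's chosen OR belongs to its clade's OR set
    rd <- SummarizedExperiment::rowData(sce)
    mo <- sce$stage == "mature_or"
    cladeOfOr <- assignClade(rd$or_subfamily[rd$is_or])
    names(cladeOfOr) <- rownames(rd)[rd$is_or]
    expect_equal(unname(cladeOfOr[sce$chosen_or[mo]]),
                 unname(sce$true_clade[mo]))
    ## planted sets are pairwise disjoint
    expect_false(anyDuplicated(rownames(rd)[!is.na(rd$planted_clade)]) > 0)
})

test_that("same seed gives bit-identical matrices, different seed differs", {
    spec1 <- SimSpec(nGenes = 300, predominantOrFraction = 0.9, seed = 7)
    spec2 <- SimSpec(nGenes = 300, predominantOrFraction = 0.9, seed = 8)
    a <- SummarizedExperiment::assay(simulateCells(spec1))
    b <- SummarizedExperiment::assay(simulateCells(spec1))
    c <- SummarizedExperiment::assay(simulateCells(spec2))
    expect_identical(a, b)
    expect_false(identical(a, c))
})

test_that("infinitely steep dropout below all log-means adds no zeros", {
    base <- SimSpec(nGenes = 300, nCellsPerClade = 4, nImmature = 0,
                    nMatureNoOR = 0, predominantOrFraction = 0.9,
                    dropoutMidpoint = -1e6, dropoutSteepness = Inf,
                    nbDispersion = 1e-4, seed = 3,
                    libsizeLogmean = log(5e6), libsizeLogsd = 0)
    sce <- simulateCells(base)
    cnt <- SummarizedExperiment::assay(sce)
    ## with near-zero NB dispersion and dropout disabled, zeros only occur
    ## for genes whose expected count is essentially zero
    pm <- perMillion(cnt)
    expect_lt(mean(cnt == 0), 0.25)
    ## the same spec with an aggressive midpoint zeroes most entries
    heavy <- SimSpec(nGenes = 300, nCellsPerClade = 4, nImmature = 0,
                     nMatureNoOR = 0, predominantOrFraction = 0.9,
                     dropoutMidpoint = 1e6, dropoutSteepness = Inf,
                     nbDispersion = 1e-4, seed = 3,
                     libsizeLogmean = log(5e6), libsizeLogsd = 0)
    expect_true(all(SummarizedExperiment::assay(simulateCells(heavy)) == 0))
})

test_that("planted fold-change is recovered from empirical group means", {
    ## direct-simulation check of the generative contrast at large n
    spec <- SimSpec(nCellsPerClade = 20, nImmature = 0, nMatureNoOR = 0,
                    nGenes = 400, nPlantedMarkersPerClade = 10,
                    plantedLog2Fc = 3, nbDispersion = 0.05,
                    dropoutMidpoint = -1e6, dropoutSteepness = Inf,
                    predominantOrFraction = 0.9, seed = 4)
    sce <- simulateCells(spec)
    rd <- SummarizedExperiment::rowData(sce)
    pm <- perMillion(SummarizedExperiment::assay(sce))
    planted <- rownames(rd)[!is.na(rd$planted_clade)]
    ratios <- vapply(planted, function(g) {
        cl <- rd$planted_clade[match(g, rownames(rd))]
        inClade <- sce$true_clade == cl
        mean(pm[g, inClade]) / mean(pm[g, !inClade])
    }, numeric(1))
    ## per-gene empirical ratio within 25% of the planted 8-fold on average
    expect_lt(abs(mean(ratios) - 8) / 8, 0.25)
})

test_that("planted log2 fold-change converges at 200 cells per clade", {
    spec <- SimSpec(nCellsPerClade = 200, nImmature = 0, nMatureNoOR = 0,
                    nGenes = 200, nPlantedMarkersPerClade = 6,
                    plantedLog2Fc = 3, predominantOrFraction = 0.9,
                    seed = 5)
    sce <- simulateCells(spec)
    rd <- SummarizedExperiment::rowData(sce)
    pm <- perMillion(SummarizedExperiment::assay(sce))
    planted <- rownames(rd)[!is.na(rd$planted_clade)]
    lfc <- vapply(planted, function(g) {
        cl <- rd$planted_clade[match(g, rownames(rd))]
        inClade <- sce$true_clade == cl
        log2(mean(pm[g, inClade]) / mean(pm[g, !inClade]))
    }, numeric(1))
    expect_lt(abs(median(lfc) - 3), 0.3)
})

test_that("column sums concentrate around drawn library sizes", {
    spec <- SimSpec(nCellsPerClade = 3, nImmature = 1, nMatureNoOR = 1,
                    nGenes = 10000, predominantOrFraction = 0.9,
                    dropoutMidpoint = -1e6, dropoutSteepness = Inf,
                    seed = 6)
    sce <- simulateCells(spec)
    relErr <- abs(colSums(SummarizedExperiment::assay(sce)) -
                  sce$mapped_reads) / sce$mapped_reads
    expect_true(all(relErr < 0.05))
})

test_that("predominant OR dominates trace ORs in mature cells", {
    spec <- SimSpec(nCellsPerClade = 8, nGenes = 400,
                    predominantOrFraction = 0.95, seed = 9)
    sce <- simulateCells(spec)
    rd <- SummarizedExperiment::rowData(sce)
    cnt <- SummarizedExperiment::assay(sce)
    mo <- which(sce$stage == "mature_or")
    orCnt <- cnt[rd$is_or, mo, drop = FALSE]
    top <- apply(orCnt, 2L, max)
    tot <- colSums(orCnt)
    expect_true(all(top / tot > 0.5))
    ## no OR counts outside mature_or cells
    expect_true(all(cnt[rd$is_or, sce$stage != "mature_or"] == 0))
})

test_that("simulateBulk degenerates to proportionality and bookkeeping", {
    spec <- SimSpec(nCellsPerClade = c(1, 2, 2), nImmature = 0,
                    nMatureNoOR = 0, nGenes = 300,
                    predominantOrFraction = 0.9, seed = 10)
    sce <- simulateCells(spec)
    ## single clade-A cell, zero noise, one replicate: identical profile
    b1 <- simulateBulk(sce, "A", nReplicates = 1, noiseLogsd = 0, seed = 1)
    cellA <- colnames(sce)[sce$stage == "mature_or" &
                           !is.na(sce$true_clade) & sce$true_clade == "A"]
    expect_equal(unname(b1[, 1]),
                 unname(SummarizedExperiment::assay(sce)[, cellA]))
    b3 <- simulateBulk(sce, "B", nReplicates = 3, seed = 2)
    expect_equal(ncol(b3), 3L)
    expect_error(simulateBulk(sce, "D"), "no mature")
})

test_that("spec validation rejects bad parameters", {
    expect_error(SimSpec(seed = 1), "predominantOrFraction is required")
    expect_error(SimSpec(predominantOrFraction = 0.4), "0.5")
    expect_error(SimSpec(predominantOrFraction = 0.9, nCellsPerClade = 0),
                 ">= 1")
    expect_error(SimSpec(predominantOrFraction = 0.9, nGenes = 10),
                 "too small")
})
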