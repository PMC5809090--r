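mkCounts <- function(vals, genes, cells) {
    matrix(vals, nrow = length(genes),
           dimnames = list(genes, cells))
}

test_that("qcFilter applies the three exclusion rules in order", {
    m <- mkCounts(rep(10L, 12), paste0("g", 1:4), paste0("c", 1:3))
    qc <- data.frame(cell_id = paste0("c", 1:3),
                     mapped_reads = c(2.9e6, 5e6, 5e6),
                     spikein_fraction = c(0.5, 0.10, 0.5))
    res <- qcFilter(m, qc)
    expect_equal(res$calls$stage,
                 c("excluded_low_reads", "excluded_clump", "retained"))
    expect_equal(colnames(res$counts), "c3")
    ## skew rule
    m2 <- m; m2[1, 3] <- 1000L
    res2 <- qcFilter(m2, qc)
    expect_equal(res2$calls$stage[3], "excluded_skewed")
    ## all cells passing: matrix unchanged
    qcGood <- data.frame(cell_id = paste0("c", 1:3),
                         mapped_reads = rep(5e6, 3),
                         spikein_fraction = rep(0.5, 3))
    expect_identical(qcFilter(m, qcGood)$counts, m)
    ## missing QC row errors
    expect_error(qcFilter(m, qcGood[1:2, ]), "missing QC row.*c3")
})

test_that("qcFilter is idempotent and the stage partition is exclusive", {
    sim <- matureSim(seed = 21, nGenes = 300)
    sce <- sim$sce
    first <- qcFilter(sce)
    qc2 <- data.frame(
        cell_id = colnames(first$counts),
        mapped_reads = sce$mapped_reads[match(colnames(first$counts),
                                              colnames(sce))],
        spikein_fraction = sce$spikein_fraction[
            match(colnames(first$counts), colnames(sce))])
    second <- qcFilter(first$counts, qc2)
    expect_identical(second$counts, first$counts)
    expect_true(all(second$calls$stage == "retained"))
    ## exactly one stage per cell over the full partition
    expect_equal(sort(first$calls$cell_id), sort(colnames(sce)))
    expect_equal(anyDuplicated(first$calls$cell_id), 0L)
})

test_that("clusterMarkers orders forced merges correctly", {
    panel <- markerPanel(mature = "m1", immature = "i1")
    ## two identical cells merge at height 0
    m <- mkCounts(c(5, 0, 5, 0, 9, 3), c("m1", "i1"),
                  c("a", "b", "z"))
    m[, "b"] <- m[, "a"]
    hc <- clusterMarkers(m, panel)
    expect_equal(min(hc$height), 0)
    ## single marker, values 0, 0, 10: the two zero cells merge first
    panel1 <- markerPanel(mature = "m1", immature = "i1")
    m2 <- mkCounts(c(0, 0, 0, 0, 10, 0), c("m1", "i1"), c("a", "b", "c"))
    hc2 <- clusterMarkers(suppressWarnings(m2), panel1)
    expect_equal(sort(hc2$merge[1, ]), c(-2, -1))
    ## missing panel genes are warned and dropped
    expect_warning(clusterMarkers(m, markerPanel(mature = c("m1", "nope"),
                                                 immature = "i1")),
                   "nope")
    expect_error(clusterMarkers(m[, 1, drop = FALSE], panel), "2 cells")
})

test_that("clusterMarkers separates planted stages at two clusters", {
    spec <- SimSpec(nCellsPerClade = 5, nImmature = 6, nMatureNoOR = 0,
                    nGenes = 300, predominantOrFraction = 0.9, seed = 30)
    sce <- simulateCells(spec)
    pm <- perMillion(SummarizedExperiment::assay(sce))
    hc <- clusterMarkers(pm)
    cut <- cutree(hc, k = 2)
    truth <- ifelse(sce$stage[match(names(cut), colnames(sce))] ==
                    "immature", 1, 2)
    agree <- max(mean(cut == truth), mean(cut == 3 - truth))
    expect_equal(agree, 1)
})

test_that("callStage reproduces the rule-based maturity triage", {
    genes <- c("gng13b", "gnal", "gng8", "gap43", "or101-1")
    cells <- c("imm", "noor", "withor")
    m <- t(matrix(c(0, 0, 5000, 4000, 0,        # immature, no OR
                    8000, 6000, 0, 0, 0,        # mature, no OR
                    8000, 6000, 0, 0, 3835),    # mature with OR
                  nrow = 3, byrow = TRUE,
                  dimnames = list(cells, genes)))
    st <- callStage(m, orGenes = "or101-1")
    expect_equal(st$stage, c("immature", "mature_no_or", "mature_or"))
    expect_equal(st$max_or_norm[3], 3835)
    ## stages are exhaustive and exclusive
    expect_equal(nrow(st), 3L)
    expect_error(callStage(m, panel = markerPanel(mature = "absent",
                                                  immature = "gng8")),
                 "no mature marker")
})

test_that("stage recovery on planted simulations exceeds 95%", {
    accs <- vapply(1:20, function(s) {
        spec <- SimSpec(nCellsPerClade = 4, nGenes = 300,
                        predominantOrFraction = 0.9, seed = 100 + s)
        sce <- simulateCells(spec)
        pm <- perMillion(SummarizedExperiment::assay(sce))
        org <- rownames(sce)[SummarizedExperiment::rowData(sce)$is_or]
        st <- callStage(pm, orGenes = org)
        mean(st$stage == sce$stage[match(st$cell_id, colnames(sce))])
    }, numeric(1))
    expect_gte(mean(accs), 0.95)
})
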