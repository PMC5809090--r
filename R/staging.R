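#' Maturity marker panel
#'
#' The default panels carry the canonical zebrafish OSN maturity markers:
#' mature cells express *gng13b*, *gnal*, *ompb*, *cnga2*, *cnga4*, *ano2*
#' and *adcy3b*; immature OSNs and their precursors express *gng8* and
#' *gap43*.
#'
#' @param mature,immature character vectors of marker gene ids; must be
#'   disjoint and non-empty.
#' @return A list with elements `mature` and `immature`.
#' @export
markerPanel <- function(mature = c("gng13b", "gnal", "ompb", "cnga2",
                                   "cnga4", "ano2", "adcy3b"),
                        immature = c("gng8", "gap43")) {
    if (!length(mature) || !length(immature))
        stop("marker panels must be non-empty")
    if (length(intersect(mature, immature)))
        stop("mature and immature marker sets must be disjoint")
    list(mature = mature, immature = immature)
}

#' Quality-control filter for single-cell transcriptomes
#'
#' Flags cells that fail library-level quality checks: a spike-in read
#' fraction below `minSpikeinFraction` indicates a cell clump (more cellular
#' RNA than one cell's worth relative to the fixed spike-in amount), fewer
#' than `minMappedReads` genome-mapped reads indicates a failed library, and
#' a single gene absorbing more than `maxTopGeneFraction` of a cell's counts
#' indicates a degenerate, skewed library. Flags are assigned in that order
#' of precedence. The filter is idempotent: rerunning it on its own output
#' excludes nothing further.
#'
#' @param counts gene x cell count matrix (or SummarizedExperiment).
#' @param qc data.frame with columns `cell_id`, `mapped_reads`,
#'   `spikein_fraction`; must cover every cell. For a
#'   SingleCellExperiment from [simulateCells()], taken from `colData` when
#'   `NULL`.
#' @param minSpikeinFraction spike-in fraction threshold (default 0.15).
#' @param minMappedReads mapped-read threshold (default 3e6).
#' @param maxTopGeneFraction maximum fraction of a cell's counts in its
#'   single highest gene (default 0.25).
#' @return A list: `counts`, the matrix restricted to retained cells, and
#'   `calls`, a data.frame with `cell_id`, `stage` (one of `excluded_clump`,
#'   `excluded_low_reads`, `excluded_skewed`, `retained`), and the QC
#'   statistics used.
#' @export
qcFilter <- function(counts, qc = NULL, minSpikeinFraction = 0.15,
                     minMappedReads = 3e6, maxTopGeneFraction = 0.25) {
    if (is(counts, "SummarizedExperiment") && is.null(qc)) {
        cd <- SummarizedExperiment::colData(counts)
        qc <- data.frame(cell_id = rownames(cd),
                         mapped_reads = cd$mapped_reads,
                         spikein_fraction = cd$spikein_fraction)
    }
    m <- .asCountMatrix(counts)
    if (is.null(qc))
        stop("a QC table is required")
    missing <- setdiff(colnames(m), qc$cell_id)
    if (length(missing))
        stop("missing QC row for cell(s): ", paste(missing, collapse = ", "))
    qc <- qc[match(colnames(m), qc$cell_id), ]
    topFrac <- apply(m, 2L, function(x) {
        s <- sum(x)
        if (s == 0) 0 else max(x) / s
    })
    stage <- rep("retained", ncol(m))
    stage[topFrac > maxTopGeneFraction] <- "excluded_skewed"
    stage[qc$mapped_reads < minMappedReads] <- "excluded_low_reads"
    stage[qc$spikein_fraction < minSpikeinFraction] <- "excluded_clump"
    calls <- data.frame(cell_id = colnames(m), stage = stage,
                        mapped_reads = qc$mapped_reads,
                        spikein_fraction = qc$spikein_fraction,
                        top_gene_fraction = topFrac,
                        row.names = NULL)
    list(counts = m[, stage == "retained", drop = FALSE], calls = calls)
}

#' Hierarchical clustering of cells on maturity markers
#'
#' Average-linkage clustering of cells on log10(x + 1) normalized expression
#' of the marker panel genes, for visual triage of maturity stages. Cells
#' are ordered by id before computing distances so the tree is deterministic
#' for any input ordering; the maturity call itself ([callStage()]) is
#' rule-based and does not depend on a cut height.
#'
#' @param norm gene x cell normalized expression matrix.
#' @param panel marker panel from [markerPanel()]; panel genes missing from
#'   the matrix are dropped with a warning.
#' @return An `hclust` tree over cells.
#' @export
clusterMarkers <- function(norm, panel = markerPanel()) {
    genes <- c(panel$mature, panel$immature)
    missing <- setdiff(genes, rownames(norm))
    if (length(missing)) {
        warning("marker gene(s) absent from matrix, dropped: ",
                paste(missing, collapse = ", "))
        genes <- setdiff(genes, missing)
    }
    if (!length(genes)) stop("no marker genes present in the matrix")
    if (ncol(norm) < 2L) stop("need at least 2 cells to cluster")
    expr <- .logNorm(norm[genes, order(colnames(norm)), drop = FALSE])
    stats::hclust(stats::dist(t(expr)), method = "average")
}

#' Maturity stage calls from marker scores
#'
#' A cell is called immature when the mean log10(x + 1) normalized
#' expression of the immature markers exceeds that of the mature markers,
#' and mature otherwise. Mature cells whose highest normalized OR value is
#' below `minOrNorm` are `mature_no_or` (no appreciable OR yet); the rest
#' are `mature_or` and proceed to clade calling.
#'
#' @param norm gene x cell normalized expression matrix; for the OR check
#'   this should be on the per-million scale (see [perMillion()]).
#' @param panel marker panel from [markerPanel()].
#' @param orGenes character vector of OR gene ids present in the matrix.
#' @param minOrNorm threshold on the maximum normalized OR value separating
#'   appreciable OR expression (default 50 per million).
#' @return data.frame with `cell_id`, `stage` (`immature`, `mature_no_or`
#'   or `mature_or`), `mature_score`, `immature_score`, `max_or_norm`.
#' @export
callStage <- function(norm, panel = markerPanel(), orGenes = character(),
                      minOrNorm = 50) {
    for (nm in c("mature", "immature")) {
        present <- intersect(panel[[nm]], rownames(norm))
        if (!length(present))
            stop("no ", nm, " marker genes present in the matrix")
        panel[[nm]] <- present
    }
    matScore <- colMeans(.logNorm(norm[panel$mature, , drop = FALSE]))
    immScore <- colMeans(.logNorm(norm[panel$immature, , drop = FALSE]))
    orGenes <- intersect(orGenes, rownames(norm))
    maxOr <- if (length(orGenes))
        apply(norm[orGenes, , drop = FALSE], 2L, max) else
        rep(0, ncol(norm))
    stage <- ifelse(immScore > matScore, "immature",
                    ifelse(maxOr < minOrNorm, "mature_no_or", "mature_or"))
    data.frame(cell_id = colnames(norm), stage = unname(stage),
               mature_score = unname(matScore),
               immature_score = unname(immScore),
               max_or_norm = unname(maxOr), row.names = NULL)
}
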