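#' Median-of-ratios size factors
#'
#' The standard bulk RNA-seq size-factor estimator: each cell's factor is the
#' median over genes of the ratio of its count to the gene's geometric mean
#' across cells, computed over genes with a nonzero geometric mean. Sparse
#' single-cell matrices rarely have enough all-nonzero genes for this to be
#' stable, so when fewer than `minAllNonzero` genes are nonzero in every
#' cell, geometric means are computed with a +1 pseudocount over all genes
#' instead (factors are then rescaled to geometric mean 1).
#'
#' @param counts gene x cell count matrix (or SummarizedExperiment).
#' @param minAllNonzero minimum number of all-nonzero genes required before
#'   the pseudocount fallback engages.
#' @param fallback if `FALSE`, error instead of engaging the pseudocount
#'   fallback.
#' @return Named numeric vector of positive per-cell size factors with
#'   geometric mean 1.
#' @examples
#' m <- matrix(c(10, 20, 30, 4, 8, 12, 1, 2, 3), nrow = 3, byrow = TRUE,
#'             dimnames = list(paste0("g", 1:3), paste0("c", 1:3)))
#' medianRatioSizeFactors(m)  # proportional to 1, 2, 3
#' @export
medianRatioSizeFactors <- function(counts, minAllNonzero = 50,
                                   fallback = TRUE) {
    m <- .asCountMatrix(counts)
    allNonzero <- rowSums(m == 0) == 0L
    if (sum(allNonzero) >= minAllNonzero ||
        (sum(allNonzero) >= 1L && !fallback)) {
        sub <- m[allNonzero, , drop = FALSE]
        logGeo <- rowMeans(log(sub))
        ratios <- log(sub) - logGeo
    } else {
        if (!fallback)
            stop("no gene is nonzero in every cell and fallback is disabled")
        logGeo <- rowMeans(log(m + 1))
        ratios <- log(m + 1) - logGeo
    }
    sf <- exp(apply(ratios, 2L, stats::median))
    sf <- sf / exp(mean(log(sf)))
    stats::setNames(sf, colnames(m))
}

#' Normalize counts by size factors
#'
#' Divides each cell's counts by its size factor. Multiplying each column of
#' the result by its factor recovers the raw counts exactly.
#'
#' @param counts gene x cell count matrix (or SummarizedExperiment).
#' @param sizeFactors per-cell positive factors; estimated with
#'   [medianRatioSizeFactors()] when `NULL`.
#' @return Gene x cell matrix of normalized expression, with the factors
#'   attached as `attr(, "sizeFactors")`.
#' @export
normalizeCounts <- function(counts, sizeFactors = NULL) {
    m <- .asCountMatrix(counts)
    if (is.null(sizeFactors))
        sizeFactors <- medianRatioSizeFactors(m)
    if (length(sizeFactors) != ncol(m) || any(sizeFactors <= 0))
        stop("sizeFactors must be positive, one per cell")
    out <- sweep(m, 2L, sizeFactors, "/")
    attr(out, "sizeFactors") <- sizeFactors
    out
}

#' Counts per million
#'
#' Scales each cell to reads-per-million, by default over the matrix column
#' sums; pass per-cell mapped-read totals to normalize against library depth
#' instead.
#'
#' @param counts gene x cell count matrix.
#' @param totals optional per-cell totals (defaults to column sums).
#' @return Gene x cell matrix of per-million values.
#' @export
perMillion <- function(counts, totals = NULL) {
    m <- .asCountMatrix(counts)
    if (is.null(totals)) totals <- colSums(m)
    if (length(totals) != ncol(m) || any(totals <= 0))
        stop("totals must be positive, one per cell")
    sweep(m, 2L, totals / 1e6, "/")
}

#' Expressed-gene filter
#'
#' Keeps genes observed at a minimum raw count in a minimum number of the
#' given cells; the thresholds are applied to raw (pre-normalization) counts.
#'
#' @param counts gene x cell count matrix.
#' @param cells cell ids over which prevalence is assessed (default: all).
#' @param minCells minimum number of qualifying cells (default 3).
#' @param minCount minimum raw count per qualifying cell (default 100).
#' @return Character vector of retained gene ids, in matrix order.
#' @export
filterExpressed <- function(counts, cells = NULL, minCells = 3,
                            minCount = 100) {
    m <- .asCountMatrix(counts)
    if (is.null(cells)) cells <- colnames(m)
    if (!all(cells %in% colnames(m)))
        stop("unknown cell id(s): ",
             paste(setdiff(cells, colnames(m)), collapse = ", "))
    if (minCells > length(cells))
        stop("minCells exceeds the number of cells supplied")
    sub <- m[, cells, drop = FALSE]
    keep <- rowSums(sub >= minCount) >= minCells
    rownames(m)[keep]
}

#' Build a gene universe for discriminant analysis
#'
#' Intersects the expressed-gene set with an externally curated list: the
#' full transcriptome (`"all"`, no list needed), membrane/secreted
#' candidates from a signal-peptide prediction run, or annotated
#' transcription factors. OR genes are removed from the membrane/secreted
#' universe (they carry signal peptides but are the class labels, not
#' candidate effectors).
#'
#' @param name one of `"all"`, `"membrane_secreted"`,
#'   `"transcription_factor"`.
#' @param expressed character vector of expressed gene ids (from
#'   [filterExpressed()]).
#' @param geneList curated gene-id list for the restricted universes.
#' @param orGenes OR gene ids to exclude from the membrane/secreted universe.
#' @return Sorted character vector of universe gene ids with attributes
#'   `name`.
#' @export
buildUniverse <- function(name = c("all", "membrane_secreted",
                                   "transcription_factor"),
                          expressed, geneList = NULL, orGenes = character()) {
    name <- match.arg(name)
    universe <- if (identical(name, "all")) {
        expressed
    } else {
        if (is.null(geneList))
            stop("universe '", name, "' requires a curated gene list")
        intersect(expressed, geneList)
    }
    if (identical(name, "membrane_secreted"))
        universe <- setdiff(universe, orGenes)
    universe <- sort(unique(universe))
    if (!length(universe))
        stop("empty gene universe '", name,
             "': no overlap between the expressed genes and the list")
    structure(universe, name = name)
}

#' Read a one-id-per-line gene list
#'
#' @param path file with one gene id per line; blank lines and lines
#'   starting with `#` are ignored.
#' @return Character vector of gene ids.
#' @export
readGeneList <- function(path) {
    lines <- trimws(readLines(path))
    lines[nzchar(lines) & !startsWith(lines, "#")]
}
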