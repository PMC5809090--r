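#' Gene-gene correlation blocks with average-linkage clustering
#'
#' Computes the Pearson correlation between genes across cells on
#' log10(normalized + 1) expression (or the raw normalized values), then
#' clusters genes by average linkage on distance 1 - correlation. The
#' clade-concordance score (mean within-clade correlation minus mean
#' between-clade correlation over gene pairs) summarizes how strongly the
#' clade annotation structures the correlation blocks; it is reported, not
#' a test statistic.
#'
#' @param norm gene x cell normalized expression matrix.
#' @param genes ordered gene ids to correlate (>= 2, present in `norm`).
#' @param cladeTags named character vector: clade label per gene (names
#'   matching `genes`); optional, needed only for the concordance score.
#' @param transform `"log10"` (default) or `"none"`.
#' @return A [CorrelationBlocks-class]; zero-variance genes are dropped
#'   with a warning.
#' @export
correlationBlocks <- function(norm, genes, cladeTags = NULL,
                              transform = c("log10", "none")) {
    transform <- match.arg(transform)
    missing <- setdiff(genes, rownames(norm))
    if (length(missing))
        stop("gene(s) absent from matrix: ",
             paste(missing, collapse = ", "))
    if (length(genes) < 2L) stop("need at least 2 genes")
    if (ncol(norm) < 3L) stop("need at least 3 cells")
    expr <- .applyTransform(norm[genes, , drop = FALSE], transform)
    v <- apply(expr, 1L, stats::sd)
    dropped <- genes[v == 0]
    if (length(dropped)) {
        warning("zero-variance gene(s) dropped: ",
                paste(dropped, collapse = ", "))
        genes <- genes[v > 0]
        expr <- expr[genes, , drop = FALSE]
    }
    if (length(genes) < 2L)
        stop("fewer than 2 genes with nonzero variance")
    cc <- stats::cor(t(expr))
    hc <- stats::hclust(stats::as.dist(1 - cc), method = "average")
    leafOrder <- genes[hc$order]

    concord <- NA_real_
    if (!is.null(cladeTags)) {
        tags <- cladeTags[genes]
        same <- outer(tags, tags, "==")
        ut <- upper.tri(cc)
        concord <- mean(cc[ut & same]) - mean(cc[ut & !same])
    }
    new("CorrelationBlocks",
        geneIds = leafOrder,
        corr = cc,
        linkage = hc,
        cladeAnnotation = if (is.null(cladeTags)) character()
                          else unname(cladeTags[genes]),
        concordance = concord,
        droppedGenes = dropped)
}

#' Project bulk replicates onto a single-cell PCA space
#'
#' Fits a PCA on the single cells only, over a sparse gene panel, on
#' log10(normalized + 1) expression with gene-wise centering taken from the
#' single cells; bulk replicates are transformed with the fitted
#' parameters, so a few bulk libraries cannot dominate the axes
#' (`joint = TRUE` fits on single cells and bulk together instead). Each
#' replicate is assigned the clade whose single-cell centroid is nearest in
#' the first two principal components.
#'
#' @param scNorm gene x cell normalized single-cell expression.
#' @param bulkNorm gene x replicate normalized bulk expression (same
#'   normalization scale; see [jointSizeFactors()]).
#' @param panel character vector of panel genes, or a [SparsePanel-class];
#'   every panel gene must be present in both matrices.
#' @param cladeLabels clade label per single cell.
#' @param joint fit the PCA on single cells and bulk jointly
#'   (default `FALSE`).
#' @param scale. scale genes to unit variance before PCA (default `FALSE`).
#' @param transform `"log10"` (default) or `"none"`.
#' @return A [ProjectionResult-class].
#' @export
projectBulk <- function(scNorm, bulkNorm, panel, cladeLabels,
                        joint = FALSE, scale. = FALSE,
                        transform = c("log10", "none")) {
    transform <- match.arg(transform)
    genes <- if (is(panel, "SparsePanel")) panelGenes(panel) else
        as.character(panel)
    for (nm in list(c("single-cell", "scNorm"), c("bulk", "bulkNorm"))) {
        m <- get(nm[2L])
        missing <- setdiff(genes, rownames(m))
        if (length(missing))
            stop("panel gene(s) absent from the ", nm[1L], " matrix: ",
                 paste(missing, collapse = ", "))
    }
    if (length(cladeLabels) != ncol(scNorm))
        stop("one clade label per single cell required")
    sc <- t(.applyTransform(as.matrix(scNorm)[genes, , drop = FALSE],
                            transform))
    bk <- t(.applyTransform(as.matrix(bulkNorm)[genes, , drop = FALSE],
                            transform))
    fitOn <- if (joint) rbind(sc, bk) else sc
    keep <- apply(fitOn, 2L, stats::sd) > 0
    if (sum(keep) < 2L)
        stop("fewer than 2 panel genes with nonzero variance")
    pca <- stats::prcomp(fitOn[, keep, drop = FALSE], center = TRUE,
                         scale. = scale.)
    nPc <- min(2L, ncol(pca$rotation))
    scScores <- stats::predict(pca, sc[, keep, drop = FALSE])[, seq_len(nPc),
                                                              drop = FALSE]
    bkScores <- stats::predict(pca, bk[, keep, drop = FALSE])[, seq_len(nPc),
                                                              drop = FALSE]
    clades <- sort(unique(as.character(cladeLabels)))
    centroids <- do.call(rbind, lapply(clades, function(cl)
        colMeans(scScores[cladeLabels == cl, , drop = FALSE])))
    rownames(centroids) <- clades
    d2 <- vapply(clades, function(cl)
        rowSums(sweep(bkScores, 2L, centroids[cl, ])^2),
        numeric(nrow(bkScores)))
    d2 <- matrix(d2, nrow = nrow(bkScores), dimnames = list(NULL, clades))
    assignment <- clades[max.col(-d2, ties.method = "first")]
    ev <- pca$sdev^2 / sum(pca$sdev^2)
    new("ProjectionResult",
        pcLoadings = pca$rotation[, seq_len(nPc), drop = FALSE],
        singleCellCoords = scScores,
        bulkCoords = bkScores,
        cladeCentroids = centroids,
        bulkAssignment = stats::setNames(assignment, rownames(bkScores)),
        explainedVariance = ev[seq_len(nPc)])
}

#' Joint size factors for single-cell and bulk matrices
#'
#' Computes median-of-ratios size factors over the genes shared by a
#' single-cell and a bulk matrix, treating every column of both as a
#' sample, so the two datasets end up on one comparable scale before
#' projection.
#'
#' @param scCounts,bulkCounts gene x sample raw count matrices.
#' @param ... passed to [medianRatioSizeFactors()].
#' @return List with `sc` and `bulk` named size-factor vectors.
#' @export
jointSizeFactors <- function(scCounts, bulkCounts, ...) {
    sc <- .asCountMatrix(scCounts)
    bk <- .asCountMatrix(bulkCounts)
    shared <- intersect(rownames(sc), rownames(bk))
    if (length(shared) < 2L)
        stop("single-cell and bulk matrices share fewer than 2 genes")
    joint <- cbind(sc[shared, , drop = FALSE], bk[shared, , drop = FALSE])
    sf <- medianRatioSizeFactors(joint, ...)
    list(sc = sf[seq_len(ncol(sc))],
         bulk = sf[ncol(sc) + seq_len(ncol(bk))])
}
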