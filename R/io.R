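#' Read a gene x cell count matrix
#'
#' Reads either a TSV (gene ids in the first column, a header row of cell
#' ids) or a MatrixMarket file with sidecar gene/cell name files. Duplicate
#' ids, non-integer entries and dimension mismatches are rejected.
#'
#' @param path matrix file.
#' @param format `"tsv"` or `"mtx"`.
#' @param genesFile,cellsFile sidecar one-id-per-line files for MTX;
#'   default to `<path>.genes.txt` / `<path>.cells.txt`.
#' @return Integer gene x cell matrix with dimnames.
#' @export
readCountMatrix <- function(path, format = c("tsv", "mtx"),
                            genesFile = NULL, cellsFile = NULL) {
    format <- match.arg(format)
    if (!file.exists(path)) stop("file not found: ", path)
    if (format == "tsv") {
        df <- utils::read.delim(path, check.names = FALSE,
                                stringsAsFactors = FALSE)
        genes <- df[[1L]]
        m <- as.matrix(df[, -1L, drop = FALSE])
        if (!is.numeric(m)) stop("non-numeric entries in ", path)
        rownames(m) <- genes
    } else {
        if (is.null(genesFile)) genesFile <- paste0(path, ".genes.txt")
        if (is.null(cellsFile)) cellsFile <- paste0(path, ".cells.txt")
        mm <- Matrix::readMM(path)
        genes <- readLines(genesFile)
        cells <- readLines(cellsFile)
        if (nrow(mm) != length(genes) || ncol(mm) != length(cells))
            stop("MTX dimensions (", nrow(mm), " x ", ncol(mm),
                 ") do not match sidecar files (", length(genes), " genes, ",
                 length(cells), " cells)")
        m <- as.matrix(mm)
        dimnames(m) <- list(genes, cells)
    }
    m <- .asCountMatrix(m)
    .checkCounts(m)
    storage.mode(m) <- "integer"
    m
}

#' Write a gene x cell count matrix
#'
#' TSV layout: gene ids in the first column (`gene_id`), one column per
#' cell. MTX layout: MatrixMarket sparse file plus `<path>.genes.txt` and
#' `<path>.cells.txt` sidecars. Round-trips through [readCountMatrix()]
#' reproduce the matrix exactly.
#'
#' @param m gene x cell matrix.
#' @param path output file.
#' @param format `"tsv"` or `"mtx"`.
#' @return `path`, invisibly.
#' @export
writeCountMatrix <- function(m, path, format = c("tsv", "mtx")) {
    format <- match.arg(format)
    m <- .asCountMatrix(m)
    if (format == "tsv") {
        df <- data.frame(gene_id = rownames(m), m, check.names = FALSE,
                         stringsAsFactors = FALSE)
        utils::write.table(df, path, sep = "\t", quote = FALSE,
                           row.names = FALSE)
    } else {
        Matrix::writeMM(methods::as(Matrix::Matrix(m, sparse = TRUE),
                                    "CsparseMatrix"), path)
        writeLines(rownames(m), paste0(path, ".genes.txt"))
        writeLines(colnames(m), paste0(path, ".cells.txt"))
    }
    invisible(path)
}
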