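## Internal helpers shared across modules.

## Accept a plain matrix, a SummarizedExperiment or a SingleCellExperiment
## and return the named assay as a base matrix with dimnames.
.asCountMatrix <- function(x, assay = "counts") {
    if (is(x, "SummarizedExperiment")) {
        m <- SummarizedExperiment::assay(x, assay)
        m <- as.matrix(m)
    } else if (is(x, "Matrix")) {
        m <- as.matrix(x)
    } else if (is.matrix(x)) {
        m <- x
    } else {
        stop("expected a matrix or SummarizedExperiment, got ", class(x)[1L])
    }
    if (is.null(rownames(m)) || is.null(colnames(m)))
        stop("count matrix must carry gene and cell names")
    if (anyDuplicated(rownames(m)))
        stop("duplicate gene ids: ",
             paste(unique(rownames(m)[duplicated(rownames(m))]), collapse = ", "))
    if (anyDuplicated(colnames(m)))
        stop("duplicate cell ids: ",
             paste(unique(colnames(m)[duplicated(colnames(m))]), collapse = ", "))
    m
}

.checkCounts <- function(m) {
    if (any(m < 0)) stop("counts must be non-negative")
    if (any(m != round(m))) stop("counts must be integral")
    invisible(m)
}

## log10(x + 1), the reporting/modelling transform for normalized expression.
.logNorm <- function(x) log10(x + 1)

.applyTransform <- function(x, transform) {
    switch(transform,
           log10 = .logNorm(x),
           none = x,
           stop("unknown transform: ", transform))
}

## Deterministic seeded RNG scope: runs expr with set.seed(seed) and restores
## the caller's RNG state afterwards.
.withSeed <- function(seed, expr) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        old <- get(".Random.seed", envir = globalenv())
        on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
        on.exit(suppressWarnings(
            rm(".Random.seed", envir = globalenv())), add = TRUE)
    }
    set.seed(as.integer(seed))
    expr
}
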