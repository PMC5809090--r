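#' Load the packaged per-cell OR expression table
#'
#' The published table of OR transcripts detected in 29 mature single-OSN
#' transcriptomes: for each cell, the detected ORs with their normalized
#' read counts (per million mapped reads) in printed order, plus the clade
#' label and fold-expression lower bound as printed. Normalized values are
#' stored exactly as published; raw per-OR counts were not published and are
#' not reconstructed.
#'
#' @param format `"list"` (default) returns a named list, one element per
#'   cell in table order, each a named numeric vector of normalized OR
#'   counts in printed order. `"data.frame"` returns the underlying long
#'   table with columns `cell_id`, `rank`, `or_name`, `per_million`,
#'   `clade_printed`, `fold_bound_printed`, `weak_predominance`.
#' @return See `format`.
#' @examples
#' tbl <- loadTable1()
#' length(tbl)          # 29 cells
#' tbl[["s20545"]]      # single OR: or107-1 at 3835 per million
#' @export
loadTable1 <- function(format = c("list", "data.frame")) {
    format <- match.arg(format)
    path <- system.file("extdata", "or_table1.tsv", package = "osnclade",
                        mustWork = TRUE)
    df <- utils::read.delim(path, stringsAsFactors = FALSE,
                            check.names = FALSE)
    if (identical(format, "data.frame"))
        return(df)
    cells <- unique(df$cell_id)
    out <- lapply(cells, function(id) {
        sub <- df[df$cell_id == id, ]
        sub <- sub[order(sub$rank), ]
        stats::setNames(as.numeric(sub$per_million), sub$or_name)
    })
    names(out) <- cells
    out
}

#' Printed clade labels of the packaged OR table
#'
#' @return Named character vector: cell id to published clade label.
#' @examples
#' table(table1Clades())
#' @export
table1Clades <- function() {
    df <- loadTable1(format = "data.frame")
    first <- !duplicated(df$cell_id)
    stats::setNames(df$clade_printed[first], df$cell_id[first])
}
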