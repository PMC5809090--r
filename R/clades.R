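#' OR subfamily ranges defining the three homology clades
#'
#' Zebrafish odorant receptor genes are named `orSSS-V` (subfamily `SSS`,
#' variant `V`, optional pseudogene suffix `p`). The 37 subfamilies 101-137
#' fall into three homology clades: clade A spans subfamilies 101-114,
#' clade B 115-128 and clade C 129-137.
#'
#' @return A named list of integer vectors, one per clade.
#' @examples
#' lengths(cladeSubfamilyRanges())  # 14, 14, 9
#' @export
cladeSubfamilyRanges <- function() {
    list(A = 101:114, B = 115:128, C = 129:137)
}

#' Default OR name aliases
#'
#' Non-standard OR gene identifiers mapped to their subfamily number. Ships
#' the alias used in the packaged per-cell OR table (`zgc:152857/119-1`, an
#' or119 subfamily gene catalogued under a clone id).
#'
#' @return Named integer vector: alias string to subfamily number.
#' @export
defaultOrAliases <- function() {
    c("zgc:152857/119-1" = 119L)
}

#' Parse the subfamily number from an OR gene name
#'
#' Accepts canonical names (`or107-1`), pseudogenes (`or121-2p`, suffix
#' ignored) and aliases resolved through `aliases`. The variant number is
#' ignored; only the subfamily matters for clade assignment.
#'
#' @param orName character vector of OR gene names.
#' @param aliases named integer vector mapping non-standard names to
#'   subfamily numbers; see [defaultOrAliases()].
#' @return Integer vector of subfamily numbers.
#' @examples
#' orSubfamily(c("or107-1", "or121-2p", "zgc:152857/119-1"))
#' @export
orSubfamily <- function(orName, aliases = defaultOrAliases()) {
    out <- integer(length(orName))
    pat <- "^or([0-9]{3})-[0-9]+p?$"
    hit <- grepl(pat, orName)
    out[hit] <- as.integer(sub(pat, "\\1", orName[hit]))
    rest <- !hit
    if (any(rest)) {
        known <- orName[rest] %in% names(aliases)
        if (!all(known))
            stop("cannot parse OR name(s) and no alias found: ",
                 paste(orName[rest][!known], collapse = ", "))
        out[rest] <- unname(aliases[orName[rest]])
    }
    out
}

#' Assign a subfamily number to an OR homology clade
#'
#' @param subfamily integer vector of subfamily numbers in 101-137.
#' @return Character vector of clade labels ("A", "B" or "C").
#' @examples
#' assignClade(c(107, 115, 129))
#' @export
assignClade <- function(subfamily) {
    subfamily <- as.integer(subfamily)
    if (any(is.na(subfamily) | subfamily < 101L | subfamily > 137L))
        stop("subfamily out of range [101, 137]: ",
             paste(subfamily[is.na(subfamily) |
                             subfamily < 101L | subfamily > 137L],
                   collapse = ", "))
    ranges <- cladeSubfamilyRanges()
    out <- character(length(subfamily))
    for (cl in names(ranges)) out[subfamily %in% ranges[[cl]]] <- cl
    out
}

#' Call the predominant OR and clade for one cell
#'
#' Ranks the detected ORs by normalized expression, computes the fold ratio
#' between the two highest, and assigns the clade of the predominant OR.
#' When a single OR is detected the fold ratio is `Inf`. A fold ratio below
#' two is tolerated when both top ORs belong to the same clade (a same-clade
#' tie still identifies the clade); when the top two ORs come from different
#' clades at below two-fold separation the call is flagged ambiguous and no
#' clade is emitted.
#'
#' @param orCounts named numeric vector of normalized OR counts for one cell
#'   (zeros are ignored).
#' @param cellId cell identifier carried into the result.
#' @param aliases OR name aliases, see [orSubfamily()].
#' @return A [PredominantORCall-class] object.
#' @examples
#' callPredominant(c("or106-8" = 14123, "or109-4" = 180, "or109-7" = 16),
#'                 cellId = "s18928")
#' @export
callPredominant <- function(orCounts, cellId = "cell",
                            aliases = defaultOrAliases()) {
    orCounts <- orCounts[orCounts > 0]
    if (!length(orCounts))
        stop("no OR detected in cell ", cellId,
             " (mature cell without appreciable OR)")
    if (is.null(names(orCounts)) || any(!nzchar(names(orCounts))))
        stop("orCounts must be named by OR gene")
    ord <- order(-orCounts, names(orCounts))
    ranked <- orCounts[ord]
    fold <- if (length(ranked) == 1L) Inf else
        unname(ranked[1L] / ranked[2L])
    clades <- assignClade(orSubfamily(names(ranked), aliases))
    ambiguous <- is.finite(fold) && fold < 2 && clades[1L] != clades[2L]
    new("PredominantORCall",
        cellId = as.character(cellId),
        rankedOrs = ranked,
        predominantOr = names(ranked)[1L],
        foldRatio = fold,
        clade = if (ambiguous) NA_character_ else clades[1L],
        ambiguous = ambiguous)
}

#' Call predominant ORs for many cells
#'
#' @param orCountsList named list of per-cell named numeric vectors of
#'   normalized OR counts, e.g. the output of [loadTable1()].
#' @param aliases OR name aliases.
#' @return A [S4Vectors::DataFrame] with one row per cell: `cell_id`,
#'   `predominant_or`, `fold_ratio`, `clade`, `ambiguous`, `n_ors`.
#' @examples
#' calls <- cladeCalls(loadTable1())
#' table(calls$clade)
#' @export
cladeCalls <- function(orCountsList, aliases = defaultOrAliases()) {
    calls <- lapply(names(orCountsList), function(id)
        callPredominant(orCountsList[[id]], cellId = id, aliases = aliases))
    S4Vectors::DataFrame(
        cell_id = vapply(calls, function(x) x@cellId, character(1)),
        predominant_or = vapply(calls, predominantOr, character(1)),
        fold_ratio = vapply(calls, foldRatio, numeric(1)),
        clade = vapply(calls, cladeOf, character(1)),
        ambiguous = vapply(calls, isAmbiguous, logical(1)),
        n_ors = vapply(calls, function(x) length(x@rankedOrs), integer(1)))
}

#' Count cells per clade
#'
#' @param calls a list of [PredominantORCall-class] objects, or the
#'   `DataFrame` returned by [cladeCalls()].
#' @return Named integer vector with counts for clades A, B and C.
#' @examples
#' cladeCensus(cladeCalls(loadTable1()))
#' @export
cladeCensus <- function(calls) {
    if (is.list(calls) && !is.data.frame(calls)) {
        clade <- vapply(calls, cladeOf, character(1))
        amb <- vapply(calls, isAmbiguous, logical(1))
        ids <- vapply(calls, function(x) x@cellId, character(1))
    } else {
        clade <- calls$clade
        amb <- calls$ambiguous
        ids <- calls$cell_id
    }
    if (any(amb))
        stop("ambiguous clade calls present for cell(s): ",
             paste(ids[amb], collapse = ", "))
    counts <- table(factor(clade, levels = c("A", "B", "C")))
    stats::setNames(as.integer(counts), names(counts))
}
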