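#' Two-tailed Fisher's exact test for a 2x2 table
#'
#' Exact hypergeometric test with the probability-mass two-sided rule: the
#' p-value is the sum of the probabilities of all tables with the observed
#' margins whose probability does not exceed that of the observed table.
#'
#' @param a,b,c,d non-negative integer cell counts, row-wise:
#'   `matrix(c(a, b, c, d), 2, byrow = TRUE)`.
#' @return Two-tailed p-value in (0, 1].
#' @examples
#' fisherExact2x2(0, 5, 5, 0)   # 2 / choose(10, 5)
#' @export
fisherExact2x2 <- function(a, b, c, d) {
    cells <- c(a, b, c, d)
    if (any(cells < 0) || any(cells != round(cells)))
        stop("cell counts must be non-negative integers")
    if (sum(cells) == 0) stop("degenerate table: all cells zero")
    stats::fisher.test(matrix(cells, nrow = 2L, byrow = TRUE))$p.value
}

#' Protoglomerular targeting-error report
#'
#' For each protoglomerulus, compares the proportion of olfactory bulbs
#' containing axons between a reference genotype (typically wild type) and
#' every other genotype with a two-tailed Fisher's exact test on the 2x2
#' table of bulbs with/without axons. Proportions are reported with
#' standard errors `sqrt(p(1-p)/n)`, and significance stars at p < 0.05
#' (`*`) and p <= 0.005 (`**`). No multiple-testing correction is applied
#' across protoglomeruli by default, matching per-protoglomerulus
#' reporting; `bonferroni = TRUE` adjusts within each genotype comparison.
#'
#' @param table data.frame with columns `genotype`, `protoglomerulus`,
#'   `bulbs_with_axons`, `n_bulbs`.
#' @param reference reference genotype label (default `"WT"`).
#' @param bonferroni apply a Bonferroni correction across protoglomeruli.
#' @return data.frame with one row per genotype x protoglomerulus
#'   comparison: counts, proportions, SEMs, `p_value` and `stars`.
#' @examples
#' tab <- data.frame(
#'     genotype = c("WT", "WT", "mut", "mut"),
#'     protoglomerulus = c("CZ", "DZ", "CZ", "DZ"),
#'     bulbs_with_axons = c(20, 0, 20, 10),
#'     n_bulbs = c(20, 20, 20, 20))
#' targetingReport(tab, reference = "WT")
#' @export
targetingReport <- function(table, reference = "WT", bonferroni = FALSE) {
    req <- c("genotype", "protoglomerulus", "bulbs_with_axons", "n_bulbs")
    if (!all(req %in% names(table)))
        stop("table must have columns: ", paste(req, collapse = ", "))
    if (any(table$n_bulbs == 0))
        stop("protoglomerulus with zero bulbs in a genotype")
    if (any(table$bulbs_with_axons > table$n_bulbs) ||
        any(table$bulbs_with_axons < 0))
        stop("bulbs_with_axons must lie in [0, n_bulbs]")
    if (!reference %in% table$genotype)
        stop("reference genotype '", reference, "' absent from the table")
    others <- setdiff(unique(table$genotype), reference)
    rows <- list()
    for (g in others) {
        protos <- intersect(
            table$protoglomerulus[table$genotype == reference],
            table$protoglomerulus[table$genotype == g])
        for (pr in protos) {
            refRow <- table[table$genotype == reference &
                            table$protoglomerulus == pr, ][1L, ]
            cmpRow <- table[table$genotype == g &
                            table$protoglomerulus == pr, ][1L, ]
            p <- fisherExact2x2(
                refRow$bulbs_with_axons,
                refRow$n_bulbs - refRow$bulbs_with_axons,
                cmpRow$bulbs_with_axons,
                cmpRow$n_bulbs - cmpRow$bulbs_with_axons)
            pRef <- refRow$bulbs_with_axons / refRow$n_bulbs
            pCmp <- cmpRow$bulbs_with_axons / cmpRow$n_bulbs
            rows[[length(rows) + 1L]] <- data.frame(
                genotype = g, protoglomerulus = pr,
                ref_with = refRow$bulbs_with_axons,
                ref_n = refRow$n_bulbs,
                cmp_with = cmpRow$bulbs_with_axons,
                cmp_n = cmpRow$n_bulbs,
                ref_proportion = pRef,
                cmp_proportion = pCmp,
                ref_sem = sqrt(pRef * (1 - pRef) / refRow$n_bulbs),
                cmp_sem = sqrt(pCmp * (1 - pCmp) / cmpRow$n_bulbs),
                p_value = p, stringsAsFactors = FALSE)
        }
    }
    out <- do.call(rbind, rows)
    if (bonferroni) {
        for (g in unique(out$genotype)) {
            idx <- out$genotype == g
            out$p_value[idx] <- pmin(out$p_value[idx] * sum(idx), 1)
        }
    }
    out$stars <- ifelse(out$p_value <= 0.005, "**",
                        ifelse(out$p_value < 0.05, "*", ""))
    rownames(out) <- NULL
    out
}
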