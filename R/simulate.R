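## Fraction of a mature OR-expressing cell's library allocated to OR genes.
## Matches the per-million scale of published predominant-OR values (roughly
## 1e3-3e4 per million).
.OR_LIBRARY_FRACTION <- 0.015

#' Construct a simulation specification
#'
#' User constructor for [SimSpec-class]. Defaults mirror the structure of a
#' single-cell OSN experiment: a 9/10/10 clade census of mature
#' OR-expressing cells, a handful of immature cells and mature cells without
#' appreciable OR, heavy zero dropout, lognormal library sizes around 20
#' million mapped reads, spike-in read fractions near 50%, and
#' clade-enriched marker blocks planted at a known log2 fold-change.
#' `predominantOrFraction` has no defensible default (per-cell OR read
#' fractions are not published for this system) and must be supplied.
#'
#' @param nCellsPerClade mature OR-expressing cells per clade A/B/C (length
#'   1 or 3).
#' @param nImmature,nMatureNoOR immature cells and mature cells without OR.
#' @param nGenes total genes, including OR, planted and stage-marker genes.
#' @param nOrGenesPerClade OR genes per clade (length 1 or 3).
#' @param nPlantedMarkersPerClade clade-enriched genes planted per clade
#'   (length 1 or 3); each clade's planted set mixes signal-peptide
#'   (guidance-like), transcription-factor and unannotated genes.
#' @param plantedLog2Fc log2 fold-change of planted genes in their clade.
#' @param baselineMeanShape,baselineMeanScale gamma prior on gene relative
#'   expression.
#' @param nbDispersion negative-binomial dispersion (> 0).
#' @param libsizeLogmean,libsizeLogsd lognormal library-size parameters.
#' @param dropoutMidpoint,dropoutSteepness logistic dropout on the log
#'   expected count: genes expected below the midpoint are mostly zeroed.
#' @param predominantOrFraction share of a mature cell's OR reads going to
#'   its chosen OR; must exceed 0.5.
#' @param spikeinFractionMean,spikeinFractionSd per-cell spike-in fraction.
#' @param seed RNG seed.
#' @return A validated [SimSpec-class] object.
#' @examples
#' spec <- SimSpec(predominantOrFraction = 0.95, seed = 7L)
#' spec
#' @export
SimSpec <- function(nCellsPerClade = c(9L, 10L, 10L),
                    nImmature = 5L, nMatureNoOR = 13L,
                    nGenes = 2000L,
                    nOrGenesPerClade = c(15L, 15L, 10L),
                    nPlantedMarkersPerClade = 15L,
                    plantedLog2Fc = 3,
                    baselineMeanShape = 0.6, baselineMeanScale = 1,
                    nbDispersion = 0.3,
                    libsizeLogmean = log(2e7), libsizeLogsd = 0.35,
                    dropoutMidpoint = log(50), dropoutSteepness = 1,
                    predominantOrFraction,
                    spikeinFractionMean = 0.5, spikeinFractionSd = 0.05,
                    seed = 1L) {
    if (missing(predominantOrFraction))
        stop("predominantOrFraction is required (no published default)")
    rep3 <- function(x) as.integer(rep(x, length.out = 3L))
    new("SimSpec",
        nCellsPerClade = rep3(nCellsPerClade),
        nImmature = as.integer(nImmature),
        nMatureNoOR = as.integer(nMatureNoOR),
        nGenes = as.integer(nGenes),
        nOrGenesPerClade = rep3(nOrGenesPerClade),
        nPlantedMarkersPerClade = rep3(nPlantedMarkersPerClade),
        plantedLog2Fc = plantedLog2Fc,
        baselineMeanShape = baselineMeanShape,
        baselineMeanScale = baselineMeanScale,
        nbDispersion = nbDispersion,
        libsizeLogmean = libsizeLogmean,
        libsizeLogsd = libsizeLogsd,
        dropoutMidpoint = dropoutMidpoint,
        dropoutSteepness = dropoutSteepness,
        predominantOrFraction = predominantOrFraction,
        spikeinFractionMean = spikeinFractionMean,
        spikeinFractionSd = spikeinFractionSd,
        seed = as.integer(seed))
}

## Logistic dropout probability on the log expected count, with a safe
## infinite-steepness limit.
.dropoutProb <- function(expected, midpoint, steepness) {
    logE <- log(pmax(expected, 1e-300))
    if (is.infinite(steepness)) {
        ifelse(logE > midpoint, 0, ifelse(logE < midpoint, 1, 0.5))
    } else {
        1 / (1 + exp(steepness * (logE - midpoint)))
    }
}

#' Simulate a single-cell OSN count matrix with known truth
#'
#' Draws a gene x cell integer count matrix under a negative-binomial model
#' with gamma gene means, lognormal library sizes and logistic dropout, with
#' the cell-type structure of an OSN capture: mature OR-expressing cells in
#' three clades (each with one chosen OR receiving `predominantOrFraction`
#' of its OR reads and trace counts on a few other ORs), mature cells
#' without OR expression, and immature cells with elevated early-stage and
#' suppressed mature markers and no OR counts. Planted clade-marker genes
#' have their mean multiplied by `2^plantedLog2Fc` in their clade's mature
#' cells.
#'
#' @param spec a [SimSpec-class] object.
#' @return A [SingleCellExperiment::SingleCellExperiment]: assay `counts`;
#'   `colData` columns `stage` (`mature_or`, `mature_no_or`, `immature`),
#'   `true_clade`, `chosen_or`, `mapped_reads`, `spikein_fraction`;
#'   `rowData` columns `is_or`, `or_subfamily`, `is_tf`,
#'   `has_signal_peptide`, `planted_clade`, `is_mature_marker`,
#'   `is_immature_marker`; the spec in `metadata(sce)$spec`. Fully
#'   reproducible from `spec@seed`.
#' @examples
#' sce <- simulateCells(SimSpec(nCellsPerClade = 3, nGenes = 300,
#'                              predominantOrFraction = 0.9, seed = 1))
#' table(sce$stage)
#' @export
simulateCells <- function(spec) {
    validObject(spec)
    .withSeed(spec@seed, {
        ranges <- cladeSubfamilyRanges()
        clades <- c("A", "B", "C")

        ## --- gene layout -------------------------------------------------
        panel <- markerPanel()
        matureMarkers <- panel$mature
        immatureMarkers <- panel$immature
        orNames <- unlist(lapply(seq_along(clades), function(i) {
            sf <- rep(ranges[[i]], length.out = spec@nOrGenesPerClade[i])
            variant <- stats::ave(sf, sf, FUN = seq_along)
            sprintf("or%d-%d", sf, variant)
        }))
        orClade <- rep(clades, spec@nOrGenesPerClade)
        plantedNames <- unlist(lapply(seq_along(clades), function(i) {
            n <- spec@nPlantedMarkersPerClade[i]
            if (n == 0L) character() else
                sprintf("mk%s%02d", clades[i], seq_len(n))
        }))
        plantedClade <- rep(clades, spec@nPlantedMarkersPerClade)
        nBackground <- spec@nGenes - length(orNames) - length(plantedNames) -
            length(matureMarkers) - length(immatureMarkers)
        background <- sprintf("g%04d", seq_len(nBackground))
        geneIds <- c(matureMarkers, immatureMarkers, plantedNames,
                     background, orNames)
        p <- length(geneIds)
        isOr <- geneIds %in% orNames
        orSub <- rep(NA_integer_, p)
        orSub[isOr] <- orSubfamily(orNames)

        ## planted sets mix guidance-like, TF and plain genes; background
        ## genes get annotation flags at realistic rates
        role <- unlist(lapply(spec@nPlantedMarkersPerClade, function(n)
            rep_len(c("signal", "tf", "plain"), n)), use.names = FALSE)
        isTf <- stats::setNames(rep(FALSE, p), geneIds)
        hasSp <- stats::setNames(rep(FALSE, p), geneIds)
        isTf[plantedNames] <- role == "tf"
        hasSp[plantedNames] <- role == "signal"
        isTf[background] <- runif(nBackground) < 0.10
        hasSp[background] <- !isTf[background] &
            runif(nBackground) < 0.15
        hasSp[orNames] <- TRUE   # ORs are membrane receptors
        plantedOf <- rep(NA_character_, p)
        plantedOf[match(plantedNames, geneIds)] <- plantedClade

        ## --- cell layout -------------------------------------------------
        stage <- c(rep("mature_or", sum(spec@nCellsPerClade)),
                   rep("mature_no_or", spec@nMatureNoOR),
                   rep("immature", spec@nImmature))
        trueClade <- c(rep(clades, spec@nCellsPerClade),
                       rep(NA_character_,
                           spec@nMatureNoOR + spec@nImmature))
        n <- length(stage)
        cellIds <- sprintf("cell%03d", seq_len(n))

        ## --- generative means -------------------------------------------
        baseMean <- rgamma(p, shape = spec@baselineMeanShape,
                           scale = spec@baselineMeanScale) + 1e-6
        names(baseMean) <- geneIds
        ## stage markers sit well above the typical gene so staging has the
        ## dynamic range seen in real marker panels
        baseMean[c(matureMarkers, immatureMarkers)] <-
            baseMean[c(matureMarkers, immatureMarkers)] + 5

        libsize <- rlnorm(n, spec@libsizeLogmean, spec@libsizeLogsd)
        chosenOr <- rep(NA_character_, n)
        counts <- matrix(0, nrow = p, ncol = n,
                         dimnames = list(geneIds, cellIds))
        orBudget <- .OR_LIBRARY_FRACTION
        frac <- spec@predominantOrFraction
        nonOrIdx <- which(!isOr)

        for (i in seq_len(n)) {
            rel <- baseMean[nonOrIdx]
            mature <- stage[i] != "immature"
            markerBoost <- 2^3
            if (mature) {
                rel[matureMarkers] <- rel[matureMarkers] * markerBoost
                rel[immatureMarkers] <- rel[immatureMarkers] / markerBoost
            } else {
                rel[immatureMarkers] <- rel[immatureMarkers] * markerBoost
                rel[matureMarkers] <- rel[matureMarkers] / markerBoost
            }
            if (stage[i] == "mature_or") {
                mine <- plantedNames[plantedClade == trueClade[i]]
                rel[mine] <- rel[mine] * 2^spec@plantedLog2Fc
            }
            hasOrReads <- stage[i] == "mature_or"
            budget <- if (hasOrReads) orBudget else 0
            mu <- rel / sum(rel) * libsize[i] * (1 - budget)
            x <- rnbinom(length(mu), mu = mu,
                         size = 1 / spec@nbDispersion)
            pDrop <- .dropoutProb(mu, spec@dropoutMidpoint,
                                  spec@dropoutSteepness)
            x[runif(length(x)) < pDrop] <- 0L
            counts[nonOrIdx, i] <- x

            if (hasOrReads) {
                mineOrs <- orNames[orClade == trueClade[i]]
                chosen <- mineOrs[sample.int(length(mineOrs), 1L)]
                chosenOr[i] <- chosen
                orReads <- budget * libsize[i]
                muChosen <- frac * orReads
                cx <- rnbinom(1L, mu = muChosen,
                              size = 1 / spec@nbDispersion)
                if (runif(1L) < .dropoutProb(muChosen,
                                             spec@dropoutMidpoint,
                                             spec@dropoutSteepness))
                    cx <- 0L
                counts[chosen, i] <- cx
                others <- setdiff(orNames, chosen)
                k <- min(3L, length(others))
                if (k > 0L) {
                    trace <- others[sample.int(length(others), k)]
                    muTrace <- (1 - frac) * orReads / k
                    tx <- rpois(k, muTrace)
                    tx[runif(k) < .dropoutProb(muTrace,
                                               spec@dropoutMidpoint,
                                               spec@dropoutSteepness)] <- 0L
                    counts[trace, i] <- tx
                }
            }
        }

        spike <- pmin(pmax(rnorm(n, spec@spikeinFractionMean,
                                 spec@spikeinFractionSd), 0), 1)
        storage.mode(counts) <- "integer"

        SingleCellExperiment::SingleCellExperiment(
            assays = list(counts = counts),
            colData = S4Vectors::DataFrame(
                stage = stage, true_clade = trueClade,
                chosen_or = chosenOr,
                mapped_reads = round(libsize),
                spikein_fraction = spike,
                row.names = cellIds),
            rowData = S4Vectors::DataFrame(
                is_or = isOr, or_subfamily = orSub,
                is_tf = unname(isTf), has_signal_peptide = unname(hasSp),
                planted_clade = plantedOf,
                is_mature_marker = geneIds %in% matureMarkers,
                is_immature_marker = geneIds %in% immatureMarkers,
                row.names = geneIds),
            metadata = list(spec = spec))
    })
}

#' Simulate bulk RNA-seq replicates from one clade's cells
#'
#' Each replicate is the pooled count profile of the clade's mature
#' OR-expressing cells, rescaled to a drawn library size with gene-wise
#' lognormal noise and rounded to integer counts. With zero noise and the
#' default library size the first replicate of a single-cell clade equals
#' that cell's counts.
#'
#' @param sce a [SingleCellExperiment::SingleCellExperiment] from
#'   [simulateCells()] (must carry `stage` and `true_clade` in `colData`).
#' @param clade clade label to pool ("A", "B" or "C").
#' @param nReplicates number of bulk replicates (default 3).
#' @param noiseLogsd gene-wise lognormal noise sd on the log scale.
#' @param seed RNG seed.
#' @param libsizeLogmean,libsizeLogsd lognormal library size of each
#'   replicate; defaults to the pooled profile total with 20% spread.
#' @return Gene x replicate integer matrix named `bulk_<clade>_<i>`.
#' @export
simulateBulk <- function(sce, clade, nReplicates = 3L, noiseLogsd = 0.1,
                         seed = 1L,
                         libsizeLogmean = NULL, libsizeLogsd = 0.2) {
    counts <- .asCountMatrix(sce)
    cd <- SummarizedExperiment::colData(sce)
    cells <- rownames(cd)[cd$stage == "mature_or" &
                          !is.na(cd$true_clade) & cd$true_clade == clade]
    if (!length(cells))
        stop("no mature OR-expressing cells with clade ", clade)
    prof <- rowSums(counts[, cells, drop = FALSE])
    total <- sum(prof)
    if (is.null(libsizeLogmean)) {
        libsizeLogmean <- log(total)
        if (noiseLogsd == 0 && nReplicates == 1L) libsizeLogsd <- 0
    }
    pgene <- prof / total
    .withSeed(seed, {
        out <- vapply(seq_len(nReplicates), function(r) {
            L <- rlnorm(1L, libsizeLogmean, libsizeLogsd)
            noise <- if (noiseLogsd > 0)
                exp(rnorm(length(pgene), -noiseLogsd^2 / 2, noiseLogsd))
            else rep(1, length(pgene))
            round(pgene * L * noise)
        }, numeric(length(pgene)))
        dimnames(out) <- list(rownames(counts),
                              sprintf("bulk_%s_%d", clade,
                                      seq_len(nReplicates)))
        storage.mode(out) <- "integer"
        out
    })
}
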