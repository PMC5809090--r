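#' Assemble a pipeline configuration
#'
#' Collects every threshold and model setting of the analysis into one
#' validated list with provenance, mirroring the stage order of the
#' analysis: QC, staging, clade calling, expression filtering, penalized
#' LDA per gene universe, sparse refit, cross-validation, correlation
#' blocks, and (when bulk replicates are supplied) bulk projection.
#'
#' @param minSpikeinFraction,minMappedReads,maxTopGeneFraction QC
#'   thresholds, see [qcFilter()].
#' @param minOrNorm appreciable-OR threshold (per million), see
#'   [callStage()].
#' @param minCells,minCount expressed-gene filter, see [filterExpressed()].
#' @param lambda lasso penalty for [fitPLDA()].
#' @param topK sparse-panel size per axis.
#' @param nFolds cross-validation folds.
#' @param universes subset of `"all"`, `"membrane_secreted"`,
#'   `"transcription_factor"` to analyse.
#' @param seed seed for every stochastic stage.
#' @return A validated named list of class `pipelineConfig`.
#' @export
pipelineConfig <- function(minSpikeinFraction = 0.15,
                           minMappedReads = 3e6,
                           maxTopGeneFraction = 0.25,
                           minOrNorm = 50,
                           minCells = 3L, minCount = 100L,
                           lambda = 0.05, topK = 20L, nFolds = 6L,
                           universes = "all",
                           seed = 1L) {
    stopifnot(minSpikeinFraction >= 0, minSpikeinFraction <= 1,
              minMappedReads >= 0,
              maxTopGeneFraction > 0, maxTopGeneFraction <= 1,
              minOrNorm >= 0, minCells >= 1, minCount >= 1,
              lambda >= 0, topK >= 1, nFolds >= 2)
    universes <- match.arg(universes,
                           c("all", "membrane_secreted",
                             "transcription_factor"),
                           several.ok = TRUE)
    structure(list(minSpikeinFraction = minSpikeinFraction,
                   minMappedReads = minMappedReads,
                   maxTopGeneFraction = maxTopGeneFraction,
                   minOrNorm = minOrNorm,
                   minCells = as.integer(minCells),
                   minCount = as.integer(minCount),
                   lambda = lambda, topK = as.integer(topK),
                   nFolds = as.integer(nFolds),
                   universes = universes,
                   seed = as.integer(seed)),
              class = "pipelineConfig")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys match the arguments of
#'   [pipelineConfig()].
#' @return A validated `pipelineConfig`.
#' @export
readPipelineConfig <- function(path) {
    vals <- yaml::read_yaml(path)
    do.call(pipelineConfig, vals)
}

.writeStage <- function(df, file) {
    utils::write.table(df, file, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    file
}

#' Run the full clade analysis pipeline
#'
#' Drives all stages on a single-cell experiment: QC exclusion, maturity
#' staging, predominant-OR clade calling, expression filtering and universe
#' construction, penalized LDA with sparse refit and stratified
#' cross-validation per universe, correlation blocks over the sparse panel,
#' and projection of bulk replicates when supplied. Every stage writes a
#' TSV under `outDir`, and a manifest records the configuration, seed,
#' per-stage cell/gene counts and the MD5 digest of every output, so a
#' rerun with the same config reproduces the outputs bit-exactly.
#'
#' @param sce a [SingleCellExperiment::SingleCellExperiment] with a
#'   `counts` assay and QC columns (`mapped_reads`, `spikein_fraction`) in
#'   `colData`, e.g. from [simulateCells()] or assembled from
#'   [readCountMatrix()] plus a QC table.
#' @param outDir output directory (created if needed).
#' @param config a [pipelineConfig()].
#' @param bulk optional gene x replicate bulk count matrix for the
#'   projection stage.
#' @param membraneGenes,tfGenes curated gene lists for the restricted
#'   universes; default to the `has_signal_peptide` / `is_tf` flags in
#'   `rowData(sce)` when present.
#' @return Invisibly, a list with the per-stage results and the manifest
#'   data.frame (`stage`, `file`, `md5`, `note`).
#' @export
runPipeline <- function(sce, outDir, config = pipelineConfig(),
                        bulk = NULL, membraneGenes = NULL, tfGenes = NULL) {
    if (!inherits(config, "pipelineConfig"))
        stop("config must come from pipelineConfig()")
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    counts <- .asCountMatrix(sce)
    rd <- SummarizedExperiment::rowData(sce)
    if (is.null(membraneGenes) && "has_signal_peptide" %in% names(rd))
        membraneGenes <- rownames(rd)[rd$has_signal_peptide]
    if (is.null(tfGenes) && "is_tf" %in% names(rd))
        tfGenes <- rownames(rd)[rd$is_tf]
    if (!"is_or" %in% names(rd))
        stop("clade stage requires OR annotation: rowData(sce)$is_or ",
             "is missing")
    orGenes <- rownames(rd)[rd$is_or]

    manifest <- data.frame(stage = character(), file = character(),
                           md5 = character(), note = character())
    addStage <- function(stage, file, note) {
        manifest <<- rbind(manifest, data.frame(
            stage = stage, file = basename(file),
            md5 = unname(tools::md5sum(file)), note = note))
    }

    ## 1: QC exclusion
    qcRes <- qcFilter(sce,
                      minSpikeinFraction = config$minSpikeinFraction,
                      minMappedReads = config$minMappedReads,
                      maxTopGeneFraction = config$maxTopGeneFraction)
    f <- .writeStage(qcRes$calls, file.path(outDir, "qc_calls.tsv"))
    addStage("qc", f, sprintf("%d cells in, %d retained",
                              ncol(counts), ncol(qcRes$counts)))
    counts <- qcRes$counts

    ## 2: maturity staging on per-million values
    pm <- perMillion(counts)
    stages <- callStage(pm, orGenes = orGenes, minOrNorm = config$minOrNorm)
    f <- .writeStage(stages, file.path(outDir, "stage_calls.tsv"))
    addStage("staging", f,
             paste(names(table(stages$stage)), table(stages$stage),
                   sep = "=", collapse = ", "))
    matureOr <- stages$cell_id[stages$stage == "mature_or"]
    if (length(matureOr) < 6L)
        stop("staging left fewer than 6 mature OR-expressing cells; ",
             "cannot fit a clade classifier")

    ## 3: predominant-OR clade calls
    orCountsList <- lapply(matureOr, function(cid) pm[orGenes, cid])
    names(orCountsList) <- matureOr
    calls <- cladeCalls(orCountsList)
    f <- .writeStage(as.data.frame(calls),
                     file.path(outDir, "clade_calls.tsv"))
    if (any(calls$ambiguous))
        stop("ambiguous clade call(s): ",
             paste(calls$cell_id[calls$ambiguous], collapse = ", "))
    census <- cladeCensus(calls)
    addStage("clades", f, paste(names(census), census, sep = "=",
                                collapse = ", "))
    labels <- stats::setNames(calls$clade, calls$cell_id)[matureOr]

    ## 4: expression filter and gene universes
    expressed <- filterExpressed(counts, cells = matureOr,
                                 minCells = config$minCells,
                                 minCount = config$minCount)
    uniList <- lapply(config$universes, function(u)
        buildUniverse(u, expressed,
                      geneList = switch(u, all = NULL,
                                        membrane_secreted = membraneGenes,
                                        transcription_factor = tfGenes),
                      orGenes = orGenes))
    names(uniList) <- config$universes
    uniDf <- do.call(rbind, lapply(config$universes, function(u)
        data.frame(universe = u, gene_id = as.character(uniList[[u]]))))
    f <- .writeStage(uniDf, file.path(outDir, "universes.tsv"))
    addStage("filter", f, sprintf("%d expressed genes", length(expressed)))

    ## 5-7: PLDA, sparse refit, cross-validation per universe
    sf <- medianRatioSizeFactors(counts[, matureOr, drop = FALSE])
    norm <- normalizeCounts(counts[, matureOr, drop = FALSE], sf)
    models <- list(); panels <- list(); cvs <- list()
    modelRows <- list(); panelRows <- list(); cvRows <- list()
    for (u in config$universes) {
        xs <- norm[uniList[[u]], , drop = FALSE]
        fit <- fitPLDA(xs, labels, lambda = config$lambda)
        panel <- rankLoadings(fit, topK = config$topK)
        sparse <- sparseRefit(norm[, , drop = FALSE], labels, panel,
                              lambda = config$lambda)
        cv <- crossValidate(xs, labels, lambda = config$lambda,
                            topK = config$topK, nFolds = config$nFolds,
                            seed = config$seed)
        models[[u]] <- fit; panels[[u]] <- panel; cvs[[u]] <- cv
        L <- cladeLoadings(fit)
        modelRows[[u]] <- data.frame(universe = u,
                                     gene_id = rownames(L),
                                     V1 = L[, 1L],
                                     V2 = if (ncol(L) > 1L) L[, 2L] else NA)
        panelRows[[u]] <- data.frame(universe = u,
                                     gene_id = panelGenes(panel),
                                     axis = panel@axisOfOrigin)
        cvRows[[u]] <- data.frame(universe = u, n_folds = cv@nFolds,
                                  accuracy = cvAccuracy(cv),
                                  seed = cv@seed)
    }
    f <- .writeStage(do.call(rbind, modelRows),
                     file.path(outDir, "plda_models.tsv"))
    addStage("plda", f, sprintf("lambda=%g over %d universe(s)",
                                config$lambda, length(config$universes)))
    f <- .writeStage(do.call(rbind, panelRows),
                     file.path(outDir, "sparse_panels.tsv"))
    addStage("sparse_refit", f, sprintf("topK=%d", config$topK))
    f <- .writeStage(do.call(rbind, cvRows),
                     file.path(outDir, "cv_results.tsv"))
    addStage("cv", f, paste(sprintf("%s=%.3f", config$universes,
                                    vapply(cvs, cvAccuracy, numeric(1))),
                            collapse = ", "))

    ## 8: correlation blocks over the first universe's panel
    panelG <- panelGenes(panels[[1L]])
    tags <- vapply(panelG, function(g) {
        means <- vapply(sort(unique(labels)), function(cl)
            mean(.logNorm(norm[g, names(labels)[labels == cl]])),
            numeric(1))
        names(means)[which.max(means)]
    }, character(1))
    blocks <- suppressWarnings(
        correlationBlocks(norm, panelG, cladeTags = tags))
    corDf <- data.frame(gene_id = blocks@geneIds,
                        clade_tag = tags[blocks@geneIds])
    f <- .writeStage(corDf, file.path(outDir, "correlation_blocks.tsv"))
    addStage("correlation", f,
             sprintf("concordance=%.3f", concordance(blocks)))

    ## 9: bulk projection (optional)
    projection <- NULL
    if (!is.null(bulk)) {
        jsf <- jointSizeFactors(counts[, matureOr, drop = FALSE], bulk)
        shared <- intersect(rownames(counts), rownames(bulk))
        scN <- normalizeCounts(counts[shared, matureOr, drop = FALSE],
                               jsf$sc)
        bkN <- normalizeCounts(bulk[shared, , drop = FALSE], jsf$bulk)
        projection <- projectBulk(scN, bkN,
                                  intersect(panelG, shared), labels)
        projDf <- data.frame(replicate = names(bulkAssignment(projection)),
                             clade = unname(bulkAssignment(projection)),
                             PC1 = projection@bulkCoords[, 1L],
                             PC2 = projection@bulkCoords[, 2L])
        f <- .writeStage(projDf, file.path(outDir, "bulk_projection.tsv"))
        addStage("projection", f,
                 paste(bulkAssignment(projection), collapse = ", "))
    }

    yaml::write_yaml(unclass(config), file.path(outDir, "config.yaml"))
    cfgDigest <- unname(tools::md5sum(file.path(outDir, "config.yaml")))
    manifestOut <- cbind(manifest, config_digest = cfgDigest)
    .writeStage(manifestOut, file.path(outDir, "manifest.tsv"))

    invisible(list(qc = qcRes$calls, stages = stages, calls = calls,
                   census = census, universes = uniList, models = models,
                   panels = panels, cv = cvs, blocks = blocks,
                   projection = projection, manifest = manifestOut))
}
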