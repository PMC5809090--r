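#' @import methods
#' @importFrom stats median sd cor dist hclust prcomp fisher.test rnbinom
#'   rpois rnorm rlnorm rgamma runif plogis setNames quantile as.dendrogram
#' @importFrom utils read.delim write.table head
NULL

#' Simulation specification for synthetic OSN single-cell data
#'
#' Parameters of the generative model used by [simulateCells()]: a
#' negative-binomial count model with gamma-distributed gene means, lognormal
#' library sizes and logistic dropout on the log expected count, plus the
#' OSN-specific structure (one predominant odorant receptor per mature cell,
#' planted clade-marker blocks, immature cells carrying early-stage markers).
#'
#' @slot nCellsPerClade integer(3), mature OR-expressing cells per clade A/B/C.
#' @slot nImmature integer(1), immature cells (no OR expression).
#' @slot nMatureNoOR integer(1), mature cells without appreciable OR.
#' @slot nGenes integer(1), total genes including ORs and markers.
#' @slot nOrGenesPerClade integer(3), OR genes per clade.
#' @slot nPlantedMarkersPerClade integer(3), clade-enriched marker genes
#'   planted per clade (disjoint sets).
#' @slot plantedLog2Fc numeric(1), log2 fold-change of planted genes in their
#'   clade's cells.
#' @slot baselineMeanShape,baselineMeanScale numeric(1), gamma prior on gene
#'   relative expression.
#' @slot nbDispersion numeric(1), negative-binomial dispersion (> 0).
#' @slot libsizeLogmean,libsizeLogsd numeric(1), lognormal library size.
#' @slot dropoutMidpoint,dropoutSteepness numeric(1), logistic zero-inflation
#'   on the log expected count.
#' @slot predominantOrFraction numeric(1) in (0.5, 1), share of a mature
#'   cell's OR reads allocated to its chosen OR.
#' @slot spikeinFractionMean,spikeinFractionSd numeric(1), per-cell spike-in
#'   read fraction.
#' @slot seed integer(1), RNG seed.
#'
#' @seealso [SimSpec()] for the user constructor.
#' @exportClass SimSpec
setClass("SimSpec", representation(
    nCellsPerClade = "integer",
    nImmature = "integer",
    nMatureNoOR = "integer",
    nGenes = "integer",
    nOrGenesPerClade = "integer",
    nPlantedMarkersPerClade = "integer",
    plantedLog2Fc = "numeric",
    baselineMeanShape = "numeric",
    baselineMeanScale = "numeric",
    nbDispersion = "numeric",
    libsizeLogmean = "numeric",
    libsizeLogsd = "numeric",
    dropoutMidpoint = "numeric",
    dropoutSteepness = "numeric",
    predominantOrFraction = "numeric",
    spikeinFractionMean = "numeric",
    spikeinFractionSd = "numeric",
    seed = "integer"
))

setValidity("SimSpec", function(object) {
    msg <- character()
    if (length(object@nCellsPerClade) != 3L || any(object@nCellsPerClade < 1L))
        msg <- c(msg, "nCellsPerClade must be three clade sizes, each >= 1")
    if (length(object@nOrGenesPerClade) != 3L ||
        any(object@nOrGenesPerClade < 1L))
        msg <- c(msg, "nOrGenesPerClade must be three counts, each >= 1")
    if (length(object@nPlantedMarkersPerClade) != 3L ||
        any(object@nPlantedMarkersPerClade < 0L))
        msg <- c(msg, "nPlantedMarkersPerClade must be three counts >= 0")
    if (object@nGenes < sum(object@nOrGenesPerClade) +
        sum(object@nPlantedMarkersPerClade) + 9L)
        msg <- c(msg, "nGenes too small for ORs, planted markers and stage markers")
    if (object@nImmature < 0L || object@nMatureNoOR < 0L)
        msg <- c(msg, "cell counts must be non-negative")
    if (object@nbDispersion <= 0)
        msg <- c(msg, "nbDispersion must be > 0")
    if (!(object@predominantOrFraction > 0.5 &&
          object@predominantOrFraction < 1))
        msg <- c(msg, "predominantOrFraction must lie in (0.5, 1)")
    if (object@spikeinFractionMean < 0 || object@spikeinFractionMean > 1)
        msg <- c(msg, "spikeinFractionMean must lie in [0, 1]")
    if (length(msg)) msg else TRUE
})

#' Fitted penalized linear discriminant model
#'
#' A Fisher-style discriminant fit with a lasso penalty on the discriminant
#' vectors: features are scaled by pooled within-class standard deviations,
#' and each axis maximizes the penalized between-class variance
#' \eqn{\beta' \Sigma_b \beta - \lambda \|\beta\|_1} under a unit-norm
#' constraint, with orthogonal deflation between axes.
#'
#' @slot featureIds character, genes in model order.
#' @slot classLabels character, class labels in fixed sort order.
#' @slot lambda numeric(1), lasso penalty (>= 0).
#' @slot withinScales numeric, pooled within-class standard deviations after
#'   flooring (one per feature).
#' @slot featureMeans numeric, training feature means (on the transformed
#'   scale).
#' @slot loadings matrix, features x axes discriminant vectors.
#' @slot classCentroids matrix, classes x axes centroids in discriminant
#'   space.
#' @slot transform character(1), expression transform applied before fitting
#'   ("log10" or "none").
#' @slot objectiveTrace list of numeric, per-axis objective values across
#'   iterations (non-decreasing).
#' @slot converged logical, per axis.
#' @slot degenerateAxes integer, indices of axes whose loadings were wholly
#'   removed by the penalty.
#'
#' @seealso [fitPLDA()], [predictClade()], [rankLoadings()]
#' @exportClass DiscriminantModel
setClass("DiscriminantModel", representation(
    featureIds = "character",
    classLabels = "character",
    lambda = "numeric",
    withinScales = "numeric",
    featureMeans = "numeric",
    loadings = "matrix",
    classCentroids = "matrix",
    transform = "character",
    objectiveTrace = "list",
    converged = "logical",
    degenerateAxes = "integer"
))

setValidity("DiscriminantModel", function(object) {
    msg <- character()
    p <- length(object@featureIds)
    if (nrow(object@loadings) != p)
        msg <- c(msg, "loadings rows must match featureIds")
    if (length(object@withinScales) != p || any(object@withinScales <= 0))
        msg <- c(msg, "withinScales must be positive, one per feature")
    if (length(object@featureMeans) != p)
        msg <- c(msg, "featureMeans must match featureIds")
    if (nrow(object@classCentroids) != length(object@classLabels))
        msg <- c(msg, "classCentroids rows must match classLabels")
    if (ncol(object@classCentroids) != ncol(object@loadings))
        msg <- c(msg, "centroid and loading axis counts differ")
    if (object@lambda < 0)
        msg <- c(msg, "lambda must be >= 0")
    if (length(msg)) msg else TRUE
})

#' Sparse discriminant gene panel
#'
#' Top genes per discriminant axis ranked by absolute loading, and their
#' union, as used to refit a reduced classifier.
#'
#' @slot perAxis list of character vectors, top genes per axis in rank order.
#' @slot topK integer(1), requested genes per axis.
#' @slot unionSet character, ordered union of the per-axis lists.
#' @slot axisOfOrigin integer, for each union gene the first axis it entered
#'   from.
#'
#' @seealso [rankLoadings()], [sparseRefit()]
#' @exportClass SparsePanel
setClass("SparsePanel", representation(
    perAxis = "list",
    topK = "integer",
    unionSet = "character",
    axisOfOrigin = "integer"
))

setValidity("SparsePanel", function(object) {
    msg <- character()
    if (!setequal(object@unionSet, unique(unlist(object@perAxis))))
        msg <- c(msg, "unionSet must equal the union of per-axis lists")
    if (length(object@unionSet) > object@topK * length(object@perAxis))
        msg <- c(msg, "union larger than topK times the number of axes")
    if (length(object@axisOfOrigin) != length(object@unionSet))
        msg <- c(msg, "axisOfOrigin must annotate every union gene")
    if (length(msg)) msg else TRUE
})

#' Cross-validation result for the sparse discriminant classifier
#'
#' @slot nFolds integer(1).
#' @slot foldAssignment integer, fold per cell (named by cell id).
#' @slot perFoldAccuracy numeric, accuracy per fold.
#' @slot accuracy numeric(1), overall held-out accuracy in [0, 1].
#' @slot seed integer(1), seed used for fold assignment.
#' @slot lambdaGrid,gridAccuracy numeric, optional lambda tuning curve.
#'
#' @seealso [crossValidate()]
#' @exportClass CVResult
setClass("CVResult", representation(
    nFolds = "integer",
    foldAssignment = "integer",
    perFoldAccuracy = "numeric",
    accuracy = "numeric",
    seed = "integer",
    lambdaGrid = "numeric",
    gridAccuracy = "numeric"
))

setValidity("CVResult", function(object) {
    msg <- character()
    if (object@accuracy < 0 || object@accuracy > 1)
        msg <- c(msg, "accuracy must lie in [0, 1]")
    if (length(object@perFoldAccuracy) != object@nFolds)
        msg <- c(msg, "perFoldAccuracy must have one entry per fold")
    if (!all(object@foldAssignment %in% seq_len(object@nFolds)))
        msg <- c(msg, "fold assignment outside 1..nFolds")
    if (length(msg)) msg else TRUE
})

#' Predominant-OR call for one cell
#'
#' Ranked OR expression for a mature cell, the predominant OR, the fold ratio
#' of the two highest ORs, and the resulting clade label. A call is ambiguous
#' when the two top ORs come from different clades at less than two-fold
#' separation; no clade is emitted in that case.
#'
#' @slot cellId character(1).
#' @slot rankedOrs numeric, normalized counts sorted decreasing, named by OR.
#' @slot predominantOr character(1).
#' @slot foldRatio numeric(1), top/second normalized count, `Inf` when a
#'   single OR is detected.
#' @slot clade character(1), "A", "B", "C" or `NA` when ambiguous.
#' @slot ambiguous logical(1).
#'
#' @seealso [callPredominant()], [cladeCensus()]
#' @exportClass PredominantORCall
setClass("PredominantORCall", representation(
    cellId = "character",
    rankedOrs = "numeric",
    predominantOr = "character",
    foldRatio = "numeric",
    clade = "character",
    ambiguous = "logical"
))

setValidity("PredominantORCall", function(object) {
    msg <- character()
    if (is.unsorted(rev(object@rankedOrs)))
        msg <- c(msg, "rankedOrs must be sorted in decreasing order")
    if (length(object@rankedOrs) &&
        !identical(object@predominantOr, names(object@rankedOrs)[1L]))
        msg <- c(msg, "predominantOr must be the top-ranked OR")
    if (object@foldRatio < 1)
        msg <- c(msg, "foldRatio must be >= 1")
    if (object@ambiguous && !is.na(object@clade))
        msg <- c(msg, "ambiguous calls must not carry a clade")
    if (length(msg)) msg else TRUE
})

#' Gene-gene correlation blocks
#'
#' Pearson correlation between genes across cells with average-linkage
#' clustering on distance 1 - correlation, plus a clade-concordance summary
#' (mean within-clade correlation minus mean between-clade correlation).
#'
#' @slot geneIds character, genes in post-clustering leaf order.
#' @slot corr matrix, symmetric correlation matrix in input gene order.
#' @slot linkage the `hclust` merge tree.
#' @slot cladeAnnotation character, clade tag per gene (input order).
#' @slot concordance numeric(1).
#' @slot droppedGenes character, zero-variance genes removed before
#'   correlation.
#'
#' @seealso [correlationBlocks()]
#' @exportClass CorrelationBlocks
setClass("CorrelationBlocks", representation(
    geneIds = "character",
    corr = "matrix",
    linkage = "ANY",
    cladeAnnotation = "character",
    concordance = "numeric",
    droppedGenes = "character"
))

setValidity("CorrelationBlocks", function(object) {
    msg <- character()
    if (!isTRUE(all.equal(object@corr, t(object@corr), tolerance = 1e-8)))
        msg <- c(msg, "correlation matrix must be symmetric")
    if (any(abs(diag(object@corr) - 1) > 1e-8))
        msg <- c(msg, "correlation diagonal must be 1")
    if (!setequal(object@geneIds, colnames(object@corr)))
        msg <- c(msg, "leaf order must be a permutation of the matrix genes")
    if (length(msg)) msg else TRUE
})

#' Projection of bulk replicates onto a single-cell PCA space
#'
#' PCA fitted on single cells over a sparse gene panel; bulk replicates are
#' mapped into the fitted space and assigned to the nearest clade centroid in
#' the first two principal components.
#'
#' @slot pcLoadings matrix, features x 2 rotation.
#' @slot singleCellCoords matrix, cells x 2 scores.
#' @slot bulkCoords matrix, replicates x 2 scores.
#' @slot cladeCentroids matrix, 3 x 2 centroids.
#' @slot bulkAssignment character, clade per replicate.
#' @slot explainedVariance numeric, variance fraction per retained PC.
#'
#' @seealso [projectBulk()]
#' @exportClass ProjectionResult
setClass("ProjectionResult", representation(
    pcLoadings = "matrix",
    singleCellCoords = "matrix",
    bulkCoords = "matrix",
    cladeCentroids = "matrix",
    bulkAssignment = "character",
    explainedVariance = "numeric"
))

setValidity("ProjectionResult", function(object) {
    msg <- character()
    if (ncol(object@singleCellCoords) != ncol(object@pcLoadings))
        msg <- c(msg, "score and rotation dimensions differ")
    if (nrow(object@bulkCoords) != length(object@bulkAssignment))
        msg <- c(msg, "one assignment per bulk replicate required")
    if (length(msg)) msg else TRUE
})
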