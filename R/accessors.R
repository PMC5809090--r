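#' Accessors for fitted objects
#'
#' Slot accessors for the S4 result classes. `cladeLoadings()` returns the
#' feature x axis discriminant matrix, `classCentroids()` the class centroids
#' in discriminant space, `penalty()` the lasso penalty, `featureIds()` the
#' genes in model order, `panelGenes()` the union gene set of a sparse panel,
#' `perAxisGenes()` its per-axis ranked lists, `cvAccuracy()` the overall
#' cross-validated accuracy, `foldAssignment()` the fold index per cell,
#' `predominantOr()`, `foldRatio()`, `cladeOf()` and `isAmbiguous()` the
#' fields of a predominant-OR call, and `concordance()` the clade-concordance
#' score of a correlation-block object.
#'
#' @param object an S4 object from this package.
#' @return The slot value; see the class documentation for details.
#' @examples
#' tbl <- loadTable1()
#' call <- callPredominant(tbl[["s20545"]], cellId = "s20545")
#' cladeOf(call)
#' foldRatio(call)
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("featureIds", function(object) standardGeneric("featureIds"))
#' @rdname accessors
#' @export
setMethod("featureIds", "DiscriminantModel", function(object) object@featureIds)

#' @rdname accessors
#' @export
setGeneric("cladeLoadings", function(object) standardGeneric("cladeLoadings"))
#' @rdname accessors
#' @export
setMethod("cladeLoadings", "DiscriminantModel", function(object) {
    structure(object@loadings,
              dimnames = list(object@featureIds,
                              paste0("V", seq_len(ncol(object@loadings)))))
})

#' @rdname accessors
#' @export
setGeneric("classCentroids", function(object) standardGeneric("classCentroids"))
#' @rdname accessors
#' @export
setMethod("classCentroids", "DiscriminantModel", function(object) {
    structure(object@classCentroids,
              dimnames = list(object@classLabels,
                              paste0("V", seq_len(ncol(object@classCentroids)))))
})

#' @rdname accessors
#' @export
setGeneric("penalty", function(object) standardGeneric("penalty"))
#' @rdname accessors
#' @export
setMethod("penalty", "DiscriminantModel", function(object) object@lambda)

#' @rdname accessors
#' @export
setGeneric("panelGenes", function(object) standardGeneric("panelGenes"))
#' @rdname accessors
#' @export
setMethod("panelGenes", "SparsePanel", function(object) object@unionSet)

#' @rdname accessors
#' @export
setGeneric("perAxisGenes", function(object) standardGeneric("perAxisGenes"))
#' @rdname accessors
#' @export
setMethod("perAxisGenes", "SparsePanel", function(object) object@perAxis)

#' @rdname accessors
#' @export
setGeneric("cvAccuracy", function(object) standardGeneric("cvAccuracy"))
#' @rdname accessors
#' @export
setMethod("cvAccuracy", "CVResult", function(object) object@accuracy)

#' @rdname accessors
#' @export
setGeneric("foldAssignment", function(object) standardGeneric("foldAssignment"))
#' @rdname accessors
#' @export
setMethod("foldAssignment", "CVResult", function(object) object@foldAssignment)

#' @rdname accessors
#' @export
setGeneric("predominantOr", function(object) standardGeneric("predominantOr"))
#' @rdname accessors
#' @export
setMethod("predominantOr", "PredominantORCall",
          function(object) object@predominantOr)

#' @rdname accessors
#' @export
setGeneric("foldRatio", function(object) standardGeneric("foldRatio"))
#' @rdname accessors
#' @export
setMethod("foldRatio", "PredominantORCall", function(object) object@foldRatio)

#' @rdname accessors
#' @export
setGeneric("cladeOf", function(object) standardGeneric("cladeOf"))
#' @rdname accessors
#' @export
setMethod("cladeOf", "PredominantORCall", function(object) object@clade)

#' @rdname accessors
#' @export
setGeneric("isAmbiguous", function(object) standardGeneric("isAmbiguous"))
#' @rdname accessors
#' @export
setMethod("isAmbiguous", "PredominantORCall", function(object) object@ambiguous)

#' @rdname accessors
#' @export
setGeneric("rankedOrs", function(object) standardGeneric("rankedOrs"))
#' @rdname accessors
#' @export
setMethod("rankedOrs", "PredominantORCall", function(object) object@rankedOrs)

#' @rdname accessors
#' @export
setGeneric("concordance", function(object) standardGeneric("concordance"))
#' @rdname accessors
#' @export
setMethod("concordance", "CorrelationBlocks", function(object) object@concordance)

#' @rdname accessors
#' @export
setGeneric("bulkAssignment", function(object) standardGeneric("bulkAssignment"))
#' @rdname accessors
#' @export
setMethod("bulkAssignment", "ProjectionResult",
          function(object) object@bulkAssignment)

setMethod("show", "SimSpec", function(object) {
    cat("SimSpec:",
        sum(object@nCellsPerClade), "mature OR cells (",
        paste(object@nCellsPerClade, collapse = "/"), "per clade ),",
        object@nImmature, "immature,",
        object@nMatureNoOR, "mature without OR;",
        object@nGenes, "genes\n")
    cat("  planted markers per clade:",
        paste(object@nPlantedMarkersPerClade, collapse = "/"),
        "at log2 fc", object@plantedLog2Fc, "\n")
    cat("  predominant OR fraction:", object@predominantOrFraction,
        "; seed:", object@seed, "\n")
})

setMethod("show", "DiscriminantModel", function(object) {
    nz <- colSums(object@loadings != 0)
    cat("DiscriminantModel:", length(object@featureIds), "features,",
        length(object@classLabels), "classes (",
        paste(object@classLabels, collapse = ", "), ")\n")
    cat("  lambda:", object@lambda, "; nonzero loadings per axis:",
        paste(nz, collapse = ", "), "\n")
    if (length(object@degenerateAxes))
        cat("  degenerate axes:",
            paste(object@degenerateAxes, collapse = ", "), "\n")
})

setMethod("show", "SparsePanel", function(object) {
    cat("SparsePanel: top", object@topK, "genes per axis over",
        length(object@perAxis), "axes; union of",
        length(object@unionSet), "genes\n")
})

setMethod("show", "CVResult", function(object) {
    cat("CVResult:", object@nFolds, "stratified folds, overall accuracy",
        sprintf("%.3f", object@accuracy), "\n")
})

setMethod("show", "PredominantORCall", function(object) {
    cat("PredominantORCall", object@cellId, ":",
        object@predominantOr,
        sprintf("(fold ratio %s)",
                if (is.infinite(object@foldRatio)) "Inf"
                else sprintf("%.2f", object@foldRatio)),
        if (object@ambiguous) "AMBIGUOUS" else paste("clade", object@clade),
        "\n")
})

setMethod("show", "CorrelationBlocks", function(object) {
    cat("CorrelationBlocks:", ncol(object@corr), "genes, concordance",
        sprintf("%.3f", object@concordance), "\n")
})

setMethod("show", "ProjectionResult", function(object) {
    cat("ProjectionResult:", nrow(object@singleCellCoords),
        "single cells,", nrow(object@bulkCoords), "bulk replicates ->",
        paste(object@bulkAssignment, collapse = ", "), "\n")
})
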