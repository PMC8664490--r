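#' @rdname FilteredAlignment-class
#' @param x a \linkS4class{FilteredAlignment} or \linkS4class{FamilyCounts}
#'   object.
#' @export
setGeneric("alignmentOverlap", function(x) standardGeneric("alignmentOverlap"))

#' @rdname FilteredAlignment-class
#' @export
setGeneric("keptBlocks", function(x) standardGeneric("keptBlocks"))

#' @rdname FilteredAlignment-class
#' @export
setGeneric("saturation", function(x) standardGeneric("saturation"))

#' @rdname FilteredAlignment-class
#' @export
setGeneric("filteredSequences", function(x) standardGeneric("filteredSequences"))

#' @rdname FamilyCounts-class
#' @param x a \linkS4class{FamilyCounts} object.
#' @export
setGeneric("branchCounts", function(x) standardGeneric("branchCounts"))

#' @rdname FamilyCounts-class
#' @export
setGeneric("totalSubstitutions", function(x) standardGeneric("totalSubstitutions"))

#' @rdname FamilyCounts-class
#' @export
setGeneric("categoryCounts", function(x) standardGeneric("categoryCounts"))

#' @rdname MeanTree-class
#' @param x a \linkS4class{MeanTree} object.
#' @export
setGeneric("meanBranchLengths", function(x) standardGeneric("meanBranchLengths"))

#' @rdname FilteredAlignment-class
#' @export
setGeneric("familyId", function(x) standardGeneric("familyId"))

## ---- accessors -------------------------------------------------------------

#' @rdname FilteredAlignment-class
#' @export
setMethod("alignmentOverlap", "FilteredAlignment", function(x) x@L)

#' @rdname FamilyCounts-class
#' @export
setMethod("alignmentOverlap", "FamilyCounts", function(x) x@L)

#' @rdname FilteredAlignment-class
#' @export
setMethod("keptBlocks", "FilteredAlignment", function(x) x@blocks)

#' @rdname FilteredAlignment-class
#' @export
setMethod("saturation", "FilteredAlignment", function(x) x@saturation)

#' @rdname FilteredAlignment-class
#' @export
setMethod("filteredSequences", "FilteredAlignment", function(x) x@seqs)

#' @rdname FilteredAlignment-class
#' @export
setMethod("familyId", "FilteredAlignment", function(x) x@familyId)

#' @rdname FamilyCounts-class
#' @export
setMethod("familyId", "FamilyCounts", function(x) x@familyId)

#' @rdname FamilyCounts-class
#' @export
setMethod("branchCounts", "FamilyCounts", function(x) x@counts)

#' @rdname FamilyCounts-class
#' @export
setMethod("totalSubstitutions", "FamilyCounts", function(x) x@N)

#' @rdname FamilyCounts-class
#' @export
setMethod("categoryCounts", "FamilyCounts", function(x) x@categoryCounts)

#' @rdname MeanTree-class
#' @export
setMethod("meanBranchLengths", "MeanTree", function(x) x@pcbar)

## ---- show methods ----------------------------------------------------------

setMethod("show", "SimulationParams", function(object) {
    cat("SimulationParams:", object@nFamilies, "families, length",
        paste(object@lengthRange, collapse = "-"), "\n")
    cat("  branch rates:",
        paste(sprintf("%s=%.4g", .BRANCHES, object@branchRates),
              collapse = " "), "\n")
    cat("  family rate multiplier: gamma(shape=", object@familyShape,
        ", mean=1)\n", sep = "")
    if (object@episodicFraction > 0 && !is.na(object@episodicBranch))
        cat("  episodic:", sprintf("%.0f%%", 100 * object@episodicFraction),
            "of families,", object@episodicFold, "fold on",
            object@episodicBranch, "\n")
    cat("  indel rate:", object@indelRate, " seed:", object@seed, "\n")
})

setMethod("show", "FilteredAlignment", function(object) {
    cat("FilteredAlignment", object@familyId, "\n")
    cat("  L =", object@L, "kept columns in", length(object@blocks),
        "block(s); shortest ortholog", object@shortestLen, "aa;",
        sprintf("saturation %.2f%%\n", object@saturation))
    if (object@L == 0L)
        cat("  [non-overlapping family: no conserved block survived]\n")
})

setMethod("show", "FamilyCounts", function(object) {
    cat("FamilyCounts", object@familyId, ": N =", object@N, "of L =",
        object@L, "\n  ")
    cat(paste(sprintf("%s=%d", .BRANCHES, object@counts), collapse = " "),
        "\n")
})

setMethod("show", "MeanTree", function(object) {
    cat("MeanTree over", object@nFamiliesUsed, "substituted families (",
        object@nZeroFamilies, "zero-substitution families excluded)\n  ")
    cat(paste(sprintf("%s=%.6f", .BRANCHES, object@pcbar), collapse = " "),
        "\n")
})

setMethod("show", "SimulationNull", function(object) {
    cat("SimulationNull: N =", object@N, ",", object@S, "replicates\n")
})
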