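#' @rdname FundusImage-class
#' @param x a FundusImage
#' @export
setGeneric("pixels", function(x) standardGeneric("pixels"))
#' @rdname FundusImage-class
#' @export
setGeneric("laterality", function(x) standardGeneric("laterality"))
#' @rdname FundusImage-class
#' @export
setGeneric("eyeId", function(x) standardGeneric("eyeId"))

#' @rdname RoiSet-class
#' @param x an RoiSet
#' @export
setGeneric("discContour", function(x) standardGeneric("discContour"))
#' @rdname RoiSet-class
#' @export
setGeneric("ppaContour", function(x) standardGeneric("ppaContour"))
#' @rdname RoiSet-class
#' @export
setGeneric("maculaXY", function(x) standardGeneric("maculaXY"))
#' @rdname RoiSet-class
#' @export
setGeneric("discMask", function(x) standardGeneric("discMask"))
#' @rdname RoiSet-class
#' @export
setGeneric("ppaMask", function(x) standardGeneric("ppaMask"))
#' @rdname RoiSet-class
#' @export
setGeneric("hasPPA", function(x) standardGeneric("hasPPA"))

#' @rdname FeatureTable-class
#' @param x a FeatureTable
#' @export
setGeneric("featureMatrix", function(x) standardGeneric("featureMatrix"))
#' @rdname FeatureTable-class
#' @export
setGeneric("featureCategories", function(x) standardGeneric("featureCategories"))
#' @rdname FeatureTable-class
#' @export
setGeneric("severeLabels", function(x) standardGeneric("severeLabels"))
#' @rdname FeatureTable-class
#' @export
setGeneric("splitTag", function(x) standardGeneric("splitTag"))

#' @rdname SelectionTrace-class
#' @param x a SelectionTrace
#' @export
setGeneric("selectionScores", function(x) standardGeneric("selectionScores"))
#' @rdname SelectionTrace-class
#' @export
setGeneric("chosenK", function(x) standardGeneric("chosenK"))
#' @rdname SelectionTrace-class
#' @export
setGeneric("finalSet", function(x) standardGeneric("finalSet"))

setMethod("pixels", "FundusImage", function(x) x@pixels)
setMethod("laterality", "FundusImage", function(x) x@laterality)
setMethod("eyeId", "FundusImage", function(x) x@eyeId)

setMethod("discContour", "RoiSet", function(x) x@discContour)
setMethod("ppaContour", "RoiSet", function(x) x@ppaContour)
setMethod("maculaXY", "RoiSet", function(x) x@macula)
setMethod("discMask", "RoiSet", function(x) x@discMask)
setMethod("ppaMask", "RoiSet", function(x) x@ppaMask)
setMethod("hasPPA", "RoiSet", function(x) sum(x@ppaMask) > 0L)

setMethod("featureMatrix", "FeatureTable", function(x)
  t(SummarizedExperiment::assay(x, "features")))
setMethod("featureCategories", "FeatureTable", function(x)
  setNames(as.character(SummarizedExperiment::rowData(x)$category),
           rownames(x)))
setMethod("severeLabels", "FeatureTable", function(x)
  setNames(as.integer(SummarizedExperiment::colData(x)$severe), colnames(x)))
setMethod("splitTag", "FeatureTable", function(x)
  setNames(as.character(SummarizedExperiment::colData(x)$split), colnames(x)))

setMethod("selectionScores", "SelectionTrace", function(x) x@trace)
setMethod("chosenK", "SelectionTrace", function(x) x@chosenK)
setMethod("finalSet", "SelectionTrace", function(x) x@finalSet)

setMethod("show", "FundusImage", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("FundusImage '%s' (%s eye): %d x %d x 3, dpi %g\n",
              object@eyeId, object@laterality, d[1], d[2], object@dpi))
})

setMethod("show", "RoiSet", function(object) {
  cat(sprintf(
    "RoiSet: disc %d px (contour %d pts), PPA %d px, macula (%.1f, %.1f)\n",
    sum(object@discMask), nrow(object@discContour), sum(object@ppaMask),
    object@macula[1], object@macula[2]))
})

setMethod("show", "SelectionTrace", function(object) {
  cat(sprintf("SelectionTrace: %d cardinalities, criterion %s\n",
              nrow(object@trace), object@criterion))
  if (!is.na(object@chosenK))
    cat(sprintf("  chosen k = %d: %s\n", object@chosenK,
                paste(object@finalSet, collapse = ", ")))
})

setMethod("show", "EvalReport", function(object) {
  cat("EvalReport\n  validation AUC:",
      paste(sprintf("%s=%.3f", names(object@setAuc), object@setAuc),
            collapse = "  "), "\n")
  cat(sprintf("  univariate table: %d features; profiles: %d\n",
              nrow(object@univariate),
              length(object@profiles$features %||% character(0))))
})

`%||%` <- function(a, b) if (is.null(a)) b else a
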