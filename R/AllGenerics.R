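#' @name coralhue-accessors
#' @title Accessors for coralhue S4 classes
#' @description Small accessor generics so downstream code never touches
#'   slots directly.
#' @param x an object of the relevant class
#' @return the accessed component
NULL

#' @rdname coralhue-accessors
#' @export
setGeneric("nPixels", function(x) standardGeneric("nPixels"))

#' @rdname coralhue-accessors
#' @export
setGeneric("binCount", function(x) standardGeneric("binCount"))

#' @rdname coralhue-accessors
#' @export
setGeneric("binProportions", function(x) standardGeneric("binProportions"))

#' @rdname coralhue-accessors
#' @export
setGeneric("binCentroids", function(x) standardGeneric("binCentroids"))

#' @rdname coralhue-accessors
#' @export
setGeneric("speciesId", function(x) standardGeneric("speciesId"))

#' @rdname coralhue-accessors
#' @export
setGeneric("categoryIndices", function(x) standardGeneric("categoryIndices"))

#' @rdname coralhue-accessors
#' @export
setGeneric("reefId", function(x) standardGeneric("reefId"))

#' @rdname coralhue-accessors
#' @export
setGeneric("binWeights", function(x) standardGeneric("binWeights"))

#' @rdname coralhue-accessors
#' @export
setGeneric("adjustedR2", function(x) standardGeneric("adjustedR2"))

#' @rdname coralhue-accessors
#' @export
setGeneric("aicValue", function(x) standardGeneric("aicValue"))

#' @rdname coralhue-accessors
#' @export
setGeneric("modelLabel", function(x) standardGeneric("modelLabel"))

#' @rdname coralhue-accessors
#' @export
setGeneric("deltaAic", function(x) standardGeneric("deltaAic"))

#' @rdname coralhue-accessors
#' @export
setGeneric("bestModel", function(x) standardGeneric("bestModel"))

#' @rdname coralhue-accessors
#' @export
setMethod("nPixels", "ColourHistogram", function(x) x@nPixels)

#' @rdname coralhue-accessors
#' @export
setMethod("binCount", "ColourHistogram", function(x) nrow(x@bins))

#' @rdname coralhue-accessors
#' @export
setMethod("binProportions", "ColourHistogram", function(x) x@bins$proportion)

#' @rdname coralhue-accessors
#' @export
setMethod("binCentroids", "ColourHistogram",
          function(x) as.matrix(x@bins[, c("r", "g", "b")]))

#' @rdname coralhue-accessors
#' @export
setMethod("speciesId", "HueProfile", function(x) x@speciesId)

#' @rdname coralhue-accessors
#' @export
setMethod("categoryIndices", "HueProfile", function(x) x@categories)

#' @rdname coralhue-accessors
#' @export
setMethod("reefId", "ColourSignature", function(x) x@reefId)

#' @rdname coralhue-accessors
#' @export
setMethod("binWeights", "ColourSignature", function(x) x@bins$weight)

#' @rdname coralhue-accessors
#' @export
setMethod("binCentroids", "ColourSignature",
          function(x) as.matrix(x@bins[, c("r", "g", "b")]))

#' @rdname coralhue-accessors
#' @export
setMethod("binCount", "ColourSignature", function(x) nrow(x@bins))

#' @rdname coralhue-accessors
#' @export
setMethod("adjustedR2", "ModelFit", function(x) x@adjustedR2)

#' @rdname coralhue-accessors
#' @export
setMethod("aicValue", "ModelFit", function(x) x@aic)

#' @rdname coralhue-accessors
#' @export
setMethod("modelLabel", "ModelFit", function(x) x@modelLabel)

#' @rdname coralhue-accessors
#' @export
setMethod("deltaAic", "ModelComparison", function(x) x@deltaAic)

#' @rdname coralhue-accessors
#' @export
setMethod("bestModel", "ModelComparison", function(x) x@best)

#' @rdname coralhue-accessors
#' @export
setMethod("coef", "ModelFit", function(object, ...) object@coefficients)

setMethod("show", "IsccTable", function(object) {
  cat("IsccTable with", nrow(object@categories), "categories (",
      sum(object@categories$achromatic == 1), "achromatic ), matching in",
      object@colourSpace, "\n")
})

setMethod("show", "ColourHistogram", function(object) {
  cat("ColourHistogram:", nrow(object@bins), "occupied of",
      object@binsPerChannel^3, "bins,", object@nPixels, "pixels",
      if (object@renormalised) "(rare bins excluded)" else "", "\n")
})

setMethod("show", "HueProfile", function(object) {
  cat("HueProfile for", object@speciesId, ":",
      length(object@categories), "categories from",
      object@nBinsRetained, "bins\n")
})

setMethod("show", "ColourSignature", function(object) {
  cat("ColourSignature for", object@reefId, ":", nrow(object@bins),
      "bins, total weight", format(sum(object@bins$weight)), "\n")
})

setMethod("show", "ModelFit", function(object) {
  cat(sprintf("ModelFit '%s': %s ~ %s\n", object@modelLabel, object@response,
              paste(object@predictors, collapse = " + ")))
  cat(sprintf("  adj. R^2 = %.3f, F(%d, %d) = %.2f, p = %.3g, AIC = %.2f, n = %d\n",
              object@adjustedR2, object@dfModel, object@dfResidual,
              object@fStatistic, object@pValue, object@aic, object@n))
  if (length(object@notes)) cat("  notes:", paste(object@notes, collapse = "; "), "\n")
})

setMethod("show", "ModelComparison", function(object) {
  cat("ModelComparison of", length(object@fits), "models; best:",
      object@best, "\n")
  print(round(object@deltaAic, 3))
})

setMethod("show", "ReefDistanceMatrix", function(object) {
  cat("ReefDistanceMatrix over", length(object@ids), "reefs\n")
  print(round(object@values[object@ordering, object@ordering], 2))
})
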