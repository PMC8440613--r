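## Central S4 containers.  Validity methods enforce the structural invariants
## the pipeline relies on; accessors live in AllGenerics.R / the module files.

#' ISCC-NBS Level-3 style colour category table
#'
#' Holds the 267 named colour categories with sRGB reference centroids used to
#' classify histogram bins, together with the pre-computed coordinates in the
#' perceptual space used for nearest-centroid matching.
#'
#' @slot categories data.frame with columns `index`, `name`, `r`, `g`, `b`,
#'   `achromatic`; one row per category, indices unique and contiguous from 1.
#' @slot colourSpace label of the space used for nearest-centroid matching,
#'   `"Lab"` (CIELAB, default) or `"sRGB"`.
#' @slot matchCoords numeric matrix of centroid coordinates in `colourSpace`,
#'   one row per category.
#' @seealso [loadIsccTable()], [classifySrgb()]
#' @export
setClass("IsccTable",
  representation(categories = "data.frame",
                 colourSpace = "character",
                 matchCoords = "matrix"))

setValidity("IsccTable", function(object) {
  cats <- object@categories
  need <- c("index", "name", "r", "g", "b", "achromatic")
  if (!all(need %in% names(cats)))
    return(paste("categories must have columns:", paste(need, collapse = ", ")))
  if (nrow(cats) < 1L) return("empty category table")
  if (!identical(as.integer(cats$index), seq_len(nrow(cats))))
    return("category indices must be 1..n in order")
  if (anyDuplicated(cats$name)) return("category names must be unique")
  rgb <- as.matrix(cats[, c("r", "g", "b")])
  if (any(rgb < 0 | rgb > 255)) return("centroid channels must lie in [0,255]")
  if (!object@colourSpace %in% c("Lab", "sRGB"))
    return("colourSpace must be 'Lab' or 'sRGB'")
  if (nrow(object@matchCoords) != nrow(cats))
    return("matchCoords must have one row per category")
  TRUE
})

#' Discrete multidimensional colour histogram of an image
#'
#' Each sRGB channel is divided into `binsPerChannel` equal-width regions;
#' a bin is one region combination and carries the proportion of pixels it
#' received and the mean sRGB colour of those pixels.
#'
#' @slot binsPerChannel integer number of regions per channel (>= 2).
#' @slot bins data.frame with columns `binR`, `binG`, `binB` (1-based region
#'   indices), `proportion`, and `r`, `g`, `b` (pixel-mean centroid, 0-255).
#' @slot nPixels number of unmasked pixels considered.
#' @slot renormalised TRUE once rare-bin exclusion has renormalised the
#'   proportions.
#' @seealso [binImage()], [excludeRareBins()]
#' @export
setClass("ColourHistogram",
  representation(binsPerChannel = "integer",
                 bins = "data.frame",
                 nPixels = "integer",
                 renormalised = "logical"))

setValidity("ColourHistogram", function(object) {
  k <- object@binsPerChannel
  b <- object@bins
  if (k < 2L) return("binsPerChannel must be >= 2")
  need <- c("binR", "binG", "binB", "proportion", "r", "g", "b")
  if (!all(need %in% names(b)))
    return(paste("bins must have columns:", paste(need, collapse = ", ")))
  if (nrow(b) < 1L) return("histogram has no occupied bins")
  if (nrow(b) > k^3) return("more occupied bins than binsPerChannel^3")
  if (any(b$proportion <= 0 | b$proportion > 1))
    return("bin proportions must lie in (0,1]")
  if (abs(sum(b$proportion) - 1) > 1e-9)
    return("bin proportions must sum to 1")
  idx <- as.matrix(b[, c("binR", "binG", "binB")])
  if (any(idx < 1 | idx > k)) return("bin indices out of range")
  w <- 256 / k
  ctr <- as.matrix(b[, c("r", "g", "b")])
  if (any(ctr < (idx - 1) * w - 1e-9) || any(ctr >= idx * w + 1e-9))
    return("bin centroid lies outside its region of the sRGB cube")
  TRUE
})

#' Hue profile of a species image
#'
#' The set of distinct ISCC-NBS-style colour categories obtained by
#' classifying the retained histogram bins of one image.
#'
#' @slot speciesId identifier of the photographed species.
#' @slot categories sorted integer vector of distinct category indices.
#' @slot nBinsRetained number of histogram bins that survived rare-bin
#'   exclusion (>= length(categories); distinct bins may share a category).
#' @seealso [histogramToProfile()], [quantifyImage()]
#' @export
setClass("HueProfile",
  representation(speciesId = "character",
                 categories = "integer",
                 nBinsRetained = "integer"))

setValidity("HueProfile", function(object) {
  if (length(object@speciesId) != 1L) return("speciesId must be length 1")
  if (length(object@categories) < 1L) return("profile must be non-empty")
  if (is.unsorted(object@categories, strictly = TRUE))
    return("categories must be sorted and distinct")
  if (any(object@categories < 1L)) return("category indices must be >= 1")
  if (length(object@categories) > object@nBinsRetained)
    return("more categories than retained bins")
  TRUE
})

#' Colour signature of a reef seascape image
#'
#' A mass-1 weighted set of sRGB bin centroids, the input to the earth
#' mover's distance.
#'
#' @slot reefId identifier of the reef image.
#' @slot bins data.frame with columns `r`, `g`, `b` (centroid, 0-255) and
#'   `weight` (positive, summing to 1).
#' @seealso [buildSignature()], [emd()]
#' @export
setClass("ColourSignature",
  representation(reefId = "character", bins = "data.frame"))

setValidity("ColourSignature", function(object) {
  b <- object@bins
  if (!all(c("r", "g", "b", "weight") %in% names(b)))
    return("bins must have columns r, g, b, weight")
  if (nrow(b) < 1L) return("signature has no bins")
  if (any(b$weight <= 0)) return("weights must be positive")
  if (abs(sum(b$weight) - 1) > 1e-9) return("weights must sum to 1")
  TRUE
})

#' One fitted regression model
#'
#' Coefficients are reported on the raw predictor basis (intercept, linear,
#' quadratic, ...) even when the model is fitted on an orthogonal polynomial
#' basis for numerical stability; standard errors are transformed accordingly.
#'
#' @slot modelLabel short label, e.g. `"combined"`.
#' @slot response name of the response variable.
#' @slot predictors character description of the predictor terms.
#' @slot coefficients named numeric vector of raw-basis estimates.
#' @slot coefficientSe named numeric vector of matching standard errors.
#' @slot adjustedR2,fStatistic,pValue,aic summary statistics; `aic` uses the
#'   n*log(RSS/n) + 2k convention with k counting the intercept and the error
#'   variance.
#' @slot dfModel,dfResidual,n integer degrees of freedom and sample size.
#' @slot rss residual sum of squares.
#' @slot notes character vector of fitting notes (e.g. "underpowered").
#' @slot fit the underlying `lm`/`nls` object (or NULL).
#' @export
setClass("ModelFit",
  representation(modelLabel = "character",
                 response = "character",
                 predictors = "character",
                 coefficients = "numeric",
                 coefficientSe = "numeric",
                 adjustedR2 = "numeric",
                 fStatistic = "numeric",
                 dfModel = "integer",
                 dfResidual = "integer",
                 pValue = "numeric",
                 aic = "numeric",
                 n = "integer",
                 rss = "numeric",
                 notes = "character",
                 fit = "ANY"))

setValidity("ModelFit", function(object) {
  if (object@adjustedR2 > 1 + 1e-12) return("adjusted R^2 cannot exceed 1")
  if (object@pValue < 0 || object@pValue > 1) return("p-value outside [0,1]")
  if (object@n < object@dfModel + 2L) return("n too small for model df")
  if (object@rss < -1e-9) return("negative residual sum of squares")
  TRUE
})

#' AIC comparison of a set of model fits
#'
#' @slot fits list of [ModelFit-class] objects sharing response and n.
#' @slot deltaAic named numeric of AIC differences from the best model.
#' @slot best label of the best (lowest-AIC) model; ties break to the first.
#' @seealso [compareAIC()]
#' @export
setClass("ModelComparison",
  representation(fits = "list", deltaAic = "numeric", best = "character"))

setValidity("ModelComparison", function(object) {
  if (length(object@fits) < 1L) return("no fits to compare")
  if (any(object@deltaAic < -1e-9)) return("delta AIC must be >= 0")
  if (abs(object@deltaAic[object@best]) > 1e-9)
    return("best model must have delta AIC 0")
  TRUE
})

#' Symmetric reef colour dissimilarity matrix
#'
#' Pairwise earth mover's distances between reef colour signatures, with a
#' similarity ordering from average-linkage agglomerative clustering.
#'
#' @slot ids reef identifiers (unique).
#' @slot values symmetric numeric matrix of non-negative distances.
#' @slot ordering integer permutation of ids from the clustering dendrogram.
#' @slot tree the `hclust` object used for the ordering.
#' @seealso [reefDistanceMatrix()]
#' @export
setClass("ReefDistanceMatrix",
  representation(ids = "character", values = "matrix",
                 ordering = "integer", tree = "ANY"))

setValidity("ReefDistanceMatrix", function(object) {
  v <- object@values
  if (anyDuplicated(object@ids)) return("reef ids must be unique")
  if (nrow(v) != length(object@ids) || ncol(v) != length(object@ids))
    return("matrix dimensions must match ids")
  if (any(abs(diag(v)) > 1e-9)) return("diagonal must be zero")
  if (max(abs(v - t(v))) > 1e-9) return("matrix must be symmetric")
  if (any(v < -1e-12)) return("distances must be non-negative")
  if (!identical(sort(object@ordering), seq_along(object@ids)))
    return("ordering must be a permutation of the ids")
  TRUE
})
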