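## ISCC-NBS Level-3 style colour system: the bundled 267-category table and
## the nearest-centroid mapping from sRGB coordinates to a category.

#' Load the bundled 267-category colour table
#'
#' Reads the packaged Level-3 ISCC-NBS-style category table (267 categories:
#' 262 chromatic, 5 achromatic, each with an sRGB reference centroid) and
#' precomputes centroid coordinates in the perceptual space used for
#' nearest-centroid classification.
#'
#' The bundled table is a synthetic reconstruction of the ISCC-NBS Level-3
#' structure (see `iscc_nbs_level3_synthetic.csv` under `extdata` and the
#' methods vignette): category count, naming conventions and achromatic flags
#' follow the system, while the centroids are generated from an LCh
#' parameterisation rather than transcribed from the published Munsell-based
#' listing.
#'
#' @param path path to a category CSV with columns
#'   `index,name,r,g,b,achromatic`; defaults to the bundled table.
#' @param colourSpace space for nearest-centroid matching: `"Lab"` (CIELAB
#'   under D65, the default) or `"sRGB"` (plain Euclidean on channels).
#' @return an [IsccTable-class] object with 267 categories.
#' @examples
#' tab <- loadIsccTable()
#' tab
#' @export
loadIsccTable <- function(path = NULL, colourSpace = c("Lab", "sRGB")) {
  colourSpace <- match.arg(colourSpace)
  if (is.null(path)) {
    path <- system.file("extdata", "iscc_nbs_level3_synthetic.csv",
                        package = "coralhue")
  }
  if (!nzchar(path) || !file.exists(path)) {
    stop("ISCC-NBS category table not found at '", path,
         "': package resource missing or corrupt", call. = FALSE)
  }
  cats <- tryCatch(read.csv(path, stringsAsFactors = FALSE),
                   error = function(e) {
                     stop("failed to read ISCC-NBS category table '", path,
                          "': ", conditionMessage(e), call. = FALSE)
                   })
  need <- c("index", "name", "r", "g", "b", "achromatic")
  if (!all(need %in% names(cats)))
    stop("ISCC-NBS category table '", path, "' is corrupt: expected columns ",
         paste(need, collapse = ", "), call. = FALSE)
  cats <- cats[order(cats$index), need]
  coords <- .matchCoords(as.matrix(cats[, c("r", "g", "b")]), colourSpace)
  new("IsccTable", categories = cats, colourSpace = colourSpace,
      matchCoords = coords)
}

## centroid coordinates in the matching space (rows of rgb are 0-255 triples)
.matchCoords <- function(rgb, colourSpace) {
  if (colourSpace == "sRGB") {
    m <- rgb
  } else {
    m <- grDevices::convertColor(rgb / 255, from = "sRGB", to = "Lab")
  }
  storage.mode(m) <- "double"
  dimnames(m) <- NULL
  m
}

#' Number of categories in a colour table
#' @param table an [IsccTable-class]
#' @return integer count
#' @export
nCategories <- function(table) nrow(table@categories)

#' Look up categories by index or name
#'
#' @param table an [IsccTable-class]
#' @param index integer category indices
#' @param name character category names (used when `index` is missing)
#' @return data.frame rows of the category table
#' @examples
#' tab <- loadIsccTable()
#' isccCategory(tab, 1)
#' isccCategory(tab, name = "black")
#' @export
isccCategory <- function(table, index, name = NULL) {
  stopifnot(is(table, "IsccTable"))
  cats <- table@categories
  if (missing(index) || is.null(index)) {
    pos <- match(name, cats$name)
    if (anyNA(pos)) stop("unknown category name: ",
                         paste(name[is.na(pos)], collapse = ", "))
  } else {
    pos <- match(as.integer(index), cats$index)
    if (anyNA(pos)) stop("unknown category index: ",
                         paste(index[is.na(pos)], collapse = ", "))
  }
  cats[pos, , drop = FALSE]
}

## half-up rounding (round() rounds half to even; channel means are pixel
## averages and the hex convention here is half-up)
.roundHalfUp <- function(x) floor(x + 0.5)

#' Convert an sRGB triple to a hexadecimal colour code
#'
#' Channels are rounded half-up to integers first; the result is a lowercase
#' 6-hex-digit string that round-trips through [hexToSrgb()].
#'
#' @param rgb length-3 numeric vector, or an n x 3 matrix, of channel values
#'   in \[0, 255\]
#' @return character vector of 6-digit lowercase hex codes (no `#`)
#' @examples
#' srgbToHex(c(171, 205, 16))   # "abcd10"
#' @export
srgbToHex <- function(rgb) {
  m <- .asRgbMatrix(rgb)
  m <- .roundHalfUp(m)
  if (any(m < 0 | m > 255))
    stop("sRGB channels must lie in [0, 255]", call. = FALSE)
  sprintf("%02x%02x%02x", m[, 1], m[, 2], m[, 3])
}

#' @rdname srgbToHex
#' @param hex character vector of 6-hex-digit codes (leading `#` allowed)
#' @return for `hexToSrgb`, an n x 3 integer matrix of channel values
#' @export
hexToSrgb <- function(hex) {
  hex <- sub("^#", "", tolower(hex))
  if (any(!grepl("^[0-9a-f]{6}$", hex)))
    stop("expected 6-hex-digit colour codes", call. = FALSE)
  m <- cbind(r = strtoi(substr(hex, 1, 2), 16L),
             g = strtoi(substr(hex, 3, 4), 16L),
             b = strtoi(substr(hex, 5, 6), 16L))
  m
}

.asRgbMatrix <- function(rgb) {
  if (is.null(dim(rgb))) {
    if (length(rgb) != 3L) stop("expected an sRGB triple", call. = FALSE)
    rgb <- matrix(as.numeric(rgb), nrow = 1L)
  } else {
    rgb <- as.matrix(rgb)
    if (ncol(rgb) != 3L) stop("expected an n x 3 sRGB matrix", call. = FALSE)
    storage.mode(rgb) <- "double"
  }
  if (anyNA(rgb)) stop("sRGB values must be finite", call. = FALSE)
  rgb
}

#' Classify sRGB coordinates into colour categories
#'
#' Assigns each sRGB triple to the category whose reference centroid is
#' nearest under Euclidean distance in the table's matching space (CIELAB by
#' default, chosen for perceptual uniformity; plain sRGB distance is
#' available via `loadIsccTable(colourSpace = "sRGB")`).  Ties break to the
#' lowest category index, so the mapping is deterministic and total over the
#' sRGB cube.
#'
#' @param rgb a length-3 vector or n x 3 matrix of channel values in
#'   \[0, 255\]
#' @param table an [IsccTable-class]
#' @return integer vector of category indices (one per input row); use
#'   [isccCategory()] to retrieve names and centroids.
#' @examples
#' tab <- loadIsccTable()
#' isccCategory(tab, classifySrgb(c(255, 255, 255), tab))
#' @export
classifySrgb <- function(rgb, table) {
  stopifnot(is(table, "IsccTable"))
  m <- .asRgbMatrix(rgb)
  if (any(m < 0 | m > 255))
    stop("sRGB channels must lie in [0, 255]", call. = FALSE)
  q <- .matchCoords(m, table@colourSpace)
  cen <- table@matchCoords
  ## squared distances via the expansion |q - c|^2 = |q|^2 - 2 q.c + |c|^2;
  ## nearest centroid, ties to the lowest index (max.col on the negated
  ## distance with ties.method = "first")
  cross <- q %*% t(cen)
  d2 <- outer(rowSums(q^2), rep(1, nrow(cen))) - 2 * cross +
    outer(rep(1, nrow(q)), rowSums(cen^2))
  ## guard tiny negative fp and exact ties: round at 1e-9 so equidistant
  ## centroids compare equal and the first (lowest index) wins
  idx <- max.col(-round(d2, 9), ties.method = "first")
  as.integer(table@categories$index[idx])
}
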