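## Image -> discrete colour histogram -> hue profile.
##
## Binning convention: each sRGB channel's range [0, 256) is split into
## binsPerChannel equal half-open intervals; a pixel's bin is the triple of
## region indices.  Bin centroids are the mean sRGB of the bin's own pixels
## (not the geometric bin centre), so they always lie inside the bin region.

## Read an image file into an H x W x C numeric array in [0, 1].
.readImageFile <- function(path) {
  if (!is.character(path) || length(path) != 1L || !file.exists(path))
    stop("cannot read image file '", path, "'", call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  img <- tryCatch({
    if (ext %in% c("jpg", "jpeg")) jpeg::readJPEG(path)
    else png::readPNG(path)
  }, error = function(e) {
    stop("failed to decode image '", path, "': ", conditionMessage(e),
         call. = FALSE)
  })
  img
}

## Coerce an image (file path, H x W x {1,3,4} array, or n x 3 pixel matrix,
## values in [0,1] or [0,255]) into an n x 3 matrix of integer sRGB values
## 0-255, dropping masked pixels.  Fully transparent pixels and pixels equal
## to the background sentinel colour are masked out.
.asPixels <- function(image, bgColour = NULL) {
  src <- if (is.character(image)) image else "<in-memory image>"
  if (is.character(image)) image <- .readImageFile(image)
  if (is.matrix(image) && ncol(image) == 3L) {
    px <- image
    alpha <- NULL
  } else if (is.array(image) && length(dim(image)) == 3L) {
    nc <- dim(image)[3]
    if (!nc %in% c(3L, 4L))
      stop("expected a 3- or 4-channel image: ", src, call. = FALSE)
    px <- cbind(as.vector(image[, , 1]), as.vector(image[, , 2]),
                as.vector(image[, , 3]))
    alpha <- if (nc == 4L) as.vector(image[, , 4]) else NULL
  } else if (is.matrix(image)) {
    # greyscale H x W
    px <- cbind(as.vector(image), as.vector(image), as.vector(image))
    alpha <- NULL
  } else {
    stop("unsupported image representation: ", src, call. = FALSE)
  }
  if (is.double(px) && max(px, na.rm = TRUE) <= 1 + 1e-12) px <- px * 255
  px <- .roundHalfUp(px)
  if (any(px < 0 | px > 255))
    stop("pixel values outside [0, 255]: ", src, call. = FALSE)
  keep <- rep(TRUE, nrow(px))
  if (!is.null(alpha)) keep <- keep & alpha > 1e-6
  if (!is.null(bgColour)) {
    bg <- .roundHalfUp(.asRgbMatrix(bgColour))
    keep <- keep & !(px[, 1] == bg[1] & px[, 2] == bg[2] & px[, 3] == bg[3])
  }
  px <- px[keep, , drop = FALSE]
  if (nrow(px) == 0L)
    stop("image is empty after masking: ", src, call. = FALSE)
  storage.mode(px) <- "integer"
  px
}

#' Bin an image into a discrete multidimensional colour histogram
#'
#' Treats each pixel as a three-dimensional coordinate in sRGB colour space
#' and partitions the cube into `binsPerChannel` equal-width regions per
#' channel (`binsPerChannel^3` possible bins; 3 regions give the 27-bin
#' histogram used for single-organism images, 4 regions the 64-bin histogram
#' used for reef seascapes).  Each occupied bin carries the proportion of
#' pixels it received and the mean sRGB colour of those pixels.
#'
#' @param image a file path (PNG or JPEG), an `H x W x 3` (or `x 4`, alpha
#'   honoured as a mask) array with values in \[0,1\] or \[0,255\], or an
#'   `n x 3` pixel matrix.
#' @param binsPerChannel integer >= 2; number of regions per channel.
#' @param bgColour optional sRGB triple; pixels exactly matching it are
#'   masked out (background sentinel for pre-cropped images).
#' @return a [ColourHistogram-class]; proportions sum to 1.
#' @examples
#' img <- array(runif(16 * 16 * 3), dim = c(16, 16, 3))
#' binImage(img, 3)
#' @export
binImage <- function(image, binsPerChannel = 3, bgColour = NULL) {
  binsPerChannel <- as.integer(binsPerChannel)
  if (is.na(binsPerChannel) || binsPerChannel < 2L)
    stop("binsPerChannel must be an integer >= 2", call. = FALSE)
  px <- .asPixels(image, bgColour = bgColour)
  k <- binsPerChannel
  w <- 256 / k
  idx <- pmin(floor(px / w) + 1L, k)   # region index per channel, 1..k
  key <- (idx[, 1] - 1L) * k * k + (idx[, 2] - 1L) * k + idx[, 3]
  ord <- order(key)
  keyS <- key[ord]
  pxS <- px[ord, , drop = FALSE]
  grp <- cumsum(!duplicated(keyS))
  counts <- tabulate(grp)
  sums <- rowsum(pxS, grp, reorder = FALSE)
  ukey <- keyS[!duplicated(keyS)] - 1L
  bins <- data.frame(
    binR = ukey %/% (k * k) + 1L,
    binG = (ukey %/% k) %% k + 1L,
    binB = ukey %% k + 1L,
    proportion = counts / nrow(px),
    r = sums[, 1] / counts,
    g = sums[, 2] / counts,
    b = sums[, 3] / counts)
  new("ColourHistogram", binsPerChannel = k, bins = bins,
      nPixels = nrow(px), renormalised = FALSE)
}

#' Exclude rare histogram bins
#'
#' Drops bins holding less than `threshold` of the pixels (default 1%, the
#' safeguard against small portions of discoloured pixels near crop edges)
#' and renormalises the remaining proportions to sum to 1.  At least one bin
#' always survives: if every bin falls below the threshold, the largest bin
#' is kept.
#'
#' @param hist a [ColourHistogram-class]
#' @param threshold minimum retained proportion, in \[0, 1\]
#' @return a [ColourHistogram-class] with `renormalised = TRUE`
#' @export
excludeRareBins <- function(hist, threshold = 0.01) {
  stopifnot(is(hist, "ColourHistogram"))
  if (!is.numeric(threshold) || threshold < 0 || threshold > 1)
    stop("threshold must lie in [0, 1]", call. = FALSE)
  keep <- hist@bins$proportion >= threshold
  if (!any(keep)) keep <- hist@bins$proportion == max(hist@bins$proportion)
  bins <- hist@bins[keep, , drop = FALSE]
  bins$proportion <- bins$proportion / sum(bins$proportion)
  rownames(bins) <- NULL
  new("ColourHistogram", binsPerChannel = hist@binsPerChannel, bins = bins,
      nPixels = hist@nPixels, renormalised = TRUE)
}

#' Convert a histogram into a hue profile
#'
#' Classifies each retained bin's pixel-mean sRGB centroid into a colour
#' category via [classifySrgb()] (hexadecimal codes are the intermediate
#' representation for bin centroids); the profile is the set of distinct
#' categories — the number of visually distinct colour stimuli in the image.
#'
#' @param hist a rare-bin-filtered [ColourHistogram-class]
#' @param table an [IsccTable-class]
#' @param speciesId identifier recorded on the profile
#' @return a [HueProfile-class]
#' @export
histogramToProfile <- function(hist, table, speciesId = "species") {
  stopifnot(is(hist, "ColourHistogram"), is(table, "IsccTable"))
  cen <- hexToSrgb(srgbToHex(as.matrix(hist@bins[, c("r", "g", "b")])))
  cats <- classifySrgb(cen, table)
  new("HueProfile", speciesId = as.character(speciesId),
      categories = sort(unique(cats)), nBinsRetained = nrow(hist@bins))
}

#' Quantify the hue profile of one image
#'
#' Composition of [binImage()], [excludeRareBins()] and
#' [histogramToProfile()]: bins the image's pixels into the 27-bin (default)
#' colour histogram, drops bins under the 1% rule, and classifies the
#' surviving bin centroids into colour categories.
#'
#' @inheritParams binImage
#' @param table an [IsccTable-class]
#' @param threshold rare-bin exclusion threshold (proportion of pixels)
#' @param speciesId identifier; defaults to the file name without extension
#' @param verbose emit a progress message with pixel/bin/category counts
#' @return a [HueProfile-class]
#' @export
quantifyImage <- function(image, table, binsPerChannel = 3, threshold = 0.01,
                          speciesId = NULL, bgColour = NULL, verbose = FALSE) {
  if (is.null(speciesId)) {
    speciesId <- if (is.character(image))
      tools::file_path_sans_ext(basename(image)) else "species"
  }
  h <- binImage(image, binsPerChannel = binsPerChannel, bgColour = bgColour)
  hk <- excludeRareBins(h, threshold = threshold)
  prof <- histogramToProfile(hk, table, speciesId = speciesId)
  if (isTRUE(verbose)) {
    message(sprintf("%s: %d pixels, %d/%d bins retained, %d categories",
                    speciesId, h@nPixels, nrow(hk@bins), nrow(h@bins),
                    length(prof@categories)))
  }
  prof
}

#' Write / read a batch of hue profiles as CSV
#'
#' The batch format has one row per species: `species_id`, semicolon-joined
#' `categories`, and `n_bins_retained`.  Reading returns a named list of
#' sorted integer category vectors; duplicated species ids are merged by set
#' union (several images of one species contribute the union of their
#' profiles).
#'
#' @param profiles a list of [HueProfile-class] objects
#' @param path CSV file path
#' @return `readProfiles` returns a named list of integer vectors.
#' @export
writeProfiles <- function(profiles, path) {
  stopifnot(all(vapply(profiles, is, TRUE, "HueProfile")))
  df <- data.frame(
    species_id = vapply(profiles, speciesId, ""),
    categories = vapply(profiles, function(p)
      paste(categoryIndices(p), collapse = ";"), ""),
    n_bins_retained = vapply(profiles, function(p) p@nBinsRetained, 1L))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeProfiles
#' @export
readProfiles <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE,
                 colClasses = c(categories = "character"))
  sets <- lapply(strsplit(df$categories, ";", fixed = TRUE),
                 function(x) sort(unique(as.integer(x))))
  out <- list()
  for (i in seq_len(nrow(df))) {
    id <- df$species_id[i]
    out[[id]] <- sort(unique(c(out[[id]], sets[[i]])))
  }
  out
}
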