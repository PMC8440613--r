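# Image -> colour histogram -> hue profile.

test_that("binning a uniform image gives a single full-mass bin", {
  img <- array(c(rep(0.4, 100), rep(0.7, 100), rep(0.1, 100)),
               dim = c(10, 10, 3))
  h <- binImage(img, 3)
  expect_equal(binCount(h), 1L)
  expect_equal(binProportions(h), 1)
  expect_equal(nPixels(h), 100L)
})

test_that("bin proportions match a naive per-pixel count and sum to one", {
  set.seed(11)
  for (k in c(3L, 4L)) {
    px <- matrix(sample(0:255, 3 * 64 * 64, replace = TRUE), ncol = 3)
    h <- binImage(px, k)
    expect_lte(binCount(h), k^3)
    expect_lt(abs(sum(binProportions(h)) - 1), 1e-9)
    want <- oracle_bin_proportions(px, k)
    got <- array(0, dim = c(k, k, k))
    got[as.matrix(h@bins[, c("binR", "binG", "binB")])] <- h@bins$proportion
    expect_identical(got, want + got * 0)  # exact equality of proportions
  }
})

test_that("a known two-patch composition yields 70/30 proportions", {
  img <- array(0, dim = c(20, 20, 3))
  img[1:14, , 1] <- 1          # 70% red rows
  img[15:20, , 2] <- 1         # 30% green rows
  h <- binImage(img, 3)
  expect_equal(sort(binProportions(h)), c(0.3, 0.7))
})

test_that("histograms are invariant to pixel order", {
  set.seed(5)
  px <- matrix(sample(0:255, 3 * 500, replace = TRUE), ncol = 3)
  h1 <- binImage(px, 3)
  h2 <- binImage(px[sample(nrow(px)), ], 3)
  expect_equal(h1@bins, h2@bins)
})

test_that("bin centroids are pixel means lying inside their bin region", {
  set.seed(6)
  px <- matrix(sample(0:255, 3 * 400, replace = TRUE), ncol = 3)
  h <- binImage(px, 3)
  w <- 256 / 3
  idx <- as.matrix(h@bins[, c("binR", "binG", "binB")])
  ctr <- as.matrix(h@bins[, c("r", "g", "b")])
  expect_true(all(ctr >= (idx - 1) * w & ctr < idx * w))
})

test_that("transparent and sentinel-background pixels are masked", {
  img <- array(0, dim = c(10, 10, 4))
  img[, , 1] <- 0.8
  img[, , 4] <- 1
  img[1:5, , 4] <- 0  # half the image fully transparent
  h <- binImage(img, 3)
  expect_equal(nPixels(h), 50L)
  img2 <- array(0, dim = c(10, 10, 3))
  img2[, , 2] <- 0.5
  img2[1:2, , ] <- 1  # white sentinel padding
  h2 <- binImage(img2, 3, bgColour = c(255, 255, 255))
  expect_equal(nPixels(h2), 80L)
  expect_error(binImage(array(c(0 * diag(10) + 1, 0 * diag(10) + 1,
                                0 * diag(10) + 1, 0 * diag(10)),
                              dim = c(10, 10, 4)), 3), "empty after masking")
})

test_that("rare-bin exclusion applies the threshold and renormalises", {
  mk <- function(props) {
    n <- length(props)
    new("ColourHistogram", binsPerChannel = 3L,
        bins = data.frame(binR = seq_len(n), binG = 1L, binB = 1L,
                          proportion = props,
                          r = (seq_len(n) - 1) * 256 / 3 + 1, g = 1, b = 1),
        nPixels = 1000L, renormalised = FALSE)
  }
  one <- excludeRareBins(mk(1))
  expect_equal(binProportions(one), 1)
  two <- excludeRareBins(mk(c(0.995, 0.005)))
  expect_equal(binCount(two), 1L)
  expect_equal(binProportions(two), 1)
  all3 <- excludeRareBins(mk(c(0.5, 0.3, 0.2)))
  expect_equal(binProportions(all3), c(0.5, 0.3, 0.2))
  # renormalisation after a real exclusion
  some <- excludeRareBins(mk(c(0.9, 0.092, 0.008)))
  expect_equal(sum(binProportions(some)), 1, tolerance = 1e-12)
  expect_equal(binProportions(some), c(0.9, 0.092) / 0.992)
  # at least one bin survives even when all are below threshold
  surv <- excludeRareBins(mk(c(0.4, 0.35, 0.25)), threshold = 0.5)
  expect_equal(binCount(surv), 1L)
})

test_that("raising the threshold never increases the retained bin count", {
  set.seed(12)
  px <- matrix(sample(0:255, 3 * 2000, replace = TRUE), ncol = 3)
  h <- binImage(px, 3)
  counts <- vapply(c(0, 0.005, 0.01, 0.03, 0.1, 0.5),
                   function(t) binCount(excludeRareBins(h, t)), 1L)
  expect_true(all(diff(counts) <= 0))
})

test_that("profiles have set semantics over bin categories", {
  h <- excludeRareBins(binImage(matrix(c(250, 10, 10,
                                         252, 12, 12,
                                         10, 250, 10), ncol = 3,
                                       byrow = TRUE), 3))
  p <- histogramToProfile(h, iscc_tab, "sp1")
  expect_s4_class(p, "HueProfile")
  expect_equal(speciesId(p), "sp1")
  # two near-identical reds share a bin or a category; union is a set
  expect_lte(length(categoryIndices(p)), p@nBinsRetained)
  # a single-bin histogram gives a single-category profile
  hh <- excludeRareBins(binImage(matrix(rep(c(30, 200, 40), 5),
                                        ncol = 3, byrow = TRUE), 3))
  expect_equal(length(categoryIndices(histogramToProfile(hh, iscc_tab))), 1L)
})

test_that("patches placed at distinct category centroids are recovered exactly", {
  # choose three self-classifying centroids in three different bins
  cen <- as.matrix(iscc_tab@categories[, c("r", "g", "b")])
  selfc <- which(classifySrgb(cen, iscc_tab) == 1:267)
  keys <- (pmin(floor(cen[, 1] / (256 / 3)) + 1, 3) - 1) * 9 +
    (pmin(floor(cen[, 2] / (256 / 3)) + 1, 3) - 1) * 3 +
    pmin(floor(cen[, 3] / (256 / 3)) + 1, 3)
  pick <- selfc[!duplicated(keys[selfc])][1:3]
  spec <- data.frame(cen[pick, ], proportion = c(0.5, 0.3, 0.2))
  names(spec)[1:3] <- c("r", "g", "b")
  path <- tempfile(fileext = ".png")
  makeCoralImage(spec, imageSize = 32, path = path, table = iscc_tab)
  prof <- quantifyImage(path, iscc_tab)
  expect_equal(categoryIndices(prof), sort(pick), ignore_attr = TRUE)
})

test_that("quantifying a file is deterministic and errors carry the path", {
  img <- array(c(rep(0.2, 64), rep(0.9, 64), rep(0.3, 64)), dim = c(8, 8, 3))
  path <- tempfile(fileext = ".png")
  png::writePNG(img, path)
  p1 <- quantifyImage(path, iscc_tab)
  p2 <- quantifyImage(path, iscc_tab)
  expect_equal(categoryIndices(p1), categoryIndices(p2))
  expect_equal(length(categoryIndices(p1)), 1L)  # single-colour fixture
  expect_equal(speciesId(p1), tools::file_path_sans_ext(basename(path)))
  bad <- file.path(tempdir(), "no_such_image.png")
  expect_error(quantifyImage(bad, iscc_tab), "no_such_image")
})

test_that("profile batches round-trip through CSV with union of duplicates", {
  p1 <- new("HueProfile", speciesId = "a", categories = c(2L, 5L),
            nBinsRetained = 3L)
  p2 <- new("HueProfile", speciesId = "b", categories = 7L,
            nBinsRetained = 1L)
  p3 <- new("HueProfile", speciesId = "a", categories = c(5L, 9L),
            nBinsRetained = 2L)
  f <- tempfile(fileext = ".csv")
  writeProfiles(list(p1, p2, p3), f)
  got <- readProfiles(f)
  expect_equal(got, list(a = c(2L, 5L, 9L), b = 7L))
})
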