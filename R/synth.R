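## Synthetic inputs with recorded ground truth for every pipeline stage:
## patch-composed species images with known colour proportions, an
## ecoregion table generated from the fitted model forms with known
## coefficients, and meta-analysis comparison records with known true
## standardized mean differences.
##
## Default scale mirrors the study conditions: 74 ecoregions split across
## four oceanic regions (31/16/13/14, the sizes implied by the per-region
## residual degrees of freedom), 784 coral species, 25 fish families, and a
## saturating-logistic hue curve plateauing near 180 unique colours with the
## plateau effectively reached around 300 coral species.

.reefFamilies <- c(
  "Pomacentridae", "Chaetodontidae", "Labridae", "Gobiidae", "Blenniidae",
  "Apogonidae", "Serranidae", "Lutjanidae", "Acanthuridae", "Scaridae",
  "Pomacanthidae", "Syngnathidae", "Carangidae", "Holocentridae",
  "Mullidae", "Balistidae", "Tetraodontidae", "Muraenidae", "Haemulidae",
  "Lethrinidae", "Siganidae", "Scorpaenidae", "Carcharhinidae",
  "Monacanthidae", "Nemipteridae")

#' Configuration for the synthetic-data generator
#'
#' `preset = "study"` (default) mirrors the study conditions (74 ecoregions,
#' 784 coral species, 25 families, hue plateau at 180 colours);
#' `preset = "smoke"` is a small configuration for fast end-to-end checks
#' (8 ecoregions, 20 species, 32 x 32 images).  Any field can be overridden.
#'
#' @param seed integer seed; all generator randomness flows from it
#' @param preset `"study"` or `"smoke"`
#' @param ... overrides for the fields below
#' @return a list of class `SynthConfig` with fields `seed`, `nEcoregions`,
#'   `nCoralSpecies`, `nFamilies`, `imageSize`, `regionSizes`, `coralRange`
#'   (per-region richness range), `logisticTruth` (A, k, x0), `extraCoefs`
#'   and `noiseSD` (non-family fish component), `familyCoefs` /
#'   `familyNoiseSD` (NULL to draw from the seed), and `metaTruth`.
#' @export
synthConfig <- function(seed = 1L, preset = c("study", "smoke"), ...) {
  preset <- match.arg(preset)
  cfg <- if (preset == "study") {
    list(
      seed = as.integer(seed),
      nEcoregions = 74L, nCoralSpecies = 784L, nFamilies = 25L,
      imageSize = 64L,
      regionSizes = c("Western Pacific" = 31L,
                      "Central and East Pacific" = 16L,
                      "Atlantic" = 13L,
                      "Northern Indian" = 14L),
      coralRange = list("Western Pacific" = c(200, 600),
                        "Central and East Pacific" = c(80, 350),
                        "Atlantic" = c(20, 120),
                        "Northern Indian" = c(60, 300)),
      logisticTruth = c(A = 180, k = 0.022, x0 = 110),
      extraCoefs = c(b0 = 20, b1 = 0.5, b2 = -3e-4, b3 = 1.0),
      noiseSD = 60,
      familyCoefs = NULL, familyNoiseSD = NULL,
      metaTruth = list(
        classD = c(richness = -0.8, abundance = -0.6, recruitment = -1.2),
        familyD = -0.5, tau2 = 0.05,
        kPerClass = c(richness = 20L, abundance = 45L, recruitment = 18L,
                      family_abundance = 50L),
        nStudies = 8L, nMetaFamilies = 6L))
  } else {
    list(
      seed = as.integer(seed),
      nEcoregions = 8L, nCoralSpecies = 20L, nFamilies = 3L,
      imageSize = 32L,
      regionSizes = c("Western Pacific" = 4L, "Atlantic" = 4L),
      coralRange = list("Western Pacific" = c(8, 20),
                        "Atlantic" = c(2, 10)),
      logisticTruth = c(A = 12, k = 0.3, x0 = 8),
      extraCoefs = c(b0 = 5, b1 = 2, b2 = -0.02, b3 = 3),
      noiseSD = 0,
      familyCoefs = NULL, familyNoiseSD = 0,
      metaTruth = list(
        classD = c(richness = -0.8, abundance = -0.6, recruitment = -1.2),
        familyD = -0.5, tau2 = 0.05,
        kPerClass = c(richness = 6L, abundance = 6L, recruitment = 6L,
                      family_abundance = 12L),
        nStudies = 4L, nMetaFamilies = 3L))
  }
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad))
    stop("unknown config field(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  cfg[names(over)] <- over
  if (sum(cfg$regionSizes) != cfg$nEcoregions)
    stop("regionSizes must sum to nEcoregions", call. = FALSE)
  if (any(cfg$logisticTruth[c("A", "k")] <= 0))
    stop("logistic truth A and k must be positive", call. = FALSE)
  if (!is.null(cfg$noiseSD) && cfg$noiseSD < 0)
    stop("noise SDs must be >= 0", call. = FALSE)
  class(cfg) <- "SynthConfig"
  cfg
}

#' Compose a synthetic patch image with known colour proportions
#'
#' Writes (or returns) an image made of solid colour patches in the given
#' proportions, allocated at pixel granularity so realized counts are within
#' one pixel of the target.  Patches below the 1% rare-bin threshold act as
#' contaminants that the quantification pipeline should drop.
#'
#' @param patchSpec data.frame with columns `r`, `g`, `b` (0-255) and
#'   `proportion` (summing to 1)
#' @param imageSize side length in pixels of the square image
#' @param path optional PNG path to write
#' @param table optional [IsccTable-class]; when given, the intended
#'   category of each patch colour is recorded in the ground truth
#' @return list with `image` (H x W x 3 array in \[0,1\]), `counts`
#'   (realized pixels per patch), `proportions` (realized), `categories`
#'   (intended category per patch, or NULL), and `path`
#' @export
makeCoralImage <- function(patchSpec, imageSize = 64L, path = NULL,
                           table = NULL) {
  if (!is.data.frame(patchSpec) ||
      !all(c("r", "g", "b", "proportion") %in% names(patchSpec)))
    stop("patchSpec must have columns r, g, b, proportion", call. = FALSE)
  if (abs(sum(patchSpec$proportion) - 1) > 1e-8)
    stop("patch proportions must sum to 1", call. = FALSE)
  h <- as.integer(imageSize)
  npix <- h * h
  counts <- diff(c(0L, round(cumsum(patchSpec$proportion) * npix)))
  cols <- as.matrix(patchSpec[, c("r", "g", "b")]) / 255
  px <- cols[rep(seq_len(nrow(patchSpec)), counts), , drop = FALSE]
  img <- array(c(px[, 1], px[, 2], px[, 3]), dim = c(h, h, 3))
  if (!is.null(path)) png::writePNG(img, target = path)
  cats <- if (!is.null(table))
    classifySrgb(as.matrix(patchSpec[, c("r", "g", "b")]), table) else NULL
  list(image = img, counts = counts, proportions = counts / npix,
       categories = cats, path = path)
}

## palette of categories whose centroid classifies back to itself; shuffled
.selfClassifyingPalette <- function(table) {
  cen <- as.matrix(table@categories[, c("r", "g", "b")])
  ok <- which(classifySrgb(cen, table) == table@categories$index)
  sample(ok)
}

.binKey <- function(rgb, k = 3L) {
  w <- 256 / k
  idx <- pmin(floor(rgb / w) + 1L, k)
  (idx[, 1] - 1L) * k * k + (idx[, 2] - 1L) * k + idx[, 3]
}

#' Generate a synthetic ecoregion dataset with recorded ground truth
#'
#' Builds a nested species-presence matrix along a coral-richness gradient,
#' assigns each species a small colour-category set so that ecoregion hue
#' diversity follows the configured saturating logistic of coral richness
#' exactly (up to integer rounding of the curve), and generates per-family
#' and total fish richness from the combined hue + coral-polynomial model
#' with known coefficients and Gaussian noise.  Total fish richness is the
#' family sum plus a non-negative non-family component, so the total always
#' dominates every family.  With all noise SDs zero the emitted values are
#' exact model values (no integer rounding), preserving noiseless
#' identifiability; with positive noise, richness values are rounded to
#' non-negative integers.
#'
#' @param cfg a [synthConfig()] object
#' @param outDir optional directory: writes `presence.csv`, `profiles.csv`,
#'   `fish_richness.csv`, `regions.csv` and `truth.json`
#' @param imageDir optional directory: writes one patch-composed PNG per
#'   species, patch colours at the centroids of the species' categories
#' @param table optional [IsccTable-class] (loaded if missing)
#' @return list with `presence`, `profiles` (named list of category sets),
#'   `fishTable`, `regions`, `ecoregionTable` (the assembled tidy table),
#'   `images` (paths or NULL), and `truth`
#' @export
makeEcoregionDataset <- function(cfg, outDir = NULL, imageDir = NULL,
                                 table = NULL) {
  stopifnot(inherits(cfg, "SynthConfig"))
  if (is.null(table)) table <- loadIsccTable()
  set.seed(cfg$seed)
  nE <- cfg$nEcoregions
  nS <- cfg$nCoralSpecies
  regions <- rep(names(cfg$regionSizes), cfg$regionSizes)
  ecoIds <- sprintf("ECO%03d", seq_len(nE))
  speciesIds <- sprintf("coral%04d", seq_len(nS))

  coral <- integer(nE)
  for (i in seq_len(nE)) {
    rng <- cfg$coralRange[[regions[i]]]
    coral[i] <- max(1L, min(nS, as.integer(round(runif(1, rng[1], rng[2])))))
  }

  ## cumulative unique-colour target along the species prevalence order
  lt <- cfg$logisticTruth
  logistic <- function(x) lt["A"] / (1 + exp(-lt["k"] * (x - lt["x0"])))
  target <- cummax(pmax(1L, as.integer(round(logistic(seq_len(nS))))))
  pal <- .selfClassifyingPalette(table)
  if (max(target) > length(pal))
    stop("infeasible config: ", max(target), " colours requested but only ",
         length(pal), " usable categories", call. = FALSE)

  cen <- as.matrix(table@categories[, c("r", "g", "b")])
  sets <- vector("list", nS)
  prevT <- 0L
  for (j in seq_len(nS)) {
    tj <- target[j]
    newIdx <- if (tj > prevT) seq(prevT + 1L, tj) else integer(0)
    ## per-image bin distinctness: swap clashing new colours with unused
    ## palette entries so the union invariant is preserved
    if (length(newIdx) > 1L) {
      tries <- 0L
      repeat {
        keys <- .binKey(cen[pal[newIdx], , drop = FALSE])
        dupAt <- which(duplicated(keys))
        if (!length(dupAt) || tj + 1L + tries > length(pal) || tries > 50L)
          break
        s <- tj + 1L + tries
        p <- newIdx[dupAt[1]]
        tmp <- pal[p]; pal[p] <- pal[s]; pal[s] <- tmp
        tries <- tries + 1L
      }
    }
    set <- pal[newIdx]
    if (!length(set)) set <- pal[sample.int(tj, 1L)]
    ## pad with reused colours (distinct bins) for set-size realism
    extra <- sample.int(tj, min(tj, 2L))
    for (e in pal[extra]) {
      cand <- c(set, e)
      if (!anyDuplicated(.binKey(cen[cand, , drop = FALSE])) &&
          !e %in% set && length(set) < 6L)
        set <- cand
    }
    sets[[j]] <- sort(set)
    prevT <- tj
  }
  names(sets) <- speciesIds

  presence <- matrix(0L, nS, nE, dimnames = list(speciesIds, ecoIds))
  for (i in seq_len(nE)) presence[seq_len(coral[i]), i] <- 1L
  hue <- target[coral]

  ## per-family coefficients (drawn once from the seed unless supplied)
  nF <- cfg$nFamilies
  famNames <- if (nF <= length(.reefFamilies)) .reefFamilies[seq_len(nF)]
    else c(.reefFamilies, sprintf("family%02d", seq_len(nF - length(.reefFamilies))))
  if (is.null(cfg$familyCoefs)) {
    b1 <- runif(nF, 0.1, 0.5)
    famCoefs <- cbind(b0 = runif(nF, 5, 25), b1 = b1, b2 = -b1 / 1600,
                      b3 = runif(nF, 0.1, 0.8))
  } else famCoefs <- cfg$familyCoefs
  rownames(famCoefs) <- famNames
  famSD <- cfg$familyNoiseSD
  if (is.null(famSD)) famSD <- runif(nF, 5, 25)
  famSD <- rep_len(famSD, nF)

  mk <- function(b, sdv) {
    mu <- b[1] + b[2] * coral + b[3] * coral^2 + b[4] * hue
    v <- mu + if (sdv > 0) rnorm(nE, 0, sdv) else 0
    if (sdv > 0) pmax(0, round(v)) else pmax(0, v)
  }
  famValues <- sapply(seq_len(nF), function(f) mk(famCoefs[f, ], famSD[f]))
  colnames(famValues) <- famNames
  extra <- mk(cfg$extraCoefs, cfg$noiseSD)
  total <- rowSums(famValues) + extra

  fishTable <- data.frame(ecoregion = ecoIds, total = total,
                          stringsAsFactors = FALSE)
  for (f in famNames) fishTable[[f]] <- famValues[, f]
  regionsDf <- data.frame(ecoregion = ecoIds, ocean_region = regions,
                          stringsAsFactors = FALSE)

  images <- NULL
  if (!is.null(imageDir)) {
    dir.create(imageDir, recursive = TRUE, showWarnings = FALSE)
    images <- character(nS)
    for (j in seq_len(nS)) {
      sp <- sets[[j]]
      spec <- data.frame(cen[sp, , drop = FALSE],
                         proportion = rep(1 / length(sp), length(sp)))
      names(spec)[1:3] <- c("r", "g", "b")
      images[j] <- file.path(imageDir, paste0(speciesIds[j], ".png"))
      makeCoralImage(spec, imageSize = cfg$imageSize, path = images[j])
    }
    names(images) <- speciesIds
  }

  truth <- list(
    logistic = as.list(lt),
    totalCoefs = as.list(setNames(colSums(famCoefs) + cfg$extraCoefs,
                                  c("b0", "b1", "b2", "b3"))),
    totalNoiseSD = sqrt(sum(famSD^2) + cfg$noiseSD^2),
    familyCoefs = famCoefs, familyNoiseSD = setNames(famSD, famNames),
    coralRichness = setNames(coral, ecoIds),
    hueDiversity = setNames(hue, ecoIds),
    cumulativeColours = target, palette = pal, speciesSets = sets)

  eco <- suppressMessages(
    assembleEcoregionTable(presence, sets, fishTable, regionsDf))

  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    write.csv(data.frame(species_id = speciesIds, presence,
                         check.names = FALSE),
              file.path(outDir, "presence.csv"), row.names = FALSE)
    profs <- lapply(speciesIds, function(s)
      new("HueProfile", speciesId = s, categories = sets[[s]],
          nBinsRetained = length(sets[[s]])))
    writeProfiles(profs, file.path(outDir, "profiles.csv"))
    write.csv(fishTable, file.path(outDir, "fish_richness.csv"),
              row.names = FALSE)
    write.csv(regionsDf, file.path(outDir, "regions.csv"), row.names = FALSE)
    jsonlite::write_json(
      truth[c("logistic", "totalCoefs", "totalNoiseSD")],
      file.path(outDir, "truth.json"), auto_unbox = TRUE, digits = NA)
  }

  list(presence = presence, profiles = sets, fishTable = fishTable,
       regions = regionsDf, ecoregionTable = eco, images = images,
       truth = truth)
}

#' Generate synthetic bleached-vs-healthy comparison records
#'
#' Emits group summaries (means, SDs, sizes) whose population standardized
#' mean difference per response class equals the configured truth, with
#' between-comparison heterogeneity injected at the configured tau^2.  The
#' shape mirrors a multi-study synthesis: comparisons are spread over
#' `nStudies` study ids, and `family_abundance` comparisons are spread over
#' fish families with family-level true effects drawn around the class mean.
#'
#' @param cfg a [synthConfig()] object (uses its `metaTruth` and `seed`)
#' @param outDir optional directory: writes `comparisons.csv`
#' @return list with `records` (one row per comparison) and `truth`
#'   (per-class and per-family true effects and tau^2)
#' @export
makeMetaDataset <- function(cfg, outDir = NULL) {
  stopifnot(inherits(cfg, "SynthConfig"))
  mt <- cfg$metaTruth
  set.seed(cfg$seed + 1L)
  studies <- sprintf("study%02d", seq_len(mt$nStudies))
  metaFams <- .reefFamilies[seq_len(mt$nMetaFamilies)]
  famD <- setNames(mt$familyD + rnorm(mt$nMetaFamilies, 0, 0.3), metaFams)
  rows <- list()
  for (cls in names(mt$kPerClass)) {
    k <- mt$kPerClass[[cls]]
    for (i in seq_len(k)) {
      fam <- NA_character_
      if (cls == "family_abundance") {
        fam <- metaFams[((i - 1) %% length(metaFams)) + 1]
        dTrue <- famD[fam]
      } else dTrue <- mt$classD[[cls]]
      di <- dTrue + rnorm(1, 0, sqrt(mt$tau2))
      sdv <- runif(1, 0.8, 2.5)
      mc <- runif(1, 5, 50)
      rows[[length(rows) + 1L]] <- data.frame(
        study_id = studies[((length(rows)) %% mt$nStudies) + 1],
        response_class = cls, family = fam,
        mean_treat = mc + di * sdv, sd_treat = sdv,
        n_treat = sample(5:30, 1),
        mean_ctrl = mc, sd_ctrl = sdv, n_ctrl = sample(5:30, 1),
        stringsAsFactors = FALSE)
    }
  }
  records <- do.call(rbind, rows)
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    write.csv(records, file.path(outDir, "comparisons.csv"),
              row.names = FALSE)
  }
  list(records = records,
       truth = list(classD = mt$classD, familyD = famD, tau2 = mt$tau2))
}

#' Synthetic reef signature panel with a bleached reef
#'
#' Builds colour signatures for a panel of colourful reefs (mass spread over
#' saturated, hue-diverse bins) plus one bleached reef whose mass is
#' concentrated in pale, achromatic bins — the colour-homogenized seascape
#' that bleaching produces.  Used to exercise the distance-matrix stage
#' without photographic inputs.
#'
#' @param nReefs number of healthy, colourful reefs
#' @param seed integer seed
#' @return named list of [ColourSignature-class] objects; the bleached
#'   signature is named `"bleached"`
#' @export
makeReefPanel <- function(nReefs = 5L, seed = 1L) {
  set.seed(seed)
  out <- list()
  for (i in seq_len(nReefs)) {
    nb <- sample(6:12, 1)
    ## saturated colours: channels spread over the full cube
    cols <- matrix(runif(nb * 3, 0, 255), ncol = 3)
    ## push away from the achromatic axis
    cols <- t(apply(cols, 1, function(x) {
      x[which.max(x)] <- max(x[which.max(x)], 200)
      x[which.min(x)] <- min(x[which.min(x)], 60)
      x
    }))
    w <- runif(nb); w <- w / sum(w)
    id <- sprintf("reef%02d", i)
    out[[id]] <- new("ColourSignature", reefId = id,
                     bins = data.frame(r = cols[, 1], g = cols[, 2],
                                       b = cols[, 3], weight = w))
  }
  ## bleached: pale near-white/grey bins only
  nb <- 4L
  base <- runif(nb, 205, 250)
  jit <- matrix(runif(nb * 3, -6, 6), ncol = 3)
  cols <- pmin(pmax(base + jit, 0), 255)
  w <- runif(nb); w <- w / sum(w)
  out[["bleached"]] <- new("ColourSignature", reefId = "bleached",
                           bins = data.frame(r = cols[, 1], g = cols[, 2],
                                             b = cols[, 3], weight = w))
  out
}
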