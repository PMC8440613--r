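## End-to-end wiring: simulate -> extract -> aggregate -> fit -> reefdist ->
## meta, with one root seed, input validation up front, and a reproducible
## run manifest.  The exported functions are the primary interface; a thin
## command-line wrapper lives at inst/scripts/coralhue.R.

.stageNames <- c("simulate", "extract", "aggregate", "fit", "reefdist", "meta")

#' Run the analysis pipeline
#'
#' Executes the requested stages in order inside `outDir`.  `simulate`
#' writes synthetic inputs (presence matrix, species images, fish and
#' region tables, comparison records) with ground truth; `extract`
#' quantifies the species images into hue profiles; `aggregate` assembles
#' the ecoregion table; `fit` runs the global, per-family and per-region
#' model suite with AIC selection; `reefdist` builds the reef colour
#' distance matrix; `meta` computes and pools the Hedges' d effect sizes.
#' All randomness flows from `seed`; identical configuration and seed give
#' identical outputs and manifest.
#'
#' @param outDir output directory (created if absent)
#' @param seed integer root seed
#' @param preset synthetic scale, `"smoke"` (default) or `"study"`
#' @param stages subset of
#'   `c("simulate", "extract", "aggregate", "fit", "reefdist", "meta")`;
#'   stages consuming files require their producers to have run (here or in
#'   a previous call on the same directory)
#' @param bins,threshold histogram regions per channel and rare-bin
#'   threshold for the extract stage
#' @param verbose emit per-stage messages
#' @return invisibly, a list with the run manifest and per-stage results
#' @export
runPipeline <- function(outDir, seed = 1L, preset = c("smoke", "study"),
                        stages = .stageNames, bins = 3L, threshold = 0.01,
                        verbose = TRUE) {
  preset <- match.arg(preset)
  bad <- setdiff(stages, .stageNames)
  if (length(bad))
    stop("unknown stage(s): ", paste(bad, collapse = ", "), call. = FALSE)
  stages <- .stageNames[.stageNames %in% stages]
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (isTRUE(verbose)) message(...)

  ## validate inputs needed by the requested stages before any work
  needs <- list(
    extract = file.path(outDir, "images"),
    aggregate = file.path(outDir, c("presence.csv", "profiles.csv",
                                    "fish_richness.csv", "regions.csv")),
    fit = file.path(outDir, "ecoregion_table.csv"),
    meta = file.path(outDir, "comparisons.csv"))
  for (st in stages) {
    if (is.null(needs[[st]])) next
    produced <- stages[seq_len(match(st, stages) - 1)]
    if ("simulate" %in% produced &&
        st %in% c("extract", "aggregate", "meta")) next
    if ("aggregate" %in% produced && st == "fit") next
    missing <- needs[[st]][!file.exists(needs[[st]])]
    if (length(missing))
      stop("stage '", st, "' is missing input(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
  }

  tab <- loadIsccTable()
  cfg <- synthConfig(seed = seed, preset = preset)
  results <- list()

  if ("simulate" %in% stages) {
    say("stage simulate: generating synthetic inputs")
    results$simulate <- makeEcoregionDataset(
      cfg, outDir = outDir, imageDir = file.path(outDir, "images"),
      table = tab)
    makeMetaDataset(cfg, outDir = outDir)
  }

  if ("extract" %in% stages) {
    files <- sort(list.files(file.path(outDir, "images"),
                             pattern = "\\.(png|jpe?g)$", full.names = TRUE))
    if (!length(files))
      stop("stage 'extract': no images found under ",
           file.path(outDir, "images"), call. = FALSE)
    say("stage extract: quantifying ", length(files), " images")
    profiles <- lapply(files, quantifyImage, table = tab,
                       binsPerChannel = bins, threshold = threshold)
    writeProfiles(profiles, file.path(outDir, "profiles.csv"))
    results$extract <- profiles
  }

  if ("aggregate" %in% stages) {
    say("stage aggregate: assembling ecoregion table")
    pres <- read.csv(file.path(outDir, "presence.csv"), check.names = FALSE)
    presence <- as.matrix(pres[, -1, drop = FALSE])
    rownames(presence) <- pres[[1]]
    eco <- assembleEcoregionTable(
      presence,
      readProfiles(file.path(outDir, "profiles.csv")),
      read.csv(file.path(outDir, "fish_richness.csv"),
               check.names = FALSE),
      read.csv(file.path(outDir, "regions.csv")))
    write.csv(eco, file.path(outDir, "ecoregion_table.csv"),
              row.names = FALSE)
    results$aggregate <- eco
  }

  if ("fit" %in% stages) {
    say("stage fit: regression suite and AIC selection")
    eco <- read.csv(file.path(outDir, "ecoregion_table.csv"),
                    check.names = FALSE)
    global <- fitGlobalModels(eco)
    fams <- sub("^fish_", "",
                grep("^fish_", names(eco), value = TRUE))
    fams <- setdiff(fams, "total")
    famFits <- fitFamilyModels(eco, fams)
    regFits <- suppressWarnings(fitRegionalModels(eco))
    write.csv(famFits$ranking, file.path(outDir, "family_ranking.csv"),
              row.names = FALSE)
    aicTab <- data.frame(model = names(deltaAic(global$aic)),
                         aic = vapply(global$aic@fits, aicValue, 1),
                         delta_aic = unname(deltaAic(global$aic)))
    write.csv(aicTab, file.path(outDir, "aic_table.csv"), row.names = FALSE)
    jsonlite::write_json(
      lapply(global[c("linear", "saturating", "quadratic", "combined")],
             function(f) list(
               label = modelLabel(f), adjusted_r2 = adjustedR2(f),
               f_statistic = f@fStatistic, df = c(f@dfModel, f@dfResidual),
               p_value = f@pValue, aic = aicValue(f), n = f@n,
               coefficients = as.list(coef(f)))),
      file.path(outDir, "model_fits.json"), auto_unbox = TRUE, digits = NA)
    results$fit <- list(global = global, families = famFits,
                        regions = regFits)
  }

  if ("reefdist" %in% stages) {
    say("stage reefdist: reef colour distance matrix")
    panel <- makeReefPanel(nReefs = 5L, seed = seed)
    dm <- reefDistanceMatrix(panel)
    writeDistanceMatrix(dm, file.path(outDir, "reef_distance.csv"),
                        orderFile = file.path(outDir, "reef_order.txt"))
    results$reefdist <- dm
  }

  if ("meta" %in% stages) {
    say("stage meta: effect sizes and pooling")
    records <- read.csv(file.path(outDir, "comparisons.csv"),
                        stringsAsFactors = FALSE)
    eff <- hedgesD(records, onDegenerate = "drop")
    write.csv(eff, file.path(outDir, "effects.csv"), row.names = FALSE)
    pooled <- summarizeByClass(records)
    write.csv(pooled, file.path(outDir, "pooled.csv"), row.names = FALSE)
    results$meta <- pooled
  }

  manifest <- list(
    package = "coralhue",
    version = as.character(utils::packageVersion("coralhue")),
    seed = as.integer(seed), preset = preset, stages = stages,
    bins = as.integer(bins), threshold = threshold,
    input_digests = as.list(.digestInputs(outDir)))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(c(list(manifest = manifest), results))
}

.digestInputs <- function(outDir) {
  files <- c("presence.csv", "profiles.csv", "fish_richness.csv",
             "regions.csv", "comparisons.csv", "ecoregion_table.csv")
  paths <- file.path(outDir, files)
  ok <- file.exists(paths)
  if (!any(ok)) return(setNames(list(), character()))
  md5 <- tools::md5sum(paths[ok])
  setNames(as.list(unname(md5)), files[ok])
}
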