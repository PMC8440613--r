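## Ecoregion-level assembly: coral richness from the species-presence matrix,
## hue diversity as the union of per-species colour categories, fish richness
## joined from the supplied tables.

.checkPresence <- function(presence) {
  if (!is.matrix(presence) || is.null(rownames(presence)) ||
      is.null(colnames(presence)))
    stop("presence must be a species x ecoregion matrix with dimnames",
         call. = FALSE)
  if (!all(presence %in% c(0, 1)))
    stop("presence entries must be 0/1", call. = FALSE)
  invisible(presence)
}

#' Coral species richness of an ecoregion
#'
#' @param presence binary species x ecoregion matrix with species ids as row
#'   names and ecoregion ids as column names
#' @param ecoregionId one or more ecoregion ids; defaults to all
#' @return named integer vector of species counts
#' @export
coralRichness <- function(presence, ecoregionId = colnames(presence)) {
  .checkPresence(presence)
  miss <- setdiff(ecoregionId, colnames(presence))
  if (length(miss))
    stop("unknown ecoregion id(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  counts <- colSums(presence[, ecoregionId, drop = FALSE])
  setNames(as.integer(counts), ecoregionId)
}

.profileSet <- function(p) {
  if (is(p, "HueProfile")) categoryIndices(p) else sort(unique(as.integer(p)))
}

#' Hue diversity of an ecoregion
#'
#' The number of unique colour categories present in an ecoregion given its
#' coral composition: the size of the union of the hue-profile category sets
#' over the species present.
#'
#' @inheritParams coralRichness
#' @param profiles named list mapping species id to a [HueProfile-class] or
#'   an integer vector of category indices
#' @return named integer vector of unique-colour counts
#' @export
hueDiversity <- function(presence, profiles, ecoregionId = colnames(presence)) {
  .checkPresence(presence)
  miss <- setdiff(ecoregionId, colnames(presence))
  if (length(miss))
    stop("unknown ecoregion id(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  out <- integer(length(ecoregionId))
  names(out) <- ecoregionId
  for (e in ecoregionId) {
    sp <- rownames(presence)[presence[, e] == 1]
    lacking <- sp[!sp %in% names(profiles)]
    if (length(lacking))
      stop("species present in '", e, "' but lacking a hue profile: ",
           paste(lacking, collapse = ", "), call. = FALSE)
    cats <- unique(unlist(lapply(profiles[sp], .profileSet), use.names = FALSE))
    out[e] <- length(cats)
  }
  out
}

#' Assemble the per-ecoregion analysis table
#'
#' Joins coral richness (from the presence matrix), hue diversity (union of
#' per-species profiles), ocean-region labels, and total plus per-family fish
#' richness into one tidy row per ecoregion.  Family columns in the output
#' are prefixed `fish_`; `fish_total` is the all-species richness (species in
#' no listed family count towards the total only).
#'
#' @inheritParams hueDiversity
#' @param fishTable data.frame with column `ecoregion`, a `total` column, and
#'   one column per fish family (counts)
#' @param regions data.frame with columns `ecoregion` and `ocean_region`
#' @return data.frame with columns `ecoregion`, `ocean_region`,
#'   `coral_richness`, `hue_diversity`, `fish_total`, and `fish_<family>`...
#' @export
assembleEcoregionTable <- function(presence, profiles, fishTable, regions) {
  .checkPresence(presence)
  eco <- colnames(presence)
  if (!all(c("ecoregion", "total") %in% names(fishTable)))
    stop("fishTable must have 'ecoregion' and 'total' columns", call. = FALSE)
  if (!all(c("ecoregion", "ocean_region") %in% names(regions)))
    stop("regions must have 'ecoregion' and 'ocean_region' columns",
         call. = FALSE)
  missFish <- setdiff(eco, fishTable$ecoregion)
  missReg <- setdiff(eco, regions$ecoregion)
  if (length(missFish) || length(missReg))
    stop("ecoregion id mismatch; missing from fish table: ",
         paste(missFish, collapse = ", "), "; missing from regions: ",
         paste(missReg, collapse = ", "), call. = FALSE)
  fam <- setdiff(names(fishTable), c("ecoregion", "total"))
  fi <- fishTable[match(eco, fishTable$ecoregion), , drop = FALSE]
  bad <- eco[!complete.cases(fi[, c("total", fam), drop = FALSE])]
  if (length(bad))
    stop("fish richness missing for ecoregion(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  if (any(fi$total < 0) || (length(fam) && any(fi[, fam] < 0)))
    stop("fish richness counts must be >= 0", call. = FALSE)
  if (length(fam) && any(fi$total < do.call(pmax, fi[, fam, drop = FALSE])))
    stop("fish total richness below a family richness for ecoregion(s): ",
         paste(eco[fi$total < do.call(pmax, fi[, fam, drop = FALSE])],
               collapse = ", "), call. = FALSE)
  out <- data.frame(
    ecoregion = eco,
    ocean_region = regions$ocean_region[match(eco, regions$ecoregion)],
    coral_richness = as.integer(coralRichness(presence, eco)),
    hue_diversity = as.integer(hueDiversity(presence, profiles, eco)),
    fish_total = as.numeric(fi$total),
    stringsAsFactors = FALSE)
  for (f in fam) out[[paste0("fish_", f)]] <- as.numeric(fi[[f]])
  message(sprintf("assembled %d ecoregions, %d coral species, %d families",
                  length(eco), nrow(presence), length(fam)))
  rownames(out) <- NULL
  out
}
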