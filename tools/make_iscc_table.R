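# Regenerates inst/extdata/iscc_nbs_level3_synthetic.csv.
#
# The shipped table is a SYNTHETIC reconstruction of the Level-3 ISCC-NBS
# colour system: it reproduces the system's structure (267 named categories,
# 262 chromatic built from modifier x hue-family naming conventions plus 5
# achromatic, each with an sRGB reference centroid), but the centroids are
# generated from an LCh(ab) parameterisation rather than transcribed from the
# published Munsell-based centroid listing.  Names follow the ISCC-NBS naming
# pattern and are unique; they are not guaranteed to coincide with the
# official list entry by entry.
#
# Run from the repository root:  Rscript tools/make_iscc_table.R

families <- data.frame(
  family = c("pink", "red", "yellowish pink", "reddish orange",
             "reddish brown", "orange", "brown", "orange yellow",
             "yellowish brown", "yellow", "olive brown", "greenish yellow",
             "olive", "yellow green", "olive green", "yellowish green",
             "green", "bluish green", "greenish blue", "blue",
             "purplish blue", "violet", "purple", "reddish purple",
             "purplish pink", "purplish red"),
  hue    = c(15, 30, 40, 45, 40, 65, 60, 80, 75, 95, 90, 105,
             105, 120, 125, 140, 160, 185, 220, 270, 290, 305,
             320, 340, 355, 5),
  cscale = c(0.60, 1.00, 0.60, 1.00, 0.50, 1.00, 0.50, 1.00, 0.50, 1.00,
             0.45, 0.95, 0.45, 0.90, 0.40, 0.85, 0.80, 0.70, 0.70, 0.85,
             0.80, 0.75, 0.80, 0.80, 0.60, 0.90),
  stringsAsFactors = FALSE)

modifiers <- data.frame(
  modifier = c("vivid", "brilliant", "strong", "deep", "light", "moderate",
               "dark", "pale", "grayish", "blackish"),
  L = c(55, 72, 50, 35, 72, 50, 32, 78, 52, 20),
  C = c(75, 55, 50, 50, 30, 28, 24, 12, 10, 8),
  stringsAsFactors = FALSE)

# two extra entries bring the chromatic count to 262 (26 x 10 + 2)
extras <- data.frame(
  name = c("very deep red", "very dark green"),
  hue = c(30, 160), L = c(25, 18), C = c(40, 16),
  stringsAsFactors = FALSE)

lab_to_srgb <- function(L, a, b) {
  srgb <- grDevices::convertColor(cbind(L, a, b), from = "Lab", to = "sRGB",
                                  clip = NA)
  srgb  # NA where out of gamut
}

# largest chroma <= C0 whose LCh colour lies inside the sRGB gamut
gamut_chroma <- function(L, C0, hue_deg) {
  h <- hue_deg * pi / 180
  ok <- function(C) {
    s <- lab_to_srgb(L, C * cos(h), C * sin(h))
    !anyNA(s)
  }
  if (ok(C0)) return(C0)
  lo <- 0; hi <- C0
  for (i in 1:40) {
    mid <- (lo + hi) / 2
    if (ok(mid)) lo <- mid else hi <- mid
  }
  lo * 0.999
}

rows <- list()
k <- 0L
for (i in seq_len(nrow(families))) {
  for (j in seq_len(nrow(modifiers))) {
    k <- k + 1L
    C <- modifiers$C[j] * families$cscale[i]
    C <- gamut_chroma(modifiers$L[j], C, families$hue[i])
    h <- families$hue[i] * pi / 180
    s <- lab_to_srgb(modifiers$L[j], C * cos(h), C * sin(h))
    rows[[k]] <- data.frame(
      name = paste(modifiers$modifier[j], families$family[i]),
      r = round(255 * s[1]), g = round(255 * s[2]), b = round(255 * s[3]),
      achromatic = 0L)
  }
}
for (e in seq_len(nrow(extras))) {
  k <- k + 1L
  C <- gamut_chroma(extras$L[e], extras$C[e], extras$hue[e])
  h <- extras$hue[e] * pi / 180
  s <- lab_to_srgb(extras$L[e], C * cos(h), C * sin(h))
  rows[[k]] <- data.frame(name = extras$name[e],
                          r = round(255 * s[1]), g = round(255 * s[2]),
                          b = round(255 * s[3]), achromatic = 0L)
}

achrom <- data.frame(
  name = c("white", "light gray", "medium gray", "dark gray", "black"),
  L = c(95, 80, 55, 33, 8))
for (a in seq_len(nrow(achrom))) {
  k <- k + 1L
  s <- lab_to_srgb(achrom$L[a], 0, 0)
  rows[[k]] <- data.frame(name = achrom$name[a],
                          r = round(255 * s[1]), g = round(255 * s[2]),
                          b = round(255 * s[3]), achromatic = 1L)
}

tab <- do.call(rbind, rows)
tab <- cbind(index = seq_len(nrow(tab)), tab)

stopifnot(nrow(tab) == 267,
          !anyDuplicated(tab$name),
          all(tab$r >= 0 & tab$r <= 255),
          all(tab$g >= 0 & tab$g <= 255),
          all(tab$b >= 0 & tab$b <= 255))
dup <- duplicated(tab[, c("r", "g", "b")])
if (any(dup)) {
  # nudge exact sRGB collisions apart (rare; gamut clipping can coincide)
  for (i in which(dup)) {
    repeat {
      tab$b[i] <- min(255, tab$b[i] + 1)
      if (!any(tab$r[-i] == tab$r[i] & tab$g[-i] == tab$g[i] &
               tab$b[-i] == tab$b[i])) break
    }
  }
}
stopifnot(!anyDuplicated(tab[, c("r", "g", "b")]))

dir.create("inst/extdata", recursive = TRUE, showWarnings = FALSE)
write.csv(tab, "inst/extdata/iscc_nbs_level3_synthetic.csv",
          row.names = FALSE, quote = FALSE)
cat("wrote", nrow(tab), "categories\n")
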