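## Regression suite: fish richness ~ coral richness and hue diversity.
##
## Polynomial terms are fitted on an orthogonal basis (stats::poly) for
## conditioning — coral richness reaches several hundred species, so raw
## quadratic columns are poorly scaled — but estimates and standard errors
## are reported on the raw basis via the exact linear map between the bases.
## The AIC convention is n*log(RSS/n) + 2k with k counting all mean
## parameters, the intercept, and the error variance, so deltas are
## comparable across implementations regardless of likelihood constants.

.specAic <- function(rss, n, nMeanParams) {
  n * log(max(rss, 1e-300) / n) + 2 * (nMeanParams + 1)
}

.checkXY <- function(..., minN) {
  vars <- list(...)
  lens <- vapply(vars, length, 1L)
  if (length(unique(lens)) != 1L)
    stop("predictor/response vectors must have equal length", call. = FALSE)
  if (lens[1] < minN)
    stop("need at least ", minN, " observations", call. = FALSE)
  if (!all(vapply(vars, function(v) all(is.finite(v)), TRUE)))
    stop("all values must be finite", call. = FALSE)
  invisible(lens[1])
}

## Build a ModelFit from an lm fitted on design Z, reporting on raw basis X
## (first column the intercept).  beta_raw = A gamma with A = (X'X)^-1 X'Z,
## exact because Z and X span the same column space.
.lmModelFit <- function(fit, X, label, response, predictors, notes = character()) {
  y <- fit$model[[1L]]
  n <- length(y)
  p <- length(coef(fit))
  rss <- sum(resid(fit)^2)
  tss <- sum((y - mean(y))^2)
  df1 <- p - 1L
  df2 <- n - p
  r2 <- if (tss > 0) 1 - rss / tss else NA_real_
  adj <- if (tss > 0) 1 - (1 - r2) * (n - 1) / (n - p) else NA_real_
  f <- if (rss > 0) ((tss - rss) / df1) / (rss / df2) else Inf
  pv <- if (is.finite(f)) pf(f, df1, df2, lower.tail = FALSE) else 0
  ## QR with column equilibration, not normal equations: raw polynomial
  ## columns span several orders of magnitude at richness scales
  sc <- sqrt(colSums(X^2))
  A <- qr.solve(sweep(X, 2, sc, "/"), model.matrix(fit), tol = 1e-12) / sc
  beta <- drop(A %*% coef(fit))
  V <- A %*% suppressWarnings(vcov(fit)) %*% t(A)  # vcov warns on perfect fits
  se <- sqrt(pmax(diag(V), 0))
  names(beta) <- names(se) <- colnames(X)
  new("ModelFit", modelLabel = label, response = response,
      predictors = predictors, coefficients = beta, coefficientSe = se,
      adjustedR2 = adj, fStatistic = f, dfModel = as.integer(df1),
      dfResidual = as.integer(df2), pValue = pv,
      aic = .specAic(rss, n, p), n = as.integer(n), rss = rss,
      notes = notes, fit = fit)
}

#' Simple linear regression of fish richness on coral richness
#'
#' Ordinary least squares with intercept, reporting adjusted R^2,
#' F(1, n - 2), and AIC under the package convention.
#'
#' @param x,y numeric vectors (predictor, response), equal length >= 3
#' @param label model label recorded on the fit
#' @param response,predictor names recorded on the fit
#' @return a [ModelFit-class]
#' @examples
#' fitLinear(1:10, 2 + 3 * (1:10))
#' @export
fitLinear <- function(x, y, label = "linear", response = "fish_richness",
                      predictor = "coral_richness") {
  .checkXY(x, y, minN = 3L)
  if (sd(x) == 0)
    stop("singular design: predictor '", predictor, "' is constant",
         call. = FALSE)
  fit <- lm(y ~ x)
  X <- cbind("(Intercept)" = 1, x)
  colnames(X)[2] <- predictor
  .lmModelFit(fit, X, label, response, predictor)
}

#' Quadratic polynomial regression
#'
#' OLS of `y` on `x` and `x^2` (fitted on an orthogonal polynomial basis,
#' reported on the raw basis), F(2, n - 3).
#'
#' @inheritParams fitLinear
#' @return a [ModelFit-class]
#' @export
fitQuadratic <- function(x, y, label = "quadratic",
                         response = "fish_richness",
                         predictor = "hue_diversity") {
  .checkXY(x, y, minN = 4L)
  if (length(unique(x)) < 3L)
    stop("singular design: need >= 3 distinct predictor values",
         call. = FALSE)
  fit <- lm(y ~ poly(x, 2))
  X <- cbind(1, x, x^2)
  colnames(X) <- c("(Intercept)", predictor, paste0(predictor, "^2"))
  .lmModelFit(fit, X, label, response,
              c(predictor, paste0(predictor, "^2")))
}

#' Multiple regression: hue diversity plus coral richness as a quadratic
#'
#' The combined model: OLS of fish richness on hue diversity and coral
#' richness as a second-order polynomial (orthogonal basis internally, raw
#' basis reported), F(3, n - 4).
#'
#' @param coral,hue,fish numeric vectors of equal length >= 5
#' @inheritParams fitLinear
#' @return a [ModelFit-class] with coefficients `(Intercept)`,
#'   `hue_diversity`, `coral_richness`, `coral_richness^2`
#' @export
fitPoly2PlusHue <- function(coral, hue, fish, label = "combined",
                            response = "fish_richness") {
  .checkXY(coral, hue, fish, minN = 5L)
  X <- cbind(1, hue, coral, coral^2)
  colnames(X) <- c("(Intercept)", "hue_diversity", "coral_richness",
                   "coral_richness^2")
  if (qr(X)$rank < 4L)
    stop("singular design: hue and coral polynomial terms are collinear",
         call. = FALSE)
  fit <- lm(fish ~ hue + poly(coral, 2))
  .lmModelFit(fit, X, label, response,
              c("hue_diversity", "coral_richness", "coral_richness^2"))
}

#' Saturating logistic fit of hue diversity on coral richness
#'
#' Reef colour saturates: hue diversity plateaus as coral richness grows.
#' Fits `hue = A / (1 + exp(-k (coral - x0)))` by nonlinear least squares
#' with a multi-start grid over asymptote, midpoint and rate for robustness;
#' the asymptote `A` is the plateau in unique-colour units.
#'
#' @param coral,hue numeric vectors, equal length >= 4, `hue >= 0`
#' @inheritParams fitLinear
#' @return a [ModelFit-class] with coefficients `A`, `k`, `x0`; adjusted R^2
#'   is residual-based (1 - (RSS/(n-3)) / (TSS/(n-1))).
#' @export
fitSaturating <- function(coral, hue, label = "saturating_logistic",
                          response = "hue_diversity") {
  n <- .checkXY(coral, hue, minN = 4L)
  if (any(hue < 0)) stop("hue diversity must be >= 0", call. = FALSE)
  rng <- diff(range(coral))
  if (rng == 0) stop("singular design: coral richness is constant",
                     call. = FALSE)
  starts <- expand.grid(A = max(hue) * c(1, 1.15, 1.3),
                        k = c(1 / rng, 4 / rng, 12 / rng),
                        x0 = unname(quantile(coral, c(0.25, 0.5, 0.75))))
  best <- NULL
  diag_msgs <- character()
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      minpack.lm::nlsLM(hue ~ A / (1 + exp(-k * (coral - x0))),
                        start = as.list(starts[i, ]),
                        control = minpack.lm::nls.lm.control(
                          maxiter = 500, ftol = 1e-13, ptol = 1e-13)),
      error = function(e) e)
    if (inherits(fit, "error")) {
      diag_msgs <- c(diag_msgs, conditionMessage(fit))
      next
    }
    rss <- sum(resid(fit)^2)
    if (is.null(best) || rss < best$rss - 1e-12)
      best <- list(fit = fit, rss = rss)
  }
  if (is.null(best))
    stop("saturating logistic fit failed to converge from any start; ",
         "diagnostics: ", paste(unique(diag_msgs), collapse = " | "),
         call. = FALSE)
  fit <- best$fit
  rss <- best$rss
  tss <- sum((hue - mean(hue))^2)
  p <- 3L
  adj <- 1 - (rss / (n - p)) / (tss / (n - 1))
  f <- if (rss > 0) ((tss - rss) / (p - 1)) / (rss / (n - p)) else Inf
  pv <- if (is.finite(f)) pf(f, p - 1, n - p, lower.tail = FALSE) else 0
  est <- coef(fit)
  se <- tryCatch(sqrt(pmax(diag(vcov(fit)), 0)),
                 error = function(e) rep(NA_real_, p))
  names(se) <- names(est)
  new("ModelFit", modelLabel = label, response = response,
      predictors = "coral_richness (saturating logistic)",
      coefficients = est, coefficientSe = se, adjustedR2 = adj,
      fStatistic = f, dfModel = p - 1L, dfResidual = as.integer(n - p),
      pValue = pv, aic = .specAic(rss, n, p), n = as.integer(n), rss = rss,
      notes = character(), fit = fit)
}

#' Compare fitted models by AIC
#'
#' All fits must share the response and sample size.  Deltas are AIC
#' differences from the minimum; ties break to the first fit in the list.
#'
#' @param fits list of [ModelFit-class] objects
#' @return a [ModelComparison-class]
#' @export
compareAIC <- function(fits) {
  if (!length(fits) || !all(vapply(fits, is, TRUE, "ModelFit")))
    stop("fits must be a non-empty list of ModelFit objects", call. = FALSE)
  resp <- unique(vapply(fits, function(f) f@response, ""))
  ns <- unique(vapply(fits, function(f) f@n, 1L))
  if (length(resp) != 1L)
    stop("fits do not share a response: ", paste(resp, collapse = ", "),
         call. = FALSE)
  if (length(ns) != 1L)
    stop("fits do not share a sample size: ", paste(ns, collapse = ", "),
         call. = FALSE)
  labels <- vapply(fits, modelLabel, "")
  aics <- vapply(fits, aicValue, 1)
  delta <- aics - min(aics)
  names(delta) <- labels
  best <- labels[which.min(aics)]   # which.min takes the first minimum
  names(fits) <- labels
  new("ModelComparison", fits = fits, deltaAic = delta, best = best)
}

#' Per-family model suite
#'
#' For each fish family, fits the hue-only linear model, the coral-only
#' quadratic model, and the combined hue + coral-polynomial model of that
#' family's species richness, compares them by AIC, and ranks families by
#' the combined model's adjusted R^2.  Families whose richness column is
#' degenerate (e.g. identically zero) are flagged rather than fitted.
#'
#' @param table assembled ecoregion table (see [assembleEcoregionTable()])
#' @param families character vector of family names; column `fish_<family>`
#'   must exist in `table`
#' @return list with `comparisons` (named list of [ModelComparison-class] or
#'   NULL where degenerate) and `ranking` (data.frame sorted by combined
#'   adjusted R^2, with a `degenerate` flag)
#' @export
fitFamilyModels <- function(table, families) {
  cols <- paste0("fish_", families)
  miss <- families[!cols %in% names(table)]
  if (length(miss))
    stop("family missing from table: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (nrow(table) < 5L) stop("need >= 5 ecoregions", call. = FALSE)
  comparisons <- setNames(vector("list", length(families)), families)
  rk <- data.frame(family = families, adj_r2_combined = NA_real_,
                   adj_r2_hue = NA_real_, adj_r2_coral = NA_real_,
                   best_model = NA_character_, degenerate = FALSE,
                   stringsAsFactors = FALSE)
  for (i in seq_along(families)) {
    y <- table[[cols[i]]]
    res <- tryCatch({
      hueOnly <- fitLinear(table$hue_diversity, y, label = "hue_only",
                           response = cols[i], predictor = "hue_diversity")
      coralOnly <- fitQuadratic(table$coral_richness, y,
                                label = "coral_poly2", response = cols[i],
                                predictor = "coral_richness")
      combined <- fitPoly2PlusHue(table$coral_richness, table$hue_diversity,
                                  y, label = "combined", response = cols[i])
      compareAIC(list(hueOnly, coralOnly, combined))
    }, error = function(e) e)
    if (inherits(res, "error") || sd(y) == 0) {
      rk$degenerate[i] <- TRUE
      next
    }
    comparisons[[i]] <- res
    rk$adj_r2_combined[i] <- adjustedR2(res@fits[["combined"]])
    rk$adj_r2_hue[i] <- adjustedR2(res@fits[["hue_only"]])
    rk$adj_r2_coral[i] <- adjustedR2(res@fits[["coral_poly2"]])
    rk$best_model[i] <- bestModel(res)
  }
  rk <- rk[order(-rk$adj_r2_combined, rk$family, na.last = TRUE), ]
  rownames(rk) <- NULL
  list(comparisons = comparisons, ranking = rk)
}

#' Per-ocean-region combined models
#'
#' Fits the combined hue + coral-polynomial model of total fish richness
#' separately within each ocean region.  Regions with fewer ecoregions than
#' `minN` are flagged as underpowered but still fitted while residual
#' degrees of freedom allow; regions with n at or below the parameter count
#' yield a degenerate-fit record instead of a fit.
#'
#' @param table assembled ecoregion table with an `ocean_region` column
#' @param minN minimum region size below which fits are noted underpowered
#' @return named list, one element per region: a [ModelFit-class], or a
#'   list of class `coralhueDegenerateFit` with the failure message
#' @export
fitRegionalModels <- function(table, minN = 6L) {
  if (!"ocean_region" %in% names(table))
    stop("table must have an 'ocean_region' column", call. = FALSE)
  out <- list()
  for (reg in unique(table$ocean_region)) {
    sub <- table[table$ocean_region == reg, , drop = FALSE]
    n <- nrow(sub)
    res <- if (n <= 4L) {
      simpleError(sprintf("degenerate fit: region '%s' has n = %d <= 4 parameters",
                          reg, n))
    } else {
      tryCatch(
        fitPoly2PlusHue(sub$coral_richness, sub$hue_diversity,
                        sub$fish_total, label = paste0("combined_", reg)),
        error = function(e) e)
    }
    if (inherits(res, "error")) {
      warning("region '", reg, "': ", conditionMessage(res), call. = FALSE)
      out[[reg]] <- structure(
        list(region = reg, n = n, error = conditionMessage(res)),
        class = "coralhueDegenerateFit")
    } else {
      if (n < minN) res@notes <- c(res@notes, "underpowered")
      out[[reg]] <- res
    }
  }
  out
}

#' Global fit suite on an ecoregion table
#'
#' Runs the four headline models on an assembled ecoregion table — the
#' linear coral-richness model of fish richness, the saturating logistic of
#' hue diversity on coral richness, the quadratic hue model of fish
#' richness, and the combined multiple regression — plus the AIC comparison
#' of hue-only, coral-only and combined predictors of fish richness.
#'
#' @param table a data.frame with columns `coral_richness`, `hue_diversity`
#'   and `fish_total` (an assembled ecoregion table, or the deposited study
#'   table renamed to this schema)
#' @return list with elements `linear`, `saturating`, `quadratic`,
#'   `combined` ([ModelFit-class]) and `aic` ([ModelComparison-class])
#' @export
fitGlobalModels <- function(table) {
  need <- c("coral_richness", "hue_diversity", "fish_total")
  if (!all(need %in% names(table)))
    stop("table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  coral <- table$coral_richness
  hue <- table$hue_diversity
  fish <- table$fish_total
  linear <- fitLinear(coral, fish, label = "coral_linear",
                      predictor = "coral_richness")
  saturating <- fitSaturating(coral, hue)
  quadratic <- fitQuadratic(hue, fish, label = "hue_quadratic",
                            predictor = "hue_diversity")
  combined <- fitPoly2PlusHue(coral, hue, fish)
  coralOnly <- fitQuadratic(coral, fish, label = "coral_poly2",
                            predictor = "coral_richness")
  hueOnly <- fitLinear(hue, fish, label = "hue_only",
                       predictor = "hue_diversity")
  list(linear = linear, saturating = saturating, quadratic = quadratic,
       combined = combined,
       aic = compareAIC(list(hueOnly, coralOnly, combined)))
}
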