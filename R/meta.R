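## Bleached-vs-healthy effect sizes: Hedges' d (small-sample-corrected
## standardized mean difference) with analytic sampling variance, and
## DerSimonian-Laird random-effects pooling by response class.

.checkComparisons <- function(records) {
  need <- c("study_id", "response_class", "mean_treat", "sd_treat", "n_treat",
            "mean_ctrl", "sd_ctrl", "n_ctrl")
  if (!is.data.frame(records) || !all(need %in% names(records)))
    stop("comparison records must have columns: ",
         paste(need, collapse = ", "), call. = FALSE)
  if (nrow(records) == 0L) stop("no comparison records", call. = FALSE)
  if (any(records$sd_treat < 0 | records$sd_ctrl < 0))
    stop("standard deviations must be >= 0", call. = FALSE)
  if (any(records$n_treat < 2 | records$n_ctrl < 2))
    stop("group sizes must be >= 2", call. = FALSE)
  invisible(records)
}

#' Hedges' d effect sizes for bleached-vs-healthy comparisons
#'
#' For each comparison of group summaries, computes the small-sample
#' corrected standardized mean difference
#' `d = J * (mean_treat - mean_ctrl) / s_pooled` with
#' `s_pooled^2 = ((n_t - 1) sd_t^2 + (n_c - 1) sd_c^2) / (n_t + n_c - 2)`
#' and correction `J = 1 - 3 / (4 (n_t + n_c - 2) - 1)`, and its sampling
#' variance `(n_t + n_c) / (n_t n_c) + d^2 / (2 (n_t + n_c))`.
#'
#' @param records data.frame of comparison records with columns `study_id`,
#'   `response_class`, optional `family`, and the group summaries
#'   `mean_treat, sd_treat, n_treat, mean_ctrl, sd_ctrl, n_ctrl`
#'   (treatment = bleached, control = healthy)
#' @param onDegenerate what to do with comparisons whose pooled SD is zero
#'   (the effect is undefined): `"error"` (default) or `"drop"` with a
#'   warning
#' @return the records with columns `d` and `variance` appended (degenerate
#'   rows removed when dropping)
#' @export
hedgesD <- function(records, onDegenerate = c("error", "drop")) {
  onDegenerate <- match.arg(onDegenerate)
  .checkComparisons(records)
  nt <- records$n_treat
  nc <- records$n_ctrl
  m <- nt + nc - 2
  sp <- sqrt(((nt - 1) * records$sd_treat^2 +
              (nc - 1) * records$sd_ctrl^2) / m)
  bad <- sp <= 0
  if (any(bad)) {
    msg <- paste0("undefined effect (zero pooled SD) for comparison(s): ",
                  paste(which(bad), collapse = ", "))
    if (onDegenerate == "error") stop(msg, call. = FALSE)
    warning(msg, "; dropped", call. = FALSE)
    records <- records[!bad, , drop = FALSE]
    nt <- nt[!bad]; nc <- nc[!bad]; m <- m[!bad]; sp <- sp[!bad]
  }
  j <- 1 - 3 / (4 * m - 1)
  d <- j * (records$mean_treat - records$mean_ctrl) / sp
  records$d <- d
  records$variance <- (nt + nc) / (nt * nc) + d^2 / (2 * (nt + nc))
  records
}

#' Random-effects pooling of effect sizes
#'
#' DerSimonian-Laird pooling: the between-study variance tau^2 is estimated
#' from Cochran's Q (truncated at zero), effects are weighted by
#' `1 / (variance + tau^2)`, and the pooled effect is the weighted mean with
#' standard error `sqrt(1 / sum(weights))`.  `method = "FE"` fixes tau^2 at
#' zero (common-effect pooling).
#'
#' @param d numeric vector of effect sizes
#' @param variance matching sampling variances (> 0)
#' @param method `"DL"` (random effects, default) or `"FE"`
#' @return list with `pooled_d`, `se`, `tau2`, `k`, and `Q`
#' @export
poolRandomEffects <- function(d, variance, method = c("DL", "FE")) {
  method <- match.arg(method)
  if (!length(d)) stop("no effects to pool", call. = FALSE)
  if (length(d) != length(variance) || any(variance <= 0))
    stop("variance must match d and be positive", call. = FALSE)
  k <- length(d)
  w <- 1 / variance
  dFE <- sum(w * d) / sum(w)
  q <- sum(w * (d - dFE)^2)
  tau2 <- 0
  if (method == "DL" && k > 1L) {
    cc <- sum(w) - sum(w^2) / sum(w)
    if (cc > 0) tau2 <- max(0, (q - (k - 1)) / cc)
  }
  ws <- 1 / (variance + tau2)
  list(pooled_d = sum(ws * d) / sum(ws), se = sqrt(1 / sum(ws)),
       tau2 = tau2, k = k, Q = q)
}

#' Pool effects by response class
#'
#' Computes Hedges' d for every comparison and pools within each response
#' class (richness, abundance, recruitment, ...); comparisons of class
#' `family_abundance` are additionally pooled per fish family.  Classes in
#' which every comparison is degenerate (zero pooled SD) are omitted with a
#' warning.
#'
#' @inheritParams hedgesD
#' @param method pooling model passed to [poolRandomEffects()]
#' @return data.frame with one row per class (and per family within
#'   `family_abundance`): `response_class`, `family`, `d`, `se`, `tau2`, `k`
#' @export
summarizeByClass <- function(records, method = c("DL", "FE")) {
  method <- match.arg(method)
  .checkComparisons(records)
  eff <- hedgesD(records, onDegenerate = "drop")
  dropped <- setdiff(unique(records$response_class),
                     unique(eff$response_class))
  if (length(dropped))
    warning("omitting class(es) with only degenerate comparisons: ",
            paste(dropped, collapse = ", "), call. = FALSE)
  if (!"family" %in% names(eff)) eff$family <- NA_character_
  grp <- ifelse(eff$response_class == "family_abundance" &
                  !is.na(eff$family),
                paste(eff$response_class, eff$family, sep = "\r"),
                eff$response_class)
  rows <- lapply(unique(grp), function(g) {
    sub <- eff[grp == g, , drop = FALSE]
    pooled <- poolRandomEffects(sub$d, sub$variance, method = method)
    data.frame(response_class = sub$response_class[1],
               family = if (sub$response_class[1] == "family_abundance")
                 sub$family[1] else NA_character_,
               d = pooled$pooled_d, se = pooled$se, tau2 = pooled$tau2,
               k = pooled$k, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
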