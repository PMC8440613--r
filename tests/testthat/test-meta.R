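# Hedges' d effect sizes and random-effects pooling.

test_that("Hedges' d matches the formula oracle on random records", {
  recs <- random_comparisons(100, seed = 81)
  eff <- hedgesD(recs)
  want <- oracle_hedges(recs$mean_treat, recs$sd_treat, recs$n_treat,
                        recs$mean_ctrl, recs$sd_ctrl, recs$n_ctrl)
  expect_equal(eff$d, want$d, tolerance = 1e-12)
  expect_equal(eff$variance, want$variance, tolerance = 1e-12)
  expect_true(all(eff$variance > 0))
  # sign follows the mean difference
  expect_equal(sign(eff$d),
               sign(recs$mean_treat - recs$mean_ctrl))
})

test_that("null differences, antisymmetry, and the small-sample correction", {
  rec <- data.frame(study_id = "s", response_class = "richness",
                    mean_treat = 10, sd_treat = 2, n_treat = 10,
                    mean_ctrl = 10, sd_ctrl = 2, n_ctrl = 15)
  e <- hedgesD(rec)
  expect_equal(e$d, 0)
  expect_equal(e$variance, (10 + 15) / (10 * 15))
  # known hand computation: means 12 vs 10, common SD 2, n = 10 per group
  rec2 <- data.frame(study_id = "s", response_class = "richness",
                     mean_treat = 12, sd_treat = 2, n_treat = 10,
                     mean_ctrl = 10, sd_ctrl = 2, n_ctrl = 10)
  e2 <- hedgesD(rec2)
  j <- 1 - 3 / (4 * 18 - 1)
  expect_equal(e2$d, j * 1)
  expect_equal(e2$variance, 20 / 100 + (j * 1)^2 / 40)
  # swapping groups negates d, preserves variance
  swap <- rec2
  swap[c("mean_treat", "sd_treat", "n_treat")] <-
    rec2[c("mean_ctrl", "sd_ctrl", "n_ctrl")]
  swap[c("mean_ctrl", "sd_ctrl", "n_ctrl")] <-
    rec2[c("mean_treat", "sd_treat", "n_treat")]
  es <- hedgesD(swap)
  expect_equal(es$d, -e2$d)
  expect_equal(es$variance, e2$variance)
  # Hedges' correction always shrinks towards zero (|g| <= |Cohen's d|)
  recs <- random_comparisons(50, seed = 82)
  eff <- hedgesD(recs)
  cohens <- (recs$mean_treat - recs$mean_ctrl) /
    sqrt(((recs$n_treat - 1) * recs$sd_treat^2 +
          (recs$n_ctrl - 1) * recs$sd_ctrl^2) /
         (recs$n_treat + recs$n_ctrl - 2))
  expect_true(all(abs(eff$d) <= abs(cohens)))
  # zero pooled SD is an undefined effect
  degen <- rec; degen$sd_treat <- 0; degen$sd_ctrl <- 0
  expect_error(hedgesD(degen), "undefined effect")
})

test_that("effect sizes agree with metafor's SMD computation", {
  skip_if_not_installed("metafor")
  # moderate n and effect magnitude: the exact-vs-approximate small-sample
  # correction difference is O(1/m^2) and stays well under the tolerance
  recs <- random_comparisons(40, seed = 83, nMin = 15, meanMax = 5)
  eff <- hedgesD(recs)
  es <- metafor::escalc(measure = "SMD",
                        m1i = recs$mean_treat, sd1i = recs$sd_treat,
                        n1i = recs$n_treat, m2i = recs$mean_ctrl,
                        sd2i = recs$sd_ctrl, n2i = recs$n_ctrl)
  # metafor applies the exact gamma-based correction; ours is the
  # 1 - 3/(4m-1) approximation, so agreement is near but not exact
  expect_equal(eff$d, as.numeric(es$yi), tolerance = 2e-3)
  expect_equal(eff$variance, as.numeric(es$vi), tolerance = 2e-3)
})

test_that("DerSimonian-Laird pooling behaves on degenerate and homogeneous input", {
  one <- poolRandomEffects(0.7, 0.04)
  expect_equal(one$pooled_d, 0.7)
  expect_equal(one$tau2, 0)
  expect_equal(one$se, 0.2)
  # equal-variance homogeneous effects pool to the arithmetic mean
  d <- c(0.5, 0.52, 0.48, 0.5)
  hom <- poolRandomEffects(d, rep(0.25, 4))
  expect_equal(hom$pooled_d, mean(d))
  expect_equal(hom$tau2, 0)  # Q below its df truncates tau^2 at zero
  # pooled estimate is a convex combination of the inputs
  set.seed(84)
  dd <- rnorm(10); vv <- runif(10, 0.01, 0.5)
  p <- poolRandomEffects(dd, vv)
  expect_gte(p$pooled_d, min(dd))
  expect_lte(p$pooled_d, max(dd))
  expect_error(poolRandomEffects(numeric(0), numeric(0)), "no effects")
})

test_that("pooling agrees with metafor's DL estimator", {
  skip_if_not_installed("metafor")
  set.seed(85)
  d <- rnorm(15, -0.6, 0.4)
  v <- runif(15, 0.02, 0.3)
  p <- poolRandomEffects(d, v)
  r <- suppressWarnings(metafor::rma(yi = d, vi = v, method = "DL"))
  expect_equal(p$pooled_d, as.numeric(r$beta), tolerance = 1e-10)
  expect_equal(p$se, r$se, tolerance = 1e-10)
  expect_equal(p$tau2, r$tau2, tolerance = 1e-10)
})

test_that("random-effects pooling recovers a known mean over simulated syntheses", {
  set.seed(86)
  trueD <- -0.9
  tau2 <- 0.04
  hits <- 0L
  reps <- 500L
  for (r in seq_len(reps)) {
    k <- 12L
    v <- runif(k, 0.02, 0.2)
    d <- rnorm(k, trueD, sqrt(tau2 + v))
    p <- poolRandomEffects(d, v)
    if (abs(p$pooled_d - trueD) <= 3 * p$se) hits <- hits + 1L
  }
  expect_gte(hits / reps, 0.95)
})

test_that("class summaries pool per class and per family with conserved counts", {
  set.seed(87)
  mk <- function(cls, k, d, fam = NA_character_) {
    sdv <- runif(k, 1, 3)
    mc <- runif(k, 10, 30)
    data.frame(study_id = sprintf("s%d", seq_len(k)), response_class = cls,
               family = fam, mean_treat = mc + d * sdv, sd_treat = sdv,
               n_treat = sample(10:30, k, TRUE), mean_ctrl = mc,
               sd_ctrl = sdv, n_ctrl = sample(10:30, k, TRUE),
               stringsAsFactors = FALSE)
  }
  recs <- rbind(mk("richness", 8, -1.2), mk("abundance", 6, 0.8),
                mk("family_abundance", 5, -0.6, "Gobiidae"),
                mk("family_abundance", 4, -0.2, "Labridae"))
  out <- summarizeByClass(recs)
  expect_equal(sum(out$k), nrow(recs))
  expect_equal(out$k[out$response_class == "richness"], 8L)
  # generator-set signs of opposite direction are recovered
  expect_lt(out$d[out$response_class == "richness"], 0)
  expect_gt(out$d[out$response_class == "abundance"], 0)
  expect_setequal(out$family[out$response_class == "family_abundance"],
                  c("Gobiidae", "Labridae"))
  # a class of only degenerate comparisons is omitted with a warning
  degen <- mk("recruitment", 2, 0)
  degen$sd_treat <- 0; degen$sd_ctrl <- 0
  expect_warning(   # inner warning: degenerate rows dropped by hedgesD
    expect_warning(out2 <- summarizeByClass(rbind(recs, degen)),
                   "recruitment"),
    "dropped")
  expect_false("recruitment" %in% out2$response_class)
})
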