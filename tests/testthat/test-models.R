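# Regression suite: OLS against the normal equations, adjusted R^2 identity,
# saturating logistic recovery, AIC comparison, family and regional fits.

test_that("linear and polynomial fits reproduce the normal-equations solution", {
  set.seed(51)
  for (rep in 1:10) {
    n <- sample(5:50, 1)
    x <- runif(n, 0, 600)
    z <- runif(n, 0, 180)
    y <- 3 + 0.5 * x - 1e-3 * x^2 + 2 * z + rnorm(n, 0, 20)
    flin <- fitLinear(x, y)
    expect_lt(max(abs(coef(flin) - oracle_ols(cbind(1, x), y))), 1e-8)
    fq <- fitQuadratic(x, y)
    expect_lt(max(abs(coef(fq) - oracle_ols(cbind(1, x, x^2), y))), 1e-8)
    fc <- fitPoly2PlusHue(x, z, y)
    expect_lt(max(abs(coef(fc) - oracle_ols(cbind(1, z, x, x^2), y))), 1e-8)
  }
  expect_error(fitLinear(rep(2, 10), rnorm(10)), "singular")
  expect_error(fitPoly2PlusHue(1:10, 2 * (1:10), rnorm(10)), "singular")
})

test_that("adjusted R^2 matches the residual-based identity and edge cases", {
  set.seed(52)
  n <- 40
  x <- runif(n, 0, 100)
  y <- 2 + 0.3 * x + rnorm(n, 0, 5)
  f <- fitLinear(x, y)
  rss <- sum((y - cbind(1, x) %*% oracle_ols(cbind(1, x), y))^2)
  r2 <- 1 - rss / sum((y - mean(y))^2)
  expect_equal(adjustedR2(f), 1 - (1 - r2) * (n - 1) / (n - 2),
               tolerance = 1e-12)
  # exact line: adjusted R^2 = 1
  expect_equal(adjustedR2(fitLinear(1:10, 5 + 2 * (1:10))), 1)
  # independent response at large n: adjusted R^2 near 0
  set.seed(53)
  xr <- runif(2000); yr <- rnorm(2000)
  expect_lt(abs(adjustedR2(fitLinear(xr, yr))), 0.05)
  # exact parabola through the quadratic fit
  xx <- 1:8
  expect_equal(adjustedR2(fitQuadratic(xx, 1 + xx - 0.5 * xx^2)), 1)
})

test_that("reported F degrees of freedom follow the model structure", {
  set.seed(54)
  coral <- runif(74, 10, 600)
  hue <- runif(74, 5, 180)
  fish <- 100 + 2 * coral + 3 * hue + rnorm(74, 0, 50)
  fc <- fitPoly2PlusHue(coral, hue, fish)
  expect_equal(c(fc@dfModel, fc@dfResidual), c(3L, 70L))
  fq <- fitQuadratic(hue, fish)
  expect_equal(c(fq@dfModel, fq@dfResidual), c(2L, 71L))
  fl <- fitLinear(coral, fish)
  expect_equal(c(fl@dfModel, fl@dfResidual), c(1L, 72L))
  # a 13-ecoregion region keeps F(3, 9)
  f13 <- fitPoly2PlusHue(coral[1:13], hue[1:13], fish[1:13])
  expect_equal(c(f13@dfModel, f13@dfResidual), c(3L, 9L))
})

test_that("zero-noise data reproduce generating coefficients", {
  coral <- seq(10, 600, length.out = 30)
  hue <- 150 / (1 + exp(-0.03 * (coral - 150)))
  fish <- 50 + 1.2 * coral - 8e-4 * coral^2 + 3.5 * hue
  fc <- fitPoly2PlusHue(coral, hue, fish)
  expect_lt(max(abs(coef(fc) - c(50, 3.5, 1.2, -8e-4))), 1e-8)
  expect_equal(adjustedR2(fc), 1, tolerance = 1e-12)
  fs <- fitSaturating(coral, hue)
  expect_lt(max(abs(coef(fs) - c(A = 150, k = 0.03, x0 = 150))), 1e-6)
})

test_that("the saturating logistic recovers a noisy asymptote within its SE", {
  set.seed(55)
  coral <- runif(74, 10, 600)
  hue <- 180 / (1 + exp(-0.022 * (coral - 110))) + rnorm(74, 0, 6)
  f <- fitSaturating(coral, hue)
  expect_lt(abs(coef(f)[["A"]] - 180), 3 * f@coefficientSe[["A"]])
  expect_gt(adjustedR2(f), 0.9)
})

test_that("AIC comparison uses the stated convention, first-label ties, and input checks", {
  set.seed(56)
  x <- runif(30, 0, 10)
  y <- 1 + x + rnorm(30)
  f1 <- fitLinear(x, y, label = "m1")
  f2 <- fitLinear(x, y, label = "m2")
  cmp <- compareAIC(list(f1, f2))
  expect_equal(unname(deltaAic(cmp)), c(0, 0))
  expect_equal(bestModel(cmp), "m1")
  # AIC value follows n*log(RSS/n) + 2(p+1)
  rss <- f1@rss
  expect_equal(aicValue(f1), 30 * log(rss / 30) + 2 * 3, tolerance = 1e-10)
  # deltas agree with the likelihood-based stats::AIC deltas for lm fits
  fq <- fitQuadratic(x, y, label = "quad")
  d_spec <- aicValue(fq) - aicValue(f1)
  d_stats <- stats::AIC(fq@fit) - stats::AIC(f1@fit)
  expect_equal(d_spec, d_stats, tolerance = 1e-8)
  yy <- y[-1]
  f3 <- fitLinear(x[-1], yy, label = "short")
  expect_error(compareAIC(list(f1, f3)), "sample size")
  f4 <- fitLinear(x, y, label = "other", response = "something_else")
  expect_error(compareAIC(list(f1, f4)), "response")
})

test_that("a superfluous predictor is usually rejected and a real one selected", {
  set.seed(57)
  winsSimple <- 0L
  winsTrue <- 0L
  reps <- 200L
  coral <- runif(60, 10, 600)
  hue <- 150 / (1 + exp(-0.03 * (coral - 150))) + rnorm(60, 0, 5)
  for (r in seq_len(reps)) {
    # response depends on coral only: the hue term is pure noise
    yN <- 20 + 0.8 * coral + rnorm(60, 0, 10)
    cN <- compareAIC(list(
      fitQuadratic(coral, yN, label = "coral_poly2",
                   predictor = "coral_richness"),
      fitPoly2PlusHue(coral, hue, yN, label = "combined")))
    if (bestModel(cN) == "coral_poly2") winsSimple <- winsSimple + 1L
    # response depends on both: combined is the generating model
    yB <- 20 + 0.8 * coral - 6e-4 * coral^2 + 2.5 * hue + rnorm(60, 0, 10)
    cB <- compareAIC(list(
      fitLinear(hue, yB, label = "hue_only", predictor = "hue_diversity"),
      fitQuadratic(coral, yB, label = "coral_poly2",
                   predictor = "coral_richness"),
      fitPoly2PlusHue(coral, hue, yB, label = "combined")))
    if (bestModel(cB) == "combined") winsTrue <- winsTrue + 1L
  }
  expect_gt(winsSimple / reps, 0.5)
  expect_gt(winsTrue / reps, 0.9)
})

test_that("family fits rank families by combined fit and flag degenerate ones", {
  set.seed(58)
  n <- 40
  coral <- runif(n, 10, 600)
  hue <- 150 / (1 + exp(-0.03 * (coral - 150))) + rnorm(n, 0, 4)
  mu <- 10 + 0.4 * coral - 2e-4 * coral^2 + 0.5 * hue
  tab <- data.frame(
    ecoregion = sprintf("e%02d", 1:n), ocean_region = "A",
    coral_richness = coral, hue_diversity = hue,
    fish_total = 3 * mu,
    fish_clean = mu + rnorm(n, 0, 2),      # low noise
    fish_mid = mu + rnorm(n, 0, 25),       # moderate noise
    fish_noisy = mu + rnorm(n, 0, 120),    # high noise
    fish_flat = 0)                          # degenerate
  res <- fitFamilyModels(tab, c("clean", "mid", "noisy", "flat"))
  rk <- res$ranking
  expect_equal(rk$family[!rk$degenerate], c("clean", "mid", "noisy"))
  expect_true(rk$degenerate[rk$family == "flat"])
  expect_null(res$comparisons[["flat"]])
  expect_s4_class(res$comparisons[["clean"]], "ModelComparison")
  expect_error(fitFamilyModels(tab, "absent"), "absent")
})

test_that("regional fits share global structure and flag tiny regions", {
  set.seed(59)
  n <- 74
  region <- rep(c("WP", "CEP", "ATL", "NI"), c(31, 16, 13, 14))
  coral <- runif(n, 10, 600)
  hue <- 180 / (1 + exp(-0.022 * (coral - 110))) + rnorm(n, 0, 5)
  b <- c(50, 3, 1.2, -8e-4)
  fish <- b[1] + b[2] * hue + b[3] * coral + b[4] * coral^2 + rnorm(n, 0, 30)
  tab <- data.frame(ecoregion = sprintf("e%02d", 1:n), ocean_region = region,
                    coral_richness = coral, hue_diversity = hue,
                    fish_total = fish)
  fits <- fitRegionalModels(tab)
  expect_setequal(names(fits), c("WP", "CEP", "ATL", "NI"))
  f13 <- fits[["ATL"]]
  expect_equal(c(f13@dfModel, f13@dfResidual), c(3L, 9L))
  for (f in fits) {
    expect_s4_class(f, "ModelFit")
    ok <- abs(coef(f) - b) <= 4 * f@coefficientSe | f@coefficientSe == 0
    expect_true(all(ok))
  }
  # a 4-point region cannot support a 4-parameter model
  tiny <- tab[1:24, ]
  tiny$ocean_region <- rep(c("big", "small"), c(20, 4))
  expect_warning(fitRegionalModels(tiny), "degenerate")
  fits2 <- suppressWarnings(fitRegionalModels(tiny))
  expect_s3_class(fits2[["small"]], "coralhueDegenerateFit")
  expect_s4_class(fits2[["big"]], "ModelFit")
  # a small-but-fittable region is noted underpowered
  tab5 <- tab[1:25, ]
  tab5$ocean_region <- rep(c("big", "small"), c(20, 5))
  fits3 <- fitRegionalModels(tab5)
  expect_true("underpowered" %in% fits3[["small"]]@notes)
})
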