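test_that("fit metrics reproduce hand-computed values", {
  m <- fitMetrics(1:5, 1:5, p = 2)
  expect_equal(r2(m), 1)
  expect_equal(rmse(m), 0)

  # SSE = 0.11, SST = 10, adjustment (n-1)/(n-p) = 4/3
  m <- fitMetrics(c(1, 2, 3, 4, 5), c(1.1, 1.9, 3.2, 3.8, 5.1), p = 2)
  expect_equal(rmse(m), sqrt(0.11 / 3), tolerance = 1e-12)
  expect_equal(r2(m), 1 - (4 / 3) * 0.11 / 10, tolerance = 1e-12)
  expect_equal(rmse(m), 0.19149, tolerance = 1e-4)
  expect_equal(r2(m), 0.98533, tolerance = 1e-4)
})

test_that("adjusted R2 is below the unadjusted value whenever SSE > 0", {
  set.seed(3)
  for (i in 1:20) {
    y <- rnorm(15)
    yp <- y + rnorm(15, 0, 0.3)
    m <- fitMetrics(y, yp, p = 4)
    unadj <- 1 - sum((y - yp)^2) / sum((y - mean(y))^2)
    expect_lt(r2(m), unadj)
    # with p = 1 the adjustment factor is exactly 1
    expect_equal(r2(fitMetrics(y, yp, p = 1)), unadj, tolerance = 1e-12)
  }
})

test_that("fit metrics reject degenerate inputs", {
  expect_error(fitMetrics(1:3, 1:3, p = 4), "degrees-of-freedom")
  expect_error(fitMetrics(rep(2, 6), rnorm(6), p = 2), "zero variance")
  expect_error(fitMetrics(1:5, 1:4, p = 2), "equal length")
})

test_that("curve correlation matches hand computation", {
  expect_equal(curveCorrelation(1:5, 1:5), 1)
  expect_equal(curveCorrelation(1:5, -(1:5)), -1)
  expect_equal(curveCorrelation(c(1, 2, 3), c(2, 4, 5)), 0.9819805,
               tolerance = 1e-6)
  expect_error(curveCorrelation(rep(1, 4), 1:4), "zero variance")
  expect_error(curveCorrelation(1:2, 1:2), ">= 3")
})

test_that("noiseless data are recovered exactly by every model", {
  truth <- growthParams(4, 6, 0.06, 50)
  for (k in modelKinds()) {
    s <- evaluateCurve(k, truth, gridHours)
    fit <- fitGrowth(s, k, fastOpts)
    expect_gt(r2(fit), 1 - 1e-8)
    expect_equal(muMax(fit), 0.06, tolerance = 1e-5, label = k)
    expect_equal(lagTime(fit), 50, tolerance = 1e-3 * 50, label = k)
    expect_equal(n0(fit), 4, tolerance = 1e-5, label = k)
    expect_equal(nMax(fit), 6, tolerance = 1e-5, label = k)
  }
})

test_that("the optimizer beats an exhaustive parameter grid", {
  set.seed(5)
  tt <- seq(0, 168, length.out = 8)
  truth <- growthParams(4, 6, 0.05, 60)
  y <- GrowthSense:::.curveValues("logistic", truth, tt) + rnorm(8, 0, 0.1)
  fit <- fitGrowth(curveSeries(tt, y), "logistic", fitOptions(nRestarts = 16))
  oracle <- gridSearchSSE("logistic", tt, y, nGrid = 20L)
  expect_lte(fit@sse, oracle + 1e-12)
})

test_that("fitted SSE never exceeds SSE at the generating parameters", {
  set.seed(17)
  for (i in 1:12) {
    k <- modelKinds()[(i %% 4) + 1]
    truth <- randomParams(increasing = i %% 2 == 0)
    y <- GrowthSense:::.curveValues(k, truth, gridHours) +
      rnorm(length(gridHours), 0, 0.1)
    fit <- fitGrowth(curveSeries(gridHours, y), k, fastOpts)
    sseTruth <- sum((y - GrowthSense:::.curveValues(k, truth, gridHours))^2)
    expect_lte(fit@sse, sseTruth + 1e-10, label = k)
  }
})

test_that("fitting is bit-reproducible for a fixed seed", {
  tab <- pcTab$scores
  s <- curveSeries(tab$time_h, -tab$score)
  f1 <- fitGrowth(s, "baranyi", fitOptions(nRestarts = 12, seed = 99))
  f2 <- fitGrowth(s, "baranyi", fitOptions(nRestarts = 12, seed = 99))
  expect_identical(f1, f2)
})

test_that("fitAll ranks the generating model first on noiseless data", {
  truth <- tableParams("baranyi")
  s <- evaluateCurve("baranyi", truth, gridHours)
  fits <- fitAll(s, fastOpts)
  expect_identical(modelKind(fits[[1]]), "baranyi")
  expect_gt(r2(fits[[1]]), 1 - 1e-8)
  for (f in fits[-1]) expect_gt(f@sse, fits[[1]]@sse)
  # results arrive sorted by adjusted R2
  r2s <- vapply(fits, r2, 0)
  expect_true(all(diff(r2s) <= 1e-12))
})

test_that("constant series cannot be fitted", {
  expect_error(fitGrowth(curveSeries(gridHours, rep(2, 15)), "logistic"),
               "zero variance|degenerate")
})

test_that("a reference series yields a recorded curve correlation", {
  tab <- pcTab$scores
  ref <- evaluateCurve("baranyi", tableParams("baranyi"), tab$time_h)@values
  fit <- fitGrowth(curveSeries(tab$time_h, -tab$score), "baranyi", fastOpts,
                   reference = ref)
  expect_length(fit@r, 1)
  expect_true(abs(fit@r) <= 1)
  expect_gt(fit@r, 0.9)  # fused score tracks the growth curve closely
  noref <- fitGrowth(curveSeries(tab$time_h, -tab$score), "baranyi", fastOpts)
  expect_length(noref@r, 0)
})

test_that("validation reuses the trained curve without refitting", {
  fx <- makeFixture(seed = 1)
  train <- fx$panel[, SummarizedExperiment::colData(fx$panel)$replicate %in%
                      fx$trainReplicates]
  # identical panels: test metrics must equal train metrics
  fit <- fitWithValidation(train, train, "S7", "baranyi", fastOpts)
  expect_equal(r2(testMetrics(fit)), r2(trainMetrics(fit)), tolerance = 1e-12)
  expect_equal(rmse(testMetrics(fit)), rmse(trainMetrics(fit)),
               tolerance = 1e-12)

  # homogeneous noise: train and test R2 agree closely across the split
  test <- fx$panel[, SummarizedExperiment::colData(fx$panel)$replicate %in%
                     fx$testReplicates]
  fit2 <- fitWithValidation(train, test, "S7", "baranyi", fastOpts)
  expect_lt(abs(r2(testMetrics(fit2)) - r2(trainMetrics(fit2))), 0.1)
  expect_identical(testMetrics(fit2)@p, 4L)
})

test_that("mismatched train/test time grids raise an alignment error", {
  fx <- makeFixture(seed = 1)
  train <- GrowthSense:::.splitPanel(fx$panel, 1:15)
  test <- GrowthSense:::.splitPanel(fx$panel, 16:20)
  shifted <- test
  SummarizedExperiment::colData(shifted)$time_h <-
    SummarizedExperiment::colData(shifted)$time_h + 1
  expect_error(fitWithValidation(train, shifted, "S7", "baranyi", fastOpts),
               "alignment")
})
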