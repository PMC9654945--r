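test_that("the generator is deterministic in its seed", {
  a <- makeFixture(seed = 4)
  b <- makeFixture(seed = 4)
  expect_identical(SummarizedExperiment::assay(a$panel),
                   SummarizedExperiment::assay(b$panel))
  c <- makeFixture(seed = 5)
  expect_false(identical(SummarizedExperiment::assay(a$panel),
                         SummarizedExperiment::assay(c$panel)))
})

test_that("the fixture has the full study shape with no missing cells", {
  fx <- makeFixture(seed = 1)
  expect_identical(dim(fx$panel), c(20L, 300L))  # 20 channels, 15 x 20 samples
  expect_false(anyNA(SummarizedExperiment::assay(fx$panel)))
  expect_identical(panelTimes(fx$panel), seq(0, 168, by = 12))
  expect_identical(fx$trainReplicates, 1:15)
  expect_identical(fx$testReplicates, 16:20)
  expect_true("log_cfu" %in% panelChannels(fx$panel))
})

test_that("noiseless counts equal the latent curve exactly", {
  d <- studyDesign()
  p <- simulateCounts(noiseSd = 0, seed = 8, design = d)
  lat <- evaluateCurve("baranyi", tableParams("baranyi"), d@times)@values
  m <- GrowthSense:::.panelChannelMeans(p, "log_cfu")
  expect_equal(m$means, lat, tolerance = 1e-12)
  v <- SummarizedExperiment::assay(p)["log_cfu", ]
  expect_equal(as.numeric(tapply(v, SummarizedExperiment::colData(p)$time_h,
                                 sd)),
               rep(0, 15))
  expect_error(simulateCounts(noiseSd = -0.1, seed = 1), "noiseSd")
})

test_that("replicate scatter of simulated counts matches sigma = 0.1", {
  p <- simulateCounts(noiseSd = 0.1, seed = 2)
  v <- SummarizedExperiment::assay(p)["log_cfu", ]
  sds <- tapply(v, SummarizedExperiment::colData(p)$time_h, sd)
  # chi-square bounds on a sample sd at n = 20
  expect_gte(sum(sds > 0.05 & sds < 0.17), 13)
})

test_that("fitting the simulated means recovers the generating rate", {
  p <- simulateCounts(noiseSd = 0.1, seed = 7)
  m <- GrowthSense:::.panelChannelMeans(p, "log_cfu")
  fit <- fitGrowth(curveSeries(m$times, m$means), "baranyi", fastOpts)
  expect_lt(abs(muMax(fit) - 0.064) / 0.064, 0.10)
})

test_that("identity calibration without noise returns the latent curve", {
  d <- studyDesign()
  lat <- curveSeries(d@times, evaluateCurve("baranyi", tableParams("baranyi"),
                                            d@times)@values)
  cal <- data.frame(channel = "sweetness", intercept = 0, slope = 1,
                    noise_sd = 0)
  p <- simulatePanel(lat, cal, d, seed = 3)
  m <- GrowthSense:::.panelChannelMeans(p, "sweetness")
  expect_equal(m$means, lat@values, tolerance = 1e-12)

  bad <- data.frame(channel = "nope", intercept = 0, slope = 1, noise_sd = 0)
  expect_error(simulatePanel(lat, bad, d, seed = 3), "consistency")
  neg <- data.frame(channel = "sweetness", intercept = 0, slope = 1,
                    noise_sd = -1)
  expect_error(simulatePanel(lat, neg, d, seed = 3), "noise_sd")
})

test_that("default calibrations hit their correlation targets", {
  d <- studyDesign()
  lat <- curveSeries(d@times, evaluateCurve("baranyi", tableParams("baranyi"),
                                            d@times)@values)
  p <- simulatePanel(lat, channelCalibrations(d), d, seed = 3)
  rSweet <- cor(GrowthSense:::.panelChannelMeans(p, "sweetness")$means,
                lat@values)
  expect_gt(rSweet, 0.6)
  expect_lt(rSweet, 0.95)
  rS7 <- cor(GrowthSense:::.panelChannelMeans(p, "S7")$means, lat@values)
  expect_lt(rS7, -0.8)
})

test_that("replicate means converge to the latent curve", {
  d <- studyDesign(replicates = 2000L, trainReplicates = 1500L)
  lat <- curveSeries(d@times, evaluateCurve("baranyi", tableParams("baranyi"),
                                            d@times)@values)
  cal <- data.frame(channel = "sweetness", intercept = 2, slope = 1.5,
                    noise_sd = 1)
  p <- simulatePanel(lat, cal, d, seed = 6)
  m <- GrowthSense:::.panelChannelMeans(p, "sweetness")
  expect_true(all(abs(m$means - (2 + 1.5 * lat@values)) < 3 * 1 / sqrt(2000)))
})

test_that("a noise-free fused composite is a monotone transform of growth", {
  d <- studyDesign()
  lat <- curveSeries(d@times, evaluateCurve("baranyi", tableParams("baranyi"),
                                            d@times)@values)
  cal <- channelCalibrations(d)
  cal$noise_sd <- 0
  cal$drift1 <- cal$drift2 <- cal$drift3 <- 0
  p <- simulatePanel(lat, cal, d, seed = 1)
  mm <- GrowthSense:::.panelMeanMatrix(p)
  f <- fusePCA(standardizeMatrix(mm), 0.90, times = d@times)
  oriented <- orientForFitting(f@composite)$series
  expect_equal(abs(cor(oriented, lat@values, method = "spearman")), 1)
  expect_true(all(diff(oriented) * diff(lat@values) >= 0))
})

test_that("noiseless simulated data return the generating rate exactly", {
  for (k in modelKinds()) {
    truth <- tableParams(k)
    d <- studyDesign(replicates = 2L, trainReplicates = 1L)
    p <- simulateCounts(truth, k, d, noiseSd = 0, seed = 1)
    m <- GrowthSense:::.panelChannelMeans(p, "log_cfu")
    fit <- fitGrowth(curveSeries(m$times, m$means), k, fastOpts)
    expect_lt(abs(muMax(fit) - muMax(truth)) / muMax(truth), 1e-6)
  }
})

test_that("pipeline selection matches the generator's signal-to-noise order", {
  fx <- makeFixture(seed = 1)
  rep <- runPipeline(pipelineConfig("fixture:1", fitOptions = fastOpts))
  cal <- fx$calibrations
  en <- cal[cal$channel %in% fx$design@enoseChannels, ]
  bestSNR <- en$channel[which.max(abs(en$slope) / en$noise_sd)]
  expect_identical(rep@selection$enoseChannel, bestSNR)
})
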