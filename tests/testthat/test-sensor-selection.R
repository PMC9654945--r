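test_that("panel summaries give textbook mean/sd/n", {
  m <- matrix(c(1, 2, 3), 1, 3, dimnames = list("ch", NULL))
  p <- replicatePanel(m, time_h = c(0, 0, 0), replicate = 1:3)
  s <- summarizePanel(p)
  expect_equal(s$mean, 2)
  expect_equal(s$sd, 1)
  expect_equal(s$n, 3L)

  m2 <- matrix(5, 1, 4, dimnames = list("ch", NULL))
  p2 <- replicatePanel(m2, time_h = c(0, 0, 12, 12), replicate = c(1, 2, 1, 2))
  expect_true(all(summarizePanel(p2)$sd == 0))

  p3 <- replicatePanel(m2, time_h = c(0, 0, 12, 24), replicate = c(1, 2, 1, 1))
  expect_error(summarizePanel(p3), "insufficient replicates")
})

test_that("simulated sweetness replicate scatter matches its configured noise", {
  fx <- makeFixture(seed = 1)
  s <- summarizePanel(fx$panel["sweetness", ])
  sd0 <- s$sd[s$time_h == 0]
  # chi-square bounds on a sample sd at n = 20, sigma = 2
  expect_gt(sd0, 1.2)
  expect_lt(sd0, 2.9)
})

test_that("ANOVA from summaries reproduces hand-computed cases", {
  a <- anovaFromSummary(data.frame(mean = c(0, 1), sd = c(1, 1), n = c(2, 2)))
  expect_equal(a@fStat, 1)
  expect_identical(c(a@dfBetween, a@dfWithin), c(1L, 2L))

  b <- anovaFromSummary(data.frame(mean = c(3, 3, 3), sd = c(1, 2, 1), n = 5))
  expect_equal(b@fStat, 0)

  # all-zero sd with unequal means: infinite-F degenerate signal
  d <- anovaFromSummary(data.frame(mean = c(0, 1), sd = c(0, 0), n = 3))
  expect_true(is.infinite(d@fStat))
  expect_equal(d@pValue, 0)
})

test_that("summary ANOVA equals classic ANOVA on the raw replicates", {
  set.seed(21)
  for (i in 1:50) {
    k <- sample(3:8, 1)
    groups <- lapply(seq_len(k), function(j)
      rnorm(sample(3:12, 1), mean = rnorm(1, 0, 2), sd = runif(1, 0.2, 2)))
    summ <- data.frame(mean = vapply(groups, mean, 0),
                       sd = vapply(groups, sd, 0),
                       n = lengths(groups))
    ours <- anovaFromSummary(summ)
    oracle <- aovOracle(groups)
    expect_equal(ours@fStat, oracle$f, tolerance = 1e-10)
    expect_equal(ours@pValue, oracle$p, tolerance = 1e-10)
    expect_equal(ours@mse, oracle$mse, tolerance = 1e-10)
    expect_identical(c(ours@dfBetween, ours@dfWithin),
                     c(as.integer(oracle$dfb), as.integer(oracle$dfw)))
  }
})

test_that("the strongly significant S7 channel is detected", {
  a <- anovaFromSummary(s7Summary())
  expect_lt(a@pValue, 0.01)
})

test_that("Duncan letters separate clearly distinct means", {
  g <- data.frame(time_h = c(0, 12), mean = c(10, 1), sd = 0.1, n = 5)
  lg <- duncanLetters(g)
  expect_identical(sort(lg@letters), c("a", "b"))

  g3 <- data.frame(time_h = c(0, 12, 24), mean = c(10, 9.9, 1), sd = 0.1, n = 5)
  lg3 <- duncanLetters(g3)
  # top two share a letter, the distant third gets its own
  expect_identical(lg3@letters[1], lg3@letters[2])
  expect_false(lg3@letters[3] %in% lg3@letters[1:2])
  expect_identical(discriminationCount(lg3), 2L)
})

test_that("Duncan never separates means closer than the 2-group range", {
  set.seed(31)
  for (i in 1:25) {
    k <- sample(4:10, 1)
    g <- data.frame(time_h = seq_len(k), mean = rnorm(k, 0, 1.5),
                    sd = runif(k, 0.3, 1.5), n = sample(5:20, 1))
    a <- anovaFromSummary(g)
    lg <- duncanLetters(g, a)
    nh <- k / sum(1 / g$n)
    r2crit <- qtukey(0.95, 2, a@dfWithin) * sqrt(a@mse / nh)
    shared <- function(x, y)
      length(intersect(strsplit(x, "")[[1]], strsplit(y, "")[[1]])) > 0
    for (u in seq_len(k - 1)) for (v in seq.int(u + 1, k)) {
      if (abs(g$mean[u] - g$mean[v]) < r2crit)
        expect_true(shared(lg@letters[u], lg@letters[v]))
    }
  }
})

test_that("discrimination counts are invariant to letter renaming", {
  lets <- c("a", "ab", "b", "bc", "c")
  perm <- chartr("abc", "zxq", lets)
  expect_identical(discriminationCount(lets), discriminationCount(perm))
  expect_identical(discriminationCount(rep("a", 15)), 1L)
})

test_that("published letter columns give the published discrimination counts", {
  for (ch in c(S1 = "S1", S2 = "S2", S5 = "S5", S7 = "S7")) {
    want <- c(S1 = 7L, S2 = 9L, S5 = 10L, S7 = 12L)[[ch]]
    lets <- enoseTab$letters[enoseTab$channel == ch]
    expect_identical(discriminationCount(lets), want, label = ch)
  }
})

test_that("recomputed Duncan letters form a valid grouping for S7", {
  g <- s7Summary()
  lg <- duncanLetters(g, anovaFromSummary(g), alpha = 0.05)
  expect_true(all(nzchar(lg@letters)))
  # largest mean carries the first letter of the display
  expect_true(grepl("a", lg@letters[which.max(g$mean)]))
  # the clearly separated extremes never share a letter
  expect_false(any(strsplit(lg@letters[which.max(g$mean)], "")[[1]] %in%
                     strsplit(lg@letters[which.min(g$mean)], "")[[1]]))
})

test_that("correlation tables carry stars, symmetry and a unit diagonal", {
  ct <- pearsonWithStars(list(a = c(1, 2, 3, 4), b = c(2, 4, 5, 9),
                              c = c(4, 3, 2, 1)))
  expect_equal(diag(ct@r), c(a = 1, b = 1, c = 1))
  expect_equal(ct@r, t(ct@r))
  expect_equal(ct@r["a", "c"], -1)
  expect_identical(ct@stars["a", "c"], "**")
  expect_error(pearsonWithStars(list(a = rep(1, 4), b = 1:4)),
               "zero variance.*'a'")
})

test_that("S7 and S9 mean responses are almost perfectly correlated", {
  ct <- pearsonWithStars(list(S7 = channelMeans("S7"), S9 = channelMeans("S9")))
  expect_equal(ct@r["S7", "S9"], 0.998, tolerance = 0.002)
  expect_identical(ct@stars["S7", "S9"], "**")
})

test_that("loadings analysis ranks high-variance channels first", {
  set.seed(41)
  m <- cbind(big = cumsum(rnorm(10, 0, 5)), small = rnorm(10, 0, 0.1),
             tiny = rnorm(10, 0, 0.05))
  l <- enoseLoadings(m)
  expect_identical(l$ranking[1], "big")

  # the published mean panel: the widest-swinging channels dominate PC1
  mm <- sapply(paste0("S", 1:10), channelMeans)
  lp <- enoseLoadings(mm)
  expect_true("S2" %in% lp$ranking[1:2])
  expect_true(all(lp$varianceFractions >= 0))

  dup <- cbind(m, big2 = m[, "big"])
  ld <- enoseLoadings(dup)
  expect_equal(abs(ld$loadings["big", 1]), abs(ld$loadings["big2", 1]),
               tolerance = 1e-10)
})

test_that("sensor ranking follows count, correlation, then loading", {
  mm <- sapply(paste0("S", 1:10), channelMeans)
  counts <- vapply(paste0("S", 1:10), function(ch)
    discriminationCount(enoseTab$letters[enoseTab$channel == ch]), 0L)
  # published correlations with the log count
  rLog <- c(S1 = 0.847, S2 = -0.906, S3 = 0.823, S4 = -0.883, S5 = 0.791,
            S6 = -0.875, S7 = -0.937, S8 = -0.806, S9 = -0.934, S10 = -0.142)
  pc1 <- setNames(enoseLoadings(mm)$loadings[, 1], paste0("S", 1:10))
  ranking <- rankSensors(counts, rLog, pc1)
  expect_identical(ranking[1], "S7")

  expect_identical(rankSensors(c(X = 3L), c(X = 0.5), c(X = 0.1)), "X")
  expect_error(rankSensors(counts, rLog[-1], pc1), "consistency")

  # generator-controlled ordering: highest count + |r| wins
  counts2 <- c(S1 = 5L, S2 = 5L, S3 = 9L)
  r2v <- c(S1 = 0.2, S2 = 0.9, S3 = 0.5)
  l2 <- c(S1 = 0.9, S2 = 0.1, S3 = 0.2)
  expect_identical(rankSensors(counts2, r2v, l2), c("S3", "S2", "S1"))
})
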