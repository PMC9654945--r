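# Shared fixtures and independent oracles used across the suite.

# fast option set for tests that fit many series
fastOpts <- fitOptions(nRestarts = 8L, seed = 1L)

gridHours <- seq(0, 168, by = 12)

# packaged reference tables, loaded once
enoseTab <- enoseSummaryTable()
pcTab <- pcScoresTable()
plateTab <- plateCountParamsTable()

s7Summary <- function() {
  g <- enoseTab[enoseTab$channel == "S7", ]
  g[order(g$time_h), ]
}

channelMeans <- function(channel) {
  g <- enoseTab[enoseTab$channel == channel, ]
  g$mean[order(g$time_h)]
}

tableParams <- function(model) {
  row <- plateTab[plateTab$model == model, ]
  growthParams(row$n0, row$nmax, row$mu_max_per_h, row$lag_h)
}

# brute-force SSE oracle: best point on an nGrid^4 lattice over bounds
gridSearchSSE <- function(kind, times, values, nGrid = 20L) {
  rng <- range(values)
  span <- diff(rng)
  grid <- list(
    n0 = seq(rng[1] - 0.5 * span, rng[2] + 0.5 * span, length.out = nGrid),
    nmax = seq(rng[1] - 0.5 * span, rng[2] + 0.5 * span, length.out = nGrid),
    mu = seq(1e-4, 1, length.out = nGrid),
    lag = seq(0, max(times), length.out = nGrid))
  f <- GrowthSense:::.curveFun(kind)
  best <- Inf
  for (a in grid$n0) for (b in grid$nmax) {
    if (a == b) next
    for (m in grid$mu) {
      # vectorize over lag for speed
      for (l in grid$lag) {
        v <- f(times, a, b, m, l)
        sse <- sum((values - v)^2)
        if (is.finite(sse) && sse < best) best <- sse
      }
    }
  }
  best
}

# classical one-way ANOVA on raw replicates, via stats::aov (oracle)
aovOracle <- function(valuesByGroup) {
  df <- data.frame(
    y = unlist(valuesByGroup),
    g = factor(rep(seq_along(valuesByGroup), lengths(valuesByGroup))))
  a <- summary(stats::aov(y ~ g, data = df))[[1]]
  list(f = a$`F value`[1], p = a$`Pr(>F)`[1], mse = a$`Mean Sq`[2],
       dfb = a$Df[1], dfw = a$Df[2])
}

randomParams <- function(increasing = TRUE) {
  n0 <- runif(1, 1, 6)
  span <- runif(1, 0.5, 4)
  nmax <- if (increasing) n0 + span else n0 - span
  growthParams(n0, nmax, runif(1, 0.01, 0.5), runif(1, 0, 120))
}
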