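test_that("preprocessEEG drops bad channels and re-references", {
  set.seed(61)
  x <- rnorm(6000)
  rec <- SignalRecord(cbind(x, x, rnorm(6000)), 1000,
                      c("EEG_ipsi", "EEG_contra", "other"))
  out <- preprocessEEG(selectChannels(rec, 1:2))
  # two identical channels cancel under common-average referencing
  expect_lt(max(abs(signalMatrix(out))), 1e-9)
  out3 <- preprocessEEG(rec)
  expect_equal(rowSums(signalMatrix(out3)), rep(0, 6000),
               tolerance = 1e-9)
  # excluding a channel re-references exactly as recomputing the mean
  keep <- preprocessEEG(rec, badChannels = 3)
  manual <- bandpassFilter(selectChannels(rec, 1:2), 5, 100, order = 6)
  mm <- signalMatrix(manual) - rowMeans(signalMatrix(manual))
  expect_equal(signalMatrix(keep), mm, ignore_attr = TRUE,
               tolerance = 1e-9)
  expect_error(preprocessEEG(rec, badChannels = 1:2), "at least two")
})

test_that("pooledCoherence matches a frozen reference implementation", {
  # fixture regenerated deterministically; expected values frozen from an
  # independent Welch coherence implementation (Hann 512, 75% overlap)
  set.seed(2024)
  n <- 8192
  x <- as.numeric(arima.sim(list(ar = 0.5), n))
  y <- 0.6 * x + rnorm(n)
  sp <- pooledCoherence(x, y, 1000)
  expected <- c(0.6898046876, 0.5608696041, 0.6794950478, 0.3091970426,
                0.4373640689, 0.1629505568)
  expect_equal(coherenceValues(sp)[c(5, 11, 21, 41, 81, 161)], expected,
               tolerance = 1e-8)
  expect_equal(frequencies(sp)[2], 1000 / 512)
})

test_that("pooledCoherence honours identity, scaling and epoch structure", {
  set.seed(62)
  x <- rnorm(4096)
  same <- pooledCoherence(x, x, 1000)
  expect_true(all(coherenceValues(same) > 1 - 1e-9))
  y <- x + rnorm(4096)
  a <- pooledCoherence(x, y, 1000)
  b <- pooledCoherence(5 * x, 0.02 * y, 1000)
  expect_equal(coherenceValues(a), coherenceValues(b), tolerance = 1e-9)
  # epochs are tiled separately: fewer segments than the concatenation
  eps <- list(x[1:2048], x[2049:4096])
  yps <- list(y[1:2048], y[2049:4096])
  two <- pooledCoherence(eps, yps, 1000)
  expect_lt(effectiveSegments(two), effectiveSegments(a))
  expect_error(pooledCoherence(eps, yps[1], 1000), "number of epochs")
  expect_error(pooledCoherence(eps, list(yps[[1]], yps[[2]][1:100]), 1000),
               "equal lengths")
  expect_error(pooledCoherence(rnorm(100), rnorm(100), 1000), "segment")
})

test_that("confidenceLevel follows the analytic formula", {
  expect_equal(confidenceLevel(2), 0.95)
  expect_equal(confidenceLevel(21), 1 - 0.05^(1 / 20))
  L <- c(2, 5, 20, 100, 1000)
  expect_true(all(diff(confidenceLevel(L)) < 0))
  expect_error(confidenceLevel(1), "exceed")
})

test_that("null coherence stays below the confidence limit ~95% of bins", {
  cov <- sapply(1:5, function(s) {
    set.seed(600 + s)
    sp <- pooledCoherence(rnorm(120000), rnorm(120000), 1000)
    f <- frequencies(sp)
    sel <- f >= 5 & f <= 100
    mean(coherenceValues(sp)[sel] < confidenceLimit(sp))
  })
  expect_gt(mean(cov), 0.93)
  expect_lt(mean(cov), 0.97)
})

test_that("zDifference standardizes the Fisher-scale change", {
  set.seed(63)
  x <- rnorm(20000)
  sp <- pooledCoherence(x, x + rnorm(20000), 1000)
  zd0 <- zDifference(sp, sp)
  expect_equal(zValues(zd0), rep(0, length(frequencies(sp))))
  # a bin with higher post coherence maps to positive z
  spLow <- pooledCoherence(rnorm(20000), rnorm(20000), 1000)
  zd <- zDifference(spLow, sp)
  expect_gt(mean(zValues(zd)), 0)
  # pooled denominator reduces to the single-L form at equal L
  zdLit <- zDifference(spLow, sp, method = "literal")
  expect_equal(zValues(zd), zValues(zdLit), tolerance = 1e-9)
  other <- pooledCoherence(rnorm(4096), rnorm(4096), 1000,
                           segmentSec = 0.256)
  expect_error(zDifference(other, sp), "frequency grid")
})

test_that("bandComposite applies Stouffer's rule and the 1.96 cutoff", {
  freqs <- (0:256) * 1000 / 512
  z <- numeric(257)
  sel <- which(freqs >= 12 & freqs <= 30)[1:4]
  z[sel] <- 1
  zd <- new("ZDiffSpectrum", frequencies = freqs, z = z, LPre = 50,
            LPost = 50, method = "pooled")
  bc <- bandComposite(zd, c(freqs[sel[1]], freqs[sel[4]]))
  expect_equal(bc$composite_z, 2)
  expect_true(bc$significant)
  zd0 <- new("ZDiffSpectrum", frequencies = freqs, z = numeric(257),
             LPre = 50, LPost = 50, method = "pooled")
  tab <- bandCompositeTable(zd0)
  expect_equal(tab$composite_z, rep(0, 3))
  expect_false(any(tab$significant))
  expect_equal(tab$band, c("alpha", "beta", "gamma"))
  expect_error(bandComposite(zd, c(600, 700)), "no frequency bin")
})

test_that("in-band coherence converges to the closed form with duration", {
  errAt <- function(dur, seed) {
    cfg <- synthConfig(duration = dur, drivePowerRatioEEG = 4,
                       drivePowerRatioEMG = 4, seed = seed)
    rec <- generateCoherentPair(cfg, carrier = FALSE)
    sp <- pooledCoherence(channelSamples(rec, "EEG_contra"),
                          channelSamples(rec, "ECR"), 1000)
    f <- frequencies(sp)
    abs(mean(coherenceValues(sp)[f >= 14 & f <= 28]) - 0.64)
  }
  eShort <- mean(vapply(1:3, function(s) errAt(20, s), numeric(1)))
  eLong <- mean(vapply(1:3, function(s) errAt(160, 100 + s), numeric(1)))
  expect_lt(eLong, eShort)
  expect_lt(eLong, 0.05)
})
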