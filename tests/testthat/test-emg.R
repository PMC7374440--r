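test_that("movingEnvelope equals the brute-force trailing mean", {
  set.seed(41)
  for (i in 1:25) {
    n <- sample(50:400, 1)
    fs <- sample(c(100, 250, 500), 1)
    win <- sample(3:20, 1)
    x <- rnorm(n) * sample(c(0.1, 1, 50), 1)
    env <- movingEnvelope(toyRecord(x, fs), "ECR", win / fs)
    expect_equal(envelopeValues(env), bruteMovingMean(x, win),
                 tolerance = 1e-12)
  }
})

test_that("movingEnvelope handles constants, rectification and resampling", {
  expect_equal(envelopeValues(
    movingEnvelope(toyRecord(rep(-3, 100), 100), "ECR", 0.1)),
    rep(3, 100))
  alt <- rep(c(1, -1), 50)
  expect_equal(envelopeValues(
    movingEnvelope(toyRecord(alt, 100), "ECR", 0.1)), rep(1, 100))
  # square pulse one window long: ramp up to 1, then decay
  x <- c(rep(0, 50), rep(1, 20), rep(0, 60))
  env <- envelopeValues(movingEnvelope(toyRecord(x, 100), "ECR", 0.2))
  expect_equal(max(env), 1)
  expect_equal(env, bruteMovingMean(x, 20), tolerance = 1e-12)
  # resampled output picks the trailing mean at output ticks
  set.seed(5)
  y <- rnorm(1000)
  env4 <- movingEnvelope(toyRecord(y, 1000), "ECR", 0.048, outputRate = 250)
  full <- bruteMovingMean(y, 48)
  expect_equal(envelopeValues(env4), full[round((1:250) * 4)],
               tolerance = 1e-12)
  expect_error(movingEnvelope(toyRecord(y, 1000), "ECR", 2), "longer")
  expect_error(movingEnvelope(toyRecord(y, 1000), "ECR", 0.1,
                              outputRate = 2000), "exceed")
})

test_that("bandpassFilter keeps the passband and attenuates per the design", {
  fs <- 1000
  t <- seq_len(8000) / fs
  mid <- sin(2 * pi * 100 * t)
  rec <- toyRecord(mid, fs)
  out <- channelSamples(bandpassFilter(rec, 15, 450, order = 4), "ECR")
  core <- 2000:6000
  expect_lt(abs(sd(out[core]) / sd(mid[core]) - 1), 0.01)
  # tone at twice the high corner of a narrower design: forward-backward
  # attenuation equals the squared analytic Butterworth magnitude,
  # evaluated at the bilinear pre-warped frequencies of the digital design
  tone <- sin(2 * pi * 200 * t)
  flt <- channelSamples(bandpassFilter(toyRecord(tone, fs), 10, 100,
                                       order = 4), "ECR")
  warp <- function(f) fs / pi * tan(pi * f / fs)
  expected <- butterBandpassGain(warp(200), warp(10), warp(100), 4)^2
  measured <- sd(flt[core]) / sd(tone[core])
  expect_lt(abs(measured / expected - 1), 0.05)
  expect_equal(channelSamples(bandpassFilter(toyRecord(rep(0, 1000), fs),
                                             15, 450), "ECR"),
               rep(0, 1000))
  expect_error(bandpassFilter(rec, 0, 100), "corner")
  expect_error(bandpassFilter(rec, 100, 600), "corner")
})

test_that("hilbertEnvelope recovers amplitudes and modulators", {
  fs <- 1000
  t <- seq_len(4000) / fs
  tone <- 2.5 * sin(2 * pi * 80 * t)
  env <- envelopeValues(hilbertEnvelope(toyRecord(tone, fs), "ECR"))
  core <- 500:3500
  expect_lt(max(abs(env[core] - 2.5)), 0.02 * 2.5)
  # slow AM modulator is recovered pointwise
  A <- 1 + 0.5 * sin(2 * pi * 2 * t)
  am <- A * sin(2 * pi * 100 * t)
  envAM <- envelopeValues(hilbertEnvelope(toyRecord(am, fs), "ECR"))
  expect_lt(max(abs(envAM[core] - A[core])), 0.03)
  expect_equal(envelopeValues(hilbertEnvelope(toyRecord(rep(0, 100), fs),
                                              "ECR")), rep(0, 100))
})

test_that("standardizeSeries gives zero mean, unit variance, idempotence", {
  set.seed(7)
  x <- rnorm(500, mean = 3, sd = 4)
  z <- standardizeSeries(x)
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(sd(z), 1, tolerance = 1e-12)
  expect_equal(standardizeSeries(z), z, tolerance = 1e-12)
  # affine invariance
  expect_equal(standardizeSeries(5 + 2 * x), z, tolerance = 1e-12)
  expect_error(standardizeSeries(rep(1, 10)), "constant")
})

test_that("normalizeToReference applies grip-max and session Z-scores", {
  ref <- normalizationReference("power_grip_max", c(ECR = 2))
  env <- new("EnvelopeSeries", values = c(0, 1, 2), outputRate = 250,
             windowLength = 0.48, sourceChannel = "ECR")
  expect_equal(envelopeValues(normalizeToReference(env, ref)),
               c(0, 0.5, 1))
  # scale equivariance: doubling signal and reference leaves output fixed
  ref2 <- normalizationReference("power_grip_max", c(ECR = 4))
  env2 <- new("EnvelopeSeries", values = 2 * c(0, 1, 2), outputRate = 250,
              windowLength = 0.48, sourceChannel = "ECR")
  expect_equal(envelopeValues(normalizeToReference(env2, ref2)),
               c(0, 0.5, 1))
  # session Z-score of the reference session itself is standard
  set.seed(21)
  amps <- rnorm(40, 5, 2)
  zref <- sessionZScoreReference(list(ECR = amps))
  z <- normalizeToReference(amps, zref, "ECR")
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(sd(z), 1, tolerance = 1e-12)
  refOther <- sessionZScoreReference(list(FCU = amps))
  expect_error(normalizeToReference(env, refOther), "no entry")
  expect_error(normalizationReference("power_grip_max", c(ECR = -1)),
               "positive")
})
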