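test_that("computeER follows the extensor-ratio definition", {
  expect_equal(computeER(0.4, 0.4), 0.5)
  expect_equal(computeER(0.3, 0), 1)
  expect_equal(computeER(0.3, 0.1), 0.75)
  expect_true(is.na(computeER(0.004, 0.004)))  # below the activity floor
  expect_equal(computeER(c(0.3, 0), c(0.1, 0)), c(0.75, NA))
  expect_error(computeER(-0.1, 0.2), "nonnegative")
})

test_that("evaluateTrial enforces contiguity of the 2 s criterion", {
  rate <- 250
  n <- 5 * rate
  er <- rep(1, n); ext <- rep(1, n)
  res <- evaluateTrial(er, ext, feedbackRate = rate, erThreshold = 0.5)
  expect_true(res$success)
  expect_equal(res$max_sustained, 5)
  # two 1.9 s runs split by one failing sample: no success
  meets <- rep(TRUE, n)
  meets[round(1.9 * rate) + 1] <- FALSE
  meets[(round(3.8 * rate) + 2):n] <- FALSE
  er2 <- ifelse(meets, 1, 0)
  res2 <- evaluateTrial(er2, ext, feedbackRate = rate, erThreshold = 0.5)
  expect_false(res2$success)
  expect_lt(res2$max_sustained, 2)
  # cumulative mode counts the total meeting time instead
  res3 <- evaluateTrial(er2, ext, feedbackRate = rate, erThreshold = 0.5,
                        contiguous = FALSE)
  expect_true(res3$success)
  # undefined ER never meets the criteria
  res4 <- evaluateTrial(rep(NA_real_, n), ext, feedbackRate = rate,
                        erThreshold = 0.3)
  expect_false(res4$success)
  expect_error(evaluateTrial(rep(1, 100), rep(1, 100), feedbackRate = rate,
                             erThreshold = 0.5), "shorter")
})

test_that("longest-run computation matches the brute-force oracle", {
  set.seed(33)
  for (i in 1:200) {
    b <- runif(sample(5:80, 1)) < runif(1)
    expect_identical(longestRun(b), bruteLongestRun(b))
  }
})

test_that("staircase moves in 0.3 steps within [0.3, 0.97]", {
  s <- staircaseState()
  expect_equal(s$threshold, 0.5)
  for (i in 1:3) s <- staircaseUpdate(s, TRUE)
  expect_equal(s$threshold, 0.8)
  expect_length(s$history, 0)
  for (i in 1:3) s <- staircaseUpdate(s, TRUE)
  expect_equal(s$threshold, 0.97)  # clipped from 1.1
  s2 <- staircaseState()
  for (i in 1:3) s2 <- staircaseUpdate(s2, FALSE)
  expect_equal(s2$threshold, 0.3)  # clipped from 0.2
  # mixed outcomes leave the threshold unchanged
  s3 <- staircaseState()
  for (o in c(TRUE, FALSE, TRUE, TRUE)) s3 <- staircaseUpdate(s3, o)
  expect_equal(s3$threshold, 0.5)
  # ... until three consecutive same outcomes accumulate
  s3 <- staircaseUpdate(s3, TRUE)  # history F T T T -> last three all TRUE
  expect_equal(s3$threshold, 0.8)
})

test_that("staircase threshold never leaves its bounds (property)", {
  set.seed(99)
  for (rep in 1:60) {
    s <- staircaseState()
    inBounds <- TRUE; clearedOnAdjust <- TRUE
    for (o in runif(100) < runif(1)) {
      prev <- s$threshold
      s <- staircaseUpdate(s, o)
      inBounds <- inBounds && s$threshold >= 0.3 - 1e-12 &&
        s$threshold <= 0.97 + 1e-12
      # the accumulated history resets whenever the threshold moves
      if (s$threshold != prev)
        clearedOnAdjust <- clearedOnAdjust && length(s$history) == 0
    }
    expect_true(inBounds)
    expect_true(clearedOnAdjust)
  }
})

test_that("runSession reproduces the perfect- and null-agent dynamics", {
  cfg <- synthConfig(activationLevel = 0.5, coactivationRatio = 0,
                     seed = 301)
  rec <- generateTrainingSession(cfg, agentSkill = 1, nBlocks = 1,
                                 nTrialsPerBlock = 9,
                                 baselineLevel = 0.004)
  res <- runSession(rec)
  expect_equal(nrow(res$trials), 9)
  expect_equal(res$summary$percent_success, 100)
  expect_equal(res$trials$er_threshold_used,
               c(0.5, 0.5, 0.5, 0.8, 0.8, 0.8, 0.97, 0.97, 0.97))
  # null agent: no activation, ER undefined, threshold floors at 0.3
  cfg0 <- synthConfig(activationLevel = 0, coactivationRatio = 0,
                      seed = 302)
  rec0 <- generateTrainingSession(cfg0, agentSkill = 1, nBlocks = 1,
                                  nTrialsPerBlock = 6)
  res0 <- runSession(rec0)
  expect_equal(res0$summary$percent_success, 0)
  expect_equal(res0$trials$er_threshold_used,
               c(0.5, 0.5, 0.5, 0.3, 0.3, 0.3))
})

test_that("success probability is non-increasing in the ER threshold", {
  set.seed(71)
  rate <- 250; n <- 5 * rate
  ext <- rep(1, n)
  rateOf <- function(thr) {
    mean(replicate(200, {
      # agent with trial-level ER variability around 0.6 plus fast jitter
      er <- pmin(1, pmax(0, rnorm(1, 0.6, 0.15) + rnorm(n, 0, 0.01)))
      evaluateTrial(er, ext, feedbackRate = rate,
                    erThreshold = thr)$success
    }))
  }
  rates <- vapply(c(0.3, 0.55, 0.8), rateOf, numeric(1))
  expect_true(all(diff(rates) <= 0))
  expect_gt(rates[1], rates[3])
})
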