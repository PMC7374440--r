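mkCursor <- function(v, rate = 1000) {
  new("EnvelopeSeries", values = v, outputRate = rate, windowLength = 1,
      sourceChannel = "ECR")
}

plateauAnn <- function(starts, dur = 4) {
  data.frame(kind = "hold_plateau", start = starts, end = starts + dur,
             trial_index = seq_along(starts))
}

test_that("holdTarget validates the 6 s trapezoid", {
  tg <- holdTarget()
  expect_equal(tg$plateauLevel, 0.15)
  expect_equal(tg$rampUp + tg$plateau + tg$rampDown, 6)
  expect_error(holdTarget(rampUp = 2), "span 6 s")
  expect_error(holdTarget(sweep = 3), "sweep")
})

test_that("holdError is the median |cursor - target| over the last 3 s", {
  tg <- holdTarget()
  cur <- mkCursor(rep(0.15, 10000))
  he <- holdError(cur, tg, plateauAnn(c(1, 6)))
  expect_equal(he$errors, c(0, 0))
  # deviations -1/0/+1 in equal thirds: |dev| = {1,0,1}, median 1
  dev <- rep(c(-1, 0, 1), each = 1000)
  cur2 <- mkCursor(c(rep(0.15, 1000), 0.15 + dev))
  he2 <- holdError(cur2, tg, plateauAnn(0.5, dur = 3.5))
  expect_equal(he2$errors, 1)
  expect_error(holdError(cur, tg, plateauAnn(1, dur = 2)), "analysis")
  # exact match with the direct definition on random cursors
  set.seed(11)
  v <- runif(10000)
  cr <- mkCursor(v)
  he3 <- holdError(cr, tg, plateauAnn(c(0.8, 5.2)))
  for (k in 1:2) {
    i1 <- floor((plateauAnn(c(0.8, 5.2))$end[k]) * 1000)
    i0 <- floor((plateauAnn(c(0.8, 5.2))$end[k] - 3) * 1000) + 1
    expect_equal(he3$errors[k], median(abs(v[i0:i1] - 0.15)))
  }
})

test_that("holdError is translation-consistent", {
  set.seed(12)
  v <- runif(9000, 0, 0.3)
  a <- holdError(mkCursor(v), holdTarget(), plateauAnn(c(1, 5)))
  b <- holdError(mkCursor(v + 0.2), holdTarget(plateauLevel = 0.35),
                 plateauAnn(c(1, 5)))
  expect_equal(a$errors, b$errors, tolerance = 1e-12)
})

test_that("generated holds give zero error without noise and scale with it", {
  cfg <- synthConfig(seed = 401)
  rec0 <- generateStaticHold(cfg, trackingNoise = 0, carrier = FALSE)
  he0 <- holdError(cursorSeries(rec0, "ECR"), holdTarget(),
                   annotations(rec0))
  expect_equal(he0$n_holds, 16)
  expect_equal(he0$errors, rep(0, 16))
  expect_equal(annotations(rec0)$end - annotations(rec0)$start, rep(4, 16))
  # carrier residue stays far below any plausible tracking error
  rec1 <- generateStaticHold(synthConfig(seed = 402), trackingNoise = 0)
  he1 <- holdError(cursorSeries(rec1, "ECR"), holdTarget(),
                   annotations(rec1))
  expect_lt(max(he1$errors), 0.005)
  # doubling the noise does not decrease the mean error
  e1 <- holdError(cursorSeries(
    generateStaticHold(synthConfig(seed = 403), trackingNoise = 0.01,
                       nHolds = 24), "ECR"),
    holdTarget(), plateauAnn((0:23) * 10 + 5))
  e2 <- holdError(cursorSeries(
    generateStaticHold(synthConfig(seed = 403), trackingNoise = 0.02,
                       nHolds = 24), "ECR"),
    holdTarget(), plateauAnn((0:23) * 10 + 5))
  expect_gte(mean(e2$errors), mean(e1$errors))
})

test_that("mean per-hold error tracks the half-normal median of the noise", {
  # oracle: brute-force expectation of median(|G|) over the analysis
  # window for slow Gaussian cursor noise of SD sigma, independently
  # simulated with plain R code
  sigma <- 0.02
  set.seed(55)
  oracle <- mean(replicate(300, {
    raw <- cumsum(rnorm(2000))
    raw <- raw - mean(raw)
    slow <- stats::filter(raw, rep(1 / 250, 250), sides = 1)
    slow <- slow[!is.na(slow)]
    g <- sigma * (slow - mean(slow)) / sd(slow)
    median(abs(g[sample(length(g) - 750, 1) + 1:750]))
  }))
  rec <- generateStaticHold(synthConfig(seed = 404),
                            trackingNoise = sigma, nHolds = 48)
  he <- holdError(cursorSeries(rec, "ECR"), holdTarget(),
                  annotations(rec))
  m <- mean(he$errors)
  # the population median of |N(0, sigma)| anchors the scale; the window
  # correlation of slow noise biases both pipeline and oracle upward
  expect_gt(m, 0.6745 * sigma * 0.6)
  expect_lt(m, 0.6745 * sigma * 1.6)
  expect_lt(abs(m - oracle) / oracle, 0.45)
})

test_that("compareSessions handles identical, shifted and random errors", {
  he <- function(e) structure(list(errors = e, n_holds = length(e),
                                   analysis_window = 3,
                                   plateau_level = 0.15),
                              class = "HoldError")
  e <- runif(16, 0, 0.05)
  same <- compareSessions(he(e), he(e))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  shift <- compareSessions(he(e), he(e - 0.01))
  expect_true(shift$degenerate)
  expect_true(is.na(shift$t))
  set.seed(77)
  a <- runif(16); b <- runif(16)
  cmp <- compareSessions(he(a), he(b))
  orc <- brutePairedT(a, b)
  expect_equal(cmp$t, orc$t, tolerance = 1e-10)
  expect_equal(cmp$p, orc$p, tolerance = 1e-10)
  expect_error(compareSessions(he(a), he(b[1:8])), "equal hold counts")
})
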