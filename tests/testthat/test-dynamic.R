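test_that("bleach correction is exact on constant and linear trends", {
  # constant trace: the polynomial fit is the constant, correction a no-op
  x <- rep(7.5, 400)
  expect_equal(correctBleaching(x), x)
  # linear decay: a degree-7 fit captures a line exactly
  t <- seq_len(600)
  lin <- 100 * (1 - 0.3 * (t - 1) / 599)
  corr <- correctBleaching(lin)
  expect_lt(max(abs(corr - 100)) / 100, 1e-8)
  expect_error(correctBleaching(rep(1, 8)), "too short")
})

test_that("bleach fit crossing zero is an error, not a silent blow-up", {
  t <- seq_len(300)
  dying <- pmax(100 - t, 0) - 60  # goes deeply negative
  expect_error(correctBleaching(dying), "zero")
})

test_that("planted dips survive bleach correction across half-lives", {
  proto <- stimulusProtocol(grayS = 4)
  pop <- generatePopulation(4, c(96, 96), fractionTuned = 1, seed = 51)
  recordingS <- proto@grayS + nTrials(proto) *
    (proto@gratingS + proto@grayS)
  for (mult in c(2, 5, 10)) {
    sim <- simulateDynamicTraces(pop, proto, responseAmplitude = 0.105,
                                 bleachHalfLifeS = mult * recordingS,
                                 noiseSd = 0)
    res <- analyzeDynamicRecording(sim$traces, proto, onsets = sim$onsets)
    expect_lt(max(abs(res$peak_amplitude - (-0.105)) / 0.105), 0.05)
  }
})

test_that("trial segmentation uses the documented rounding rule", {
  proto <- stimulusProtocol(grayS = 8, frameRate = 30)
  nFrames <- round((8 + 40 * 12) * 30)
  win <- segmentTrials(nFrames, proto)
  expect_equal(nrow(win), 40)
  # 0.66 s baseline at 30 Hz -> round(19.8) = 20 frames
  expect_equal(unique(win$base_end - win$base_start + 1L), 20L)
  # 4 s grating at 30 Hz -> 120 frames
  expect_equal(unique(win$resp_end - win$resp_start + 1L), 120L)
  expect_error(segmentTrials(1000, proto), "fit inside")
  # onset too early for a baseline: trial dropped with a warning
  expect_warning(
    short <- segmentTrials(nFrames, proto,
                           onsets = c(5L, win$resp_start[-1])),
    "dropped")
  expect_equal(nrow(short), 39)
})

test_that("lowest-quartile response statistic matches hand computation", {
  # window [10,9,8,7,10,10,10,10], k = round(0.25*8) = 2 -> mean{7,8} = 7.5
  trace <- c(rep(10, 20), 10, 9, 8, 7, 10, 10, 10, 10)
  win <- data.frame(trial = 1L, direction = 0L, base_start = 1L,
                    base_end = 20L, resp_start = 21L, resp_end = 28L)
  out <- computeResponses(trace, win)
  expect_equal(out$f_base, 10)
  expect_equal(out$f_resp, 7.5)
  expect_equal(out$dff, -0.25)
  # constant window: f_resp = f_base, dff = 0
  const <- computeResponses(rep(4, 28), win)
  expect_equal(const$dff, 0)
  # dff is invariant to a positive rescaling of the whole trace
  out2 <- computeResponses(trace * 37, win)
  expect_equal(out2$dff, out$dff)
})

test_that("the lowest-quartile statistic is negatively biased under noise", {
  # under pure iid noise E[f_resp] < f_base: estimator bias of the
  # order-statistic mean, asserted as a documented property
  set.seed(52)
  base <- 100
  dffs <- replicate(300, {
    w <- rnorm(120, base, 2)
    mean(sort(w)[1:30]) - base
  })
  expect_lt(mean(dffs), 0)
  expect_lt(mean(dffs) + 3 * sd(dffs) / sqrt(300), 0)
})

test_that("tuned-cell ANOVA gate matches hand-computed sums of squares", {
  resp <- data.frame(trial = 1:3, direction = 0L, f_base = c(1, 2, 3),
                     f_resp = c(4, 5, 6), dff = 0, valid = TRUE)
  out <- classifyTuned(resp)
  # SSB = 13.5, SSW = 4 on (1, 4) df -> F = 13.5, p ~ 0.0213
  expect_equal(out$p_tuned, pf(13.5, 1, 4, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(round(out$p_tuned, 4), 0.0213)
  expect_false(out$is_tuned)  # not significant at 0.01
  # identical base and response values: degenerate, not tuned
  same <- data.frame(trial = 1:5, direction = 0L, f_base = 2, f_resp = 2,
                     dff = 0, valid = TRUE)
  d <- classifyTuned(same)
  expect_true(d$degenerate)
  expect_false(d$is_tuned)
})

test_that("planted responsive cells pass the tuned gate under noise", {
  proto <- stimulusProtocol(grayS = 4)
  pop <- generatePopulation(5, c(96, 96), fractionTuned = 1, seed = 53)
  sim <- simulateDynamicTraces(pop, proto, responseAmplitude = 0.1,
                               bleachHalfLifeS = Inf, noiseSd = 0.01,
                               seed = 54)
  res <- analyzeDynamicRecording(sim$traces, proto, onsets = sim$onsets)
  expect_true(all(res$is_tuned))
})

test_that("oriented gate only runs on tuned cells and finds the plant", {
  proto <- stimulusProtocol(grayS = 4)
  pop <- generatePopulation(6, c(96, 96), fractionTuned = 1, seed = 55)
  sim <- simulateDynamicTraces(pop, proto, responseAmplitude = 0.2,
                               bleachHalfLifeS = Inf, noiseSd = 0.005,
                               seed = 56)
  res <- analyzeDynamicRecording(sim$traces, proto, onsets = sim$onsets)
  gt <- cells(pop)
  expect_true(all(res$is_oriented))
  expect_equal(res$preferred_direction, gt$preferred_direction)
  # untuned cell: oriented ANOVA skipped, is_oriented FALSE
  resp <- data.frame(trial = 1:40, direction = rep(0:7, 5),
                     f_base = 1, f_resp = 1, dff = 0, valid = TRUE)
  sk <- classifyOriented(resp, isTuned = FALSE)
  expect_false(sk$is_oriented)
  expect_true(is.na(sk$p_oriented))
  # identical responses across directions: degenerate, not oriented
  dg <- classifyOriented(resp, isTuned = TRUE)
  expect_false(dg$is_oriented)
})

test_that("is_oriented implies is_tuned on every cell of a noisy run", {
  sess <- simulateDynamicSession(seed = 57, nCells = 20,
                                 fractionTuned = 0.3,
                                 protocol = stimulusProtocol(grayS = 4))
  expect_true(all(!sess$tuning$is_oriented | sess$tuning$is_tuned))
})

test_that("population summary reports fractions, medians and the CDF", {
  tr <- data.frame(is_tuned = c(rep(TRUE, 2), rep(FALSE, 8)),
                   is_oriented = c(TRUE, rep(FALSE, 9)),
                   peak_amplitude = c(-0.2, -0.1, -0.05, rep(-0.02, 7)))
  s <- populationSummary(tr)
  expect_equal(s$fraction_tuned, 0.2)
  expect_equal(s$fraction_oriented, 0.1)
  expect_equal(s$median_peak_amplitude, median(tr$peak_amplitude))
  expect_equal(s$cdf(-0.2), 0.1)
  expect_error(populationSummary(tr[0, ]), "no cells")
})

test_that("tuned-gate size: nominal with plain means, inflated with lowest 25%", {
  # 2000 null cells (no stimulus effect, pure iid noise). With the
  # plain-mean diagnostic response statistic the two-group ANOVA holds its
  # nominal 0.01 size; with the lowest-quartile statistic the order-
  # statistic bias makes the rate far exceed nominal. Both are properties
  # of the method, asserted and documented.
  proto <- stimulusProtocol(grayS = 4)
  win <- data.frame(trial = 1:40, direction = rep(0:7, 5))
  step <- 140L
  win$base_start <- (win$trial - 1L) * step + 1L
  win$base_end <- win$base_start + 19L
  win$resp_start <- win$base_end + 1L
  win$resp_end <- win$resp_start + 119L
  set.seed(71)
  hits <- vapply(seq_len(2000), function(i) {
    trace <- rnorm(40L * step, 100, 2)
    rDiag <- computeResponses(trace, win, lowestFraction = 1)
    rLow <- computeResponses(trace, win, lowestFraction = 0.25)
    c(classifyTuned(rDiag)$is_tuned, classifyTuned(rLow)$is_tuned)
  }, logical(2))
  fprDiag <- mean(hits[1, ])
  fprLow <- mean(hits[2, ])
  expect_lt(abs(fprDiag - 0.01), 0.005)
  expect_gt(fprLow, 0.5)  # materially above nominal
})

test_that("planted tuned fraction is recovered with the unbiased estimator", {
  # the lowest-quartile statistic is anticonservative by construction, so
  # fraction recovery uses the plain-mean diagnostic mode (lowestFraction 1)
  proto <- stimulusProtocol(grayS = 4)
  pop <- generatePopulation(80, c(256, 256), fractionTuned = 0.125,
                            seed = 58)
  sim <- simulateDynamicTraces(pop, proto, responseAmplitude = 0.105,
                               bleachHalfLifeS = 2000, noiseSd = 0.02,
                               seed = 59)
  res <- analyzeDynamicRecording(sim$traces, proto, onsets = sim$onsets,
                                 lowestFraction = 1)
  frac <- mean(res$is_tuned)
  tol <- 2 * sqrt(0.125 * 0.875 / 80) + 0.01  # binomial error + FPR
  expect_lt(abs(frac - 0.125), tol)
})
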