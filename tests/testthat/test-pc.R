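test_that("bleed-through estimation: arithmetic, zeros, failure modes", {
  expect_equal(estimateBleedthrough(
    data.frame(green_dsub = 1000, red_dsub = 131)), 0.131)
  expect_equal(estimateBleedthrough(
    data.frame(green_dsub = c(500, 800), red_dsub = c(0, 0))), 0)
  expect_error(estimateBleedthrough(
    data.frame(green_dsub = c(-5, 0), red_dsub = c(1, 1))), "no cells")
  expect_error(estimateBleedthrough(
    data.frame(green_dsub = 100, red_dsub = 150)), "channel")
})

test_that("planted contamination is recovered from noisy pre-PC images", {
  pop <- generatePopulation(200, c(256, 256), seed = 31)
  opt <- opticsModel(bleed = c(0.131, 0.146), noiseScale = 2)
  st <- renderStack(pop, opt, 1040, power = 1, nFrames = 3, seed = 32)
  tab <- extractCellSignals(st, labelSynthetic(pop))
  beta <- estimateBleedthrough(tab)
  expect_lt(abs(beta - 0.146) / 0.146, 0.05)
})

test_that("RGR formula, exclusions and invariances", {
  # hand arithmetic: ((300-50) - 0.131*(1100-100)) / (1100-100) = 0.119
  tab <- data.frame(wavelength_nm = 1000, green_raw = 1100, red_raw = 300,
                    green_dsub = 1000, red_dsub = 250)
  expect_equal(computeRgr(tab, 0.131)$rgr, 0.119)
  # red at dark level with no bleed-through: rgr = 0
  tab0 <- data.frame(wavelength_nm = 1000, green_dsub = 900, red_dsub = 0)
  expect_equal(computeRgr(tab0, 0)$rgr, 0)
  # common linear gain on both channels leaves rgr unchanged
  for (c_ in c(0.5, 3, 17)) {
    scaled <- data.frame(wavelength_nm = 1000, green_dsub = 1000 * c_,
                         red_dsub = 250 * c_)
    expect_equal(computeRgr(scaled, 0.131)$rgr, 0.119)
  }
  # invalid cells (green at or below dark) excluded with a warning
  bad <- data.frame(wavelength_nm = 1000, green_dsub = c(1000, 0, -3),
                    red_dsub = c(250, 10, 10))
  expect_warning(out <- computeRgr(bad, 0.131), "excluded")
  expect_equal(nrow(out), 1L)
  # per-wavelength beta lookup
  two <- data.frame(wavelength_nm = c(1000, 1040),
                    green_dsub = c(1000, 1000), red_dsub = c(131, 146))
  r2 <- computeRgr(two, c("1000" = 0.131, "1040" = 0.146))
  expect_equal(r2$rgr, c(0, 0))
  expect_error(computeRgr(two, c("1000" = 0.131)), "1040")
})

test_that("pre-PC corrected red has zero expectation on synthetic data", {
  pop <- generatePopulation(200, c(256, 256), seed = 33)
  opt <- opticsModel(noiseScale = 2)
  st <- renderStack(pop, opt, 1000, 1, nFrames = 2, seed = 34)
  tab <- extractCellSignals(st, labelSynthetic(pop))
  rgr <- computeRgr(tab, 0.131)$rgr  # planted beta
  expect_lt(abs(mean(rgr)), 2 * sd(rgr) / sqrt(length(rgr)))
})

test_that("median pooling piles cells, not per-FOV medians", {
  expect_equal(poolMedianRgr(data.frame(rgr = c(0.1, 0.2, 0.3)))$median_rgr,
               0.2)
  # two FOVs {0.1} and {0.2, 0.3}: pooled median 0.2, mean of medians 0.175
  rec <- data.frame(fov = c(1, 2, 2), rgr = c(0.1, 0.2, 0.3))
  pooled <- poolMedianRgr(rec)$median_rgr
  perFov <- mean(tapply(rec$rgr, rec$fov, median))
  expect_equal(pooled, 0.2)
  expect_equal(perFov, 0.175)
  expect_false(isTRUE(all.equal(pooled, perFov)))
  # duplicating every record leaves the median unchanged
  expect_equal(poolMedianRgr(rbind(rec, rec))$median_rgr, 0.2)
  # grouped pooling keys
  g <- data.frame(mouse = c("a", "a", "b"), rgr = c(0.1, 0.3, 0.5))
  out <- poolMedianRgr(g, "mouse")
  expect_equal(out$median_rgr[out$mouse == "a"], 0.2)
  expect_equal(out$n_cells, c(2L, 1L))
})

test_that("light dose matches the illumination geometry", {
  # 200 mW, 40 x 1 s pulses over a 7-mm circle -> ~208 mJ/mm^2
  expect_equal(lightDose(200, 40, 1, 7), 200 * 40 / (pi * 3.5^2))
  expect_equal(lightDose(200, 40, 1, 7), 207.8758, tolerance = 1e-6)
  expect_equal(lightDose(100, 40, 1, 7), 103.9379, tolerance = 1e-6)
  expect_equal(lightDose(150, 0, 1, 7), 0)
  expect_error(lightDose(0, 40, 1, 7), "power")
  expect_error(lightDose(100, 40, 1, 0), "diameter")
})

test_that("cumulative dose is additive over the event log", {
  ev <- data.frame(power_mW = c(100, 200, 100), n_pulses = 40,
                   pulse_s = c(1, 1, 2), spot_mm = 7)
  out <- doseFromEvents(ev)
  expect_equal(out$cumulative_dose, cumsum(out$dose))
  # concatenated log equals the sum of per-event doses
  expect_equal(sum(out$dose),
               lightDose(100, 40, 1, 7) + lightDose(200, 40, 1, 7) +
                 lightDose(100, 40, 2, 7))
})

test_that("zero-intercept fit matches the closed form and edge cases", {
  # slope through (100, 0.079), (200, 0.158) is exactly 7.9e-4
  fit <- fitDoseResponse(c(100, 200), c(0.079, 0.158))
  expect_equal(fit@slope, 7.9e-4)
  # all responses zero: slope 0, p = 1
  z <- fitDoseResponse(c(50, 100, 150), c(0, 0, 0))
  expect_equal(z@slope, 0)
  expect_equal(z@pValue, 1)
  expect_error(fitDoseResponse(100, 0.1), ">= 2")
  expect_error(fitDoseResponse(c(-1, 2), c(0.1, 0.2)), "> 0")
  expect_warning(fitDoseResponse(c(100, 100), c(0.1, 0.12)), "identical")
})

test_that("zero-intercept slope equals sum(xy)/sum(x^2) on random cases", {
  set.seed(41)
  for (i in 1:100) {
    n <- sample(3:12, 1)
    x <- runif(n, 1, 300)
    y <- runif(n, -0.1, 0.5)
    fit <- fitDoseResponse(x, y)
    expect_equal(fit@slope, sum(x * y) / sum(x^2), tolerance = 1e-13)
    # independent cross-check: lm through the origin
    expect_equal(fit@slope, unname(coef(lm(y ~ x + 0))), tolerance = 1e-10)
    expect_true(fit@ci95[1] <= fit@slope && fit@slope <= fit@ci95[2])
  }
})

test_that("planted dose-response slope is recovered from noisy sessions", {
  pts <- NULL
  for (s in 1:6) {
    nEv <- 1 + (s %% 3)
    sess <- simulatePcSession(seed = 100 + s, nCells = 120,
                              eventDoses = rep(104, nEv),
                              conversion = conversionModel(1.6e-4, 0))
    pts <- rbind(pts, sess$points)
  }
  expect_gte(nrow(pts), 10)
  fit <- fitDoseResponse(pts$cumulative_dose, pts$median_rgr)
  expect_lt(abs(fit@slope - 1.6e-4) / 1.6e-4, 0.10)
})

test_that("dual-wavelength ratios pair recordings and drop orphans", {
  tab <- data.frame(recording = c(1, 1, 2, 2, 3),
                    wavelength_nm = c(1000, 1040, 1000, 1040, 1000),
                    median_rgr = c(0.100, 0.905, 0.2, 0.2, 0.5))
  expect_warning(out <- wavelengthRatio(tab), "unpaired")
  expect_equal(unname(out$ratios), c(9.05, 1))
  expect_equal(out$n, 2)
  expect_equal(out$mean, mean(c(9.05, 1)))
})

test_that("planted excitation-efficiency ratio is recovered end to end", {
  rows <- NULL
  for (s in 1:4) {
    sess <- simulatePcSession(seed = 200 + s, nCells = 100,
                              eventDoses = 104,
                              wavelengths = c(1000, 1040))
    rows <- rbind(rows, data.frame(recording = s,
                                   wavelength_nm = sess$points$wavelength_nm,
                                   median_rgr = sess$points$median_rgr))
  }
  out <- wavelengthRatio(rows)
  expect_lt(abs(out$mean - 9.05) / 9.05, 0.10)
})

test_that("green brightness normalises by power squared", {
  expect_equal(normalizedGreenBrightness(400, 2), 100)
  expect_equal(normalizedGreenBrightness(400, 1), 400)
  expect_error(normalizedGreenBrightness(400, 0), "power")
  # render oracle: doubling power leaves the normalised value fixed
  pop <- generatePopulation(10, c(128, 128), seed = 42)
  opt <- noiseFreeOptics()
  mask <- labelSynthetic(pop)
  val <- sapply(c(1, 2), function(p) {
    st <- renderStack(pop, opt, 1000, p, seed = 1)
    tab <- extractCellSignals(st, mask)
    normalizedGreenBrightness(median(tab$green_dsub), p)
  })
  expect_equal(val[1], val[2], tolerance = 1e-12)
})

test_that("sensitivity index: hand value, symmetry and invariances", {
  expect_equal(sensitivityIndex(c(2, 3, 4), c(0, 1, 2))$d_prime, 2)
  expect_equal(sensitivityIndex(c(1, 2, 3), c(1, 2, 3))$d_prime, 0)
  a <- rnorm(20, 1, 0.3); b <- rnorm(20, 0.4, 0.2)
  d <- sensitivityIndex(a, b)$d_prime
  expect_equal(sensitivityIndex(b, a)$d_prime, -d)
  expect_equal(sensitivityIndex(a + 5, b + 5)$d_prime, d)
  expect_equal(sensitivityIndex(a * 3, b * 3)$d_prime, d)
  expect_error(sensitivityIndex(c(1), c(1, 2)), ">= 2")
  expect_error(sensitivityIndex(c(1, 1), c(2, 2)), "undefined")
})

test_that("rank-sum p-values agree with exact null enumeration", {
  # canonical worked case: complete separation of 3 vs 3 -> p = 0.1
  expect_equal(compareGroups(c(1, 2, 3), c(10, 11, 12), "ranksum")$p_value,
               0.1)
  expect_equal(ranksumEnumP(c(1, 2, 3), c(10, 11, 12)), 0.1)
  set.seed(43)
  for (i in 1:20) {
    n1 <- sample(3:6, 1); n2 <- sample(3:8, 1)
    a <- round(runif(n1, 0, 50), 3); b <- round(runif(n2, 10, 60), 3)
    if (any(duplicated(c(a, b)))) next
    expect_equal(compareGroups(a, b, "ranksum")$p_value,
                 ranksumEnumP(a, b), tolerance = 1e-12)
  }
})

test_that("group comparison wrappers handle degenerate inputs", {
  # identical samples: maximal attainable rank-sum p
  p <- compareGroups(c(1, 2, 3), c(1, 2, 3), "ranksum")$p_value
  expect_gte(p, 0.95)
  expect_equal(compareGroups(c(1, 2, 9), c(1.5, 2.5, 3.5),
                             "t_two_sample")$degenerate, FALSE)
  expect_error(compareGroups(c(1, 2), c(1, 2, 3), "t_paired"), "equal")
  expect_warning(out <- compareGroups(c(1, 2, 3), c(1, 2, 3), "t_paired"),
                 "degenerate")
  expect_true(out$degenerate)
  expect_true(is.nan(out$p_value))
})

test_that("median RGR rises strictly with cumulative dose when noise is off", {
  sess <- simulatePcSession(seed = 44, nCells = 40,
                            eventDoses = c(50, 50, 100),
                            optics = noiseFreeOptics())
  expect_true(all(diff(sess$points$median_rgr) > 0))
})
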