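test_that("empirical pmf is a point mass at zero when mu = 0", {
  prof <- oneIntervalProfile(10, 1e4, 0)
  pmf <- empiricalPmf(prof, 0, 1, InferenceSettings(seed = 1, smoothing = 0))
  expect_equal(pmf$probs[1], 1)
  expect_equal(sum(pmf$probs[-1]), 0)
})

test_that("empirical pmf at d = 0 matches the analytic LD distribution", {
  prof <- oneIntervalProfile(10, 1e4, 0)
  mu <- 1 / (1e4 - 10)  # m = 1
  st <- InferenceSettings(seed = 2, simsPerRate = 1e5, smoothing = 0)
  pmf <- empiricalPmf(prof, mu, 1, st, K = 200)
  ld <- ldProbs(mssPmf(1, 200))
  tv <- 0.5 * (sum(abs(pmf$probs[1:201] - ld)) +
               abs(pmf$probs[202] - (1 - sum(ld))))
  expect_lt(tv, 0.03)
})

test_that("empirical pmf is stable across seeds at large sim counts", {
  prof <- oneIntervalProfile(10, 1e4, 0)
  mu <- 1 / (1e4 - 10)
  a <- empiricalPmf(prof, mu, 1, InferenceSettings(seed = 3, simsPerRate = 1e5,
                                                   smoothing = 0), K = 200)
  b <- empiricalPmf(prof, mu, 1, InferenceSettings(seed = 4, simsPerRate = 1e5,
                                                   smoothing = 0), K = 200)
  expect_lt(0.5 * sum(abs(a$probs - b$probs)), 0.02)
})

test_that("estimate is deterministic given data and seed", {
  prof <- oneIntervalProfile(100, 1e5, 0.5)
  ds <- simulateFluctuationAssay(prof, 1e-5, 24, 1, SimulationSettings(seed = 5))
  st <- InferenceSettings(seed = 6, simsPerRate = 1000)
  e1 <- suppressWarnings(estimateRate(ds, prof, st))
  e2 <- suppressWarnings(estimateRate(ds, prof, st))
  expect_identical(rateValue(e1), rateValue(e2))
  expect_identical(confInt(e1), confInt(e2))
})

test_that("deepening the assumed death rate lowers the corrected estimate", {
  base <- oneIntervalProfile(100, 1e5, 0)
  ds <- simulateFluctuationAssay(base, 1e-5, 24, 1, SimulationSettings(seed = 7))
  rates <- vapply(c(0, 0.5, 0.8), function(d) {
    prof <- oneIntervalProfile(100, 1e5, d)
    rateValue(suppressWarnings(
      estimateRate(ds, prof, InferenceSettings(seed = 8, simsPerRate = 2000))))
  }, numeric(1))
  expect_true(all(diff(rates) < 0))
})

test_that("all-zero counts land on the lower grid bound with a flag", {
  prof <- oneIntervalProfile(100, 1e5, 0)
  ds <- FluctuationDataset(rep(0, 24), finalSize = 1e5, initialSize = 100)
  grid <- 10^seq(-6, -2.9, length.out = 21)
  expect_warning(
    est <- estimateRate(ds, prof, InferenceSettings(rateGrid = grid, seed = 9,
                                                    simsPerRate = 1000)),
    "boundary")
  expect_equal(rateValue(est), grid[1])
  expect_true(est@details$boundary)
})

test_that("mHat scales the rate by the profile's total divisions", {
  prof <- oneIntervalProfile(100, 1e5, 0.5)
  ds <- simulateFluctuationAssay(prof, 1e-5, 24, 1, SimulationSettings(seed = 10))
  est <- suppressWarnings(
    estimateRate(ds, prof, InferenceSettings(seed = 11, simsPerRate = 1000)))
  expect_equal(mHat(est), rateValue(est) * totalDivisions(prof))
})

test_that("the wasserstein distance variant returns a sane estimate", {
  prof <- oneIntervalProfile(100, 1e5, 0)
  mu <- 1e-5
  ds <- simulateFluctuationAssay(prof, mu, 24, 1, SimulationSettings(seed = 12))
  est <- suppressWarnings(
    estimateRate(ds, prof, InferenceSettings(seed = 13, simsPerRate = 2000,
                                             distance = "wasserstein")))
  expect_gt(rateValue(est), mu / 5)
  expect_lt(rateValue(est), mu * 5)
})

test_that("fold change combines point estimates and intervals", {
  tr <- RateEstimate(6e-9, 4e-9, 9e-9, method = "corrected")
  un <- RateEstimate(1e-9, 0.8e-9, 1.5e-9, method = "corrected")
  fc <- foldChange(tr, un)
  expect_equal(fc$ratio, 6)
  expect_equal(fc$ciLow, 4e-9 / 1.5e-9)
  expect_equal(fc$ciHigh, 9e-9 / 0.8e-9)
  expect_equal(foldChange(un, un)$ratio, 1)
  uncor <- RateEstimate(1e-9, method = "uncorrected")
  expect_error(foldChange(tr, uncor), "same method")
  zero <- RateEstimate(0, 0, 0, method = "corrected")
  expect_error(foldChange(tr, zero), "zero")
})
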