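test_that("interval divisions follow deltaN / (1 - d)", {
  expect_equal(intervalDivisions(1, 2, 0.8), 5)   # one net cell, five divisions
  expect_equal(intervalDivisions(10, 1010, 0), 1000)
  expect_equal(intervalDivisions(200, 100, 2), 100) # decline still divides
  expect_equal(intervalDivisions(50, 50, 1), 0)
  expect_error(intervalDivisions(10, 20, 1), "d = 1")
  expect_error(intervalDivisions(10, 20, 2), "sign mismatch")
  expect_error(intervalDivisions(20, 10, 0.5), "sign mismatch")
})

test_that("totalDivisions sums hidden divisions across intervals", {
  prof <- GrowthProfile(c(0, 3, 6), c(100, 200, 150), c(0.5, 1.5))
  expect_equal(totalDivisions(prof), 100 / 0.5 + 50 / 0.5)
})

test_that("no mutation rate means no mutants, for both algorithms", {
  prof <- oneIntervalProfile(5, 50, 0.5)
  expect_equal(simulateCultures(prof, 0, 50, SimulationSettings(seed = 1)),
               rep(0, 50))
  expect_equal(gillespieCounts(prof, 0, 20, SimulationSettings(seed = 1))$mutants,
               rep(0, 20))
  expect_error(simulateCultures(prof, -1e-9, 5), ">= 0")
})

test_that("simulation is deterministic given the seed", {
  prof <- oneIntervalProfile(10, 1e4, 0.4)
  a <- simulateCultures(prof, 2e-4, 100, SimulationSettings(seed = 11))
  b <- simulateCultures(prof, 2e-4, 100, SimulationSettings(seed = 11))
  expect_identical(a, b)
  c <- simulateCultures(prof, 2e-4, 100, SimulationSettings(seed = 12))
  expect_false(identical(a, c))
})

test_that("oracle bookkeeping: divisions - deaths = deltaN, ratio matches d", {
  prof <- GrowthProfile(c(0, 24), c(20, 120), 0.8)
  g <- gillespieCounts(prof, 0.001, 200, SimulationSettings(seed = 3))
  expect_true(all(g$divisions - g$deaths == 100))
  expect_equal(unique(g$deaths / g$divisions), 0.8, tolerance = 1e-12)
  # d = 0: divisions equal the net increase exactly, no deaths
  g0 <- gillespieCounts(oneIntervalProfile(10, 200, 0), 0.001, 50,
                        SimulationSettings(seed = 4))
  expect_true(all(g0$divisions == 190) && all(g0$deaths == 0))
})

test_that("oracle guard rejects large populations", {
  expect_error(gillespieCounts(oneIntervalProfile(10, 1e6), 1e-6, 1), "guard")
})

test_that("hybrid and oracle agree in distribution across death regimes", {
  n <- 3e4
  for (cfg in list(list(sizes = c(5, 50), d = 0),
                   list(sizes = c(5, 50), d = 0.5),
                   list(sizes = c(20, 60), d = 0.9),
                   list(sizes = c(200, 100), d = 2))) {
    prof <- GrowthProfile(c(0, 10), cfg$sizes, cfg$d)
    h <- simulateCultures(prof, 0.01, n, SimulationSettings(seed = 5))
    o <- gillespieCounts(prof, 0.01, n, SimulationSettings(seed = 6))$mutants
    expect_lt(tvDistance(h, o), 0.02)
  }
})

test_that("binomial plating thinning behaves at its limits", {
  prof <- oneIntervalProfile(10, 1e4, 0)
  ds <- simulateFluctuationAssay(prof, 1e-4, 200, 1e-12,
                                 SimulationSettings(seed = 7))
  expect_equal(mutantCounts(ds), rep(0, 200))
  ds0 <- simulateFluctuationAssay(prof, 0, 50, 0.2, SimulationSettings(seed = 8))
  expect_equal(mutantCounts(ds0), rep(0, 50))
  expect_equal(finalSize(ds0), 1e4)
  expect_equal(platingFraction(ds0), 0.2)
})

test_that("MSS MLE recovers m from fully plated simulated assays", {
  prof <- oneIntervalProfile(10, 1e4, 0)
  m <- 2
  counts <- simulateCultures(prof, m / (1e4 - 10), 5000,
                             SimulationSettings(seed = 9))
  fit <- mleM(counts)
  expect_equal(fit$m, m, tolerance = 0.05)
})

test_that("the mutant-count distribution is invariant to interval bookkeeping", {
  # same endpoints and death rate, with or without an interior timepoint
  n <- 3e4
  one <- GrowthProfile(c(0, 24), c(10, 1e4), 0)
  two <- GrowthProfile(c(0, 7, 24), c(10, 100, 1e4), c(0, 0))
  mu <- 1 / (1e4 - 10)
  a <- simulateCultures(one, mu, n, SimulationSettings(seed = 10))
  b <- simulateCultures(two, mu, n, SimulationSettings(seed = 20))
  expect_lt(tvDistance(a, b), 0.02)
})

test_that("downscaling sizes while upscaling mu preserves the distribution", {
  n <- 1e5
  big <- oneIntervalProfile(100, 1e5, 0)
  small <- oneIntervalProfile(10, 1e4, 0)
  mu <- 1 / (1e5 - 100)
  a <- simulateCultures(big, mu, n, SimulationSettings(seed = 21))
  b <- simulateCultures(small, mu * (1e5 - 100) / (1e4 - 10), n,
                        SimulationSettings(seed = 22))
  expect_lt(tvDistance(a, b), 0.02)
  # the scale setting does the same bookkeeping internally
  c <- simulateCultures(big, mu, n, SimulationSettings(seed = 23, scale = 10))
  expect_lt(tvDistance(a, c), 0.02)
})

test_that("mean mutant yield matches the oracle under death", {
  prof <- GrowthProfile(c(0, 10), c(20, 100), 0.6)
  n <- 4e4
  h <- simulateCultures(prof, 0.005, n, SimulationSettings(seed = 24))
  o <- gillespieCounts(prof, 0.005, n, SimulationSettings(seed = 25))$mutants
  se <- sqrt(var(h) / n + var(o) / n)
  expect_lt(abs(mean(h) - mean(o)), 4 * se + 1e-9)
})
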