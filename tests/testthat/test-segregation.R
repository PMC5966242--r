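test_that("one exact halving over one generation gives sigma = -1, res = 0", {
  s <- SegregationSeries(c(0, 3), total = c(1e6, 2e6),
                         plasmidBearing = c(0.9e6, 0.45e6))
  p <- fitSegregationParameter(s)
  expect_equal(retentionSigma(p), -1)
  expect_equal(residualReplication(p), 0)
})

test_that("a flat plasmid fraction over growth is rejected as no signal", {
  s <- SegregationSeries(c(0, 3), c(1e6, 2e6), c(0.9e6, 1.8e6))
  expect_error(fitSegregationParameter(s), "no segregation signal")
  flat <- SegregationSeries(c(0, 3), c(1e6, 1e6 + 1), c(0.9e6, 0.9e6 + 0.9))
  expect_error(fitSegregationParameter(flat), "no segregation signal")
})

test_that("a non-growing series cannot anchor generations", {
  s <- SegregationSeries(c(0, 3), c(1e6, 1e6), c(0.9e6, 0.5e6))
  expect_error(fitSegregationParameter(s), "cannot anchor")
})

test_that("res is recovered exactly from a noise-free forward simulation", {
  # 10 generations at res = 0.2: F decays by (0.6)^10, N grows 2^10
  res <- 0.2
  gens <- 0:10
  s <- SegregationSeries(gens, total = 1e4 * 2^gens,
                         plasmidBearing = 1e4 * 2^gens * 0.95 * 0.6^gens)
  p <- fitSegregationParameter(s)
  expect_equal(retentionSigma(p), log2(0.6), tolerance = 1e-9)
  expect_equal(residualReplication(p), 0.2, tolerance = 1e-9)
})

test_that("generations follow the retention recursion and its edge cases", {
  p0 <- SegregationParameter(res = 0)
  expect_equal(generationsBetween(0.4, 0.1, p0), 2)   # two halvings
  expect_equal(generationsBetween(0.4, 0.4, p0), 0)
  p <- SegregationParameter(res = 0.2)
  expect_equal(generationsBetween(0.5, 0.5 * 0.6^3, p), 3, tolerance = 1e-12)
  expect_error(generationsBetween(0.1, 0.4, p0), "increased")
})

test_that("relative death rate reproduces hand-computed cases and the cap", {
  p <- SegregationParameter(res = 0)
  # g = 2, fourfold increase: every division visible
  expect_equal(relativeDeathRate(1e6, 4e6, 0.4, 0.1, p)$rate, 0)
  # g = 2, twofold increase: half the divisions hidden
  expect_equal(relativeDeathRate(1e6, 2e6, 0.4, 0.1, p)$rate, 0.5)
  # raw d of 7 truncates to the cap, raw value preserved
  # 1 - log2(ratio)/g = 7 with g = 2 needs log2(ratio) = -12
  r <- relativeDeathRate(2^12 * 1e3, 1e3, 0.4, 0.1, p)
  expect_equal(r$rate, 5)
  expect_equal(r$raw, 7)
  # negative raw d clamps to zero but is reported
  rn <- relativeDeathRate(1e3, 2^3 * 1e3, 0.4, 0.1, p)
  expect_equal(rn$rate, 0)
  expect_equal(rn$raw, -0.5)
  expect_error(relativeDeathRate(1e6, 2e6, 0.4, 0.4, p), "inconsistent")
})

test_that("profile inversion recovers a known death-rate sequence exactly", {
  res <- 0.15
  d <- c(0.3, 0.3, 1.5)
  sizes <- c(1e5, 1e6, 1e7, 5e6)
  s <- forwardSegregation(c(0, 3, 6, 24), sizes, d, res)
  prof <- profileFromSegregation(s, SegregationParameter(res))
  expect_equal(deathRates(prof), d, tolerance = 1e-6)
  expect_equal(popSizes(prof), sizes)
  expect_length(prof@metadata$clampedIntervals, 0)
})

test_that("self-consistency: untreated series inverts to zero death", {
  s <- forwardSegregation(c(0, 24), c(1e5, 1e8), 0, res = 0.1)
  p <- fitSegregationParameter(s)
  prof <- profileFromSegregation(s, p)
  expect_equal(deathRates(prof), 0, tolerance = 1e-9)
})

test_that("round trip holds across random res and death sequences", {
  set.seed(42)
  for (i in 1:25) {
    res <- runif(1, 0, 0.9)
    K <- sample(2:4, 1)
    d <- runif(K, 0, 2.5)
    d <- ifelse(abs(d - 1) < 0.05, 1.2, d)  # stay away from the degenerate d = 1
    sizes <- 1e5 * cumprod(c(1, ifelse(d < 1, runif(K, 1.5, 20), runif(K, 0.1, 0.8))))
    s <- forwardSegregation(seq(0, 3 * K, by = 3), sizes, d, res)
    prof <- profileFromSegregation(s, SegregationParameter(res))
    expect_equal(deathRates(prof), d, tolerance = 1e-6)
  }
})

test_that("faster marker decay means more generations and a larger d", {
  p <- SegregationParameter(res = 0.1)
  fFinals <- c(0.3, 0.2, 0.1, 0.05)
  g <- vapply(fFinals, function(ff) generationsBetween(0.5, ff, p), numeric(1))
  expect_true(all(diff(g) > 0))
  d <- vapply(fFinals, function(ff)
    relativeDeathRate(1e5, 4e5, 0.5, ff, p)$rate, numeric(1))
  expect_true(all(diff(d) >= 0))
})

test_that("d is invariant to rescaling all population sizes", {
  p <- SegregationParameter(res = 0.1)
  a <- relativeDeathRate(1e5, 3e5, 0.5, 0.05, p)$rate
  b <- relativeDeathRate(1e8, 3e8, 0.5, 0.05, p)$rate
  expect_equal(a, b, tolerance = 1e-12)
})

test_that("consensus profile averages replicates and reports spread", {
  res <- 0.1
  mk <- function(jit) {
    s <- forwardSegregation(c(0, 3, 6), c(1e5, 1e6, 1e7), c(0.4, 0.6), res)
    SegregationSeries(s@times, s@total, s@plasmidBearing * jit)
  }
  profs <- consensusProfile(list(mk(1), mk(1)), SegregationParameter(res))
  expect_equal(deathRates(profs), c(0.4, 0.6), tolerance = 1e-6)
  agg <- aggregateDeathRates(profs@metadata$replicates)
  expect_equal(agg$seDeathRate, c(0, 0), tolerance = 1e-9)
  expect_equal(agg$nReplicates, c(2, 2))
})
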