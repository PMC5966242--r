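test_that("observed evolvability rescales plate counts to whole cultures", {
  d <- FluctuationDataset(c(1, 3), finalSize = 1e9, platingFraction = 0.2)
  s <- observedEvolvability(d)
  expect_equal(perCultureMutants(s), c(5, 15))
  expect_equal(meanMutants(s), 10)
  z <- observedEvolvability(FluctuationDataset(rep(0, 5), 1e9))
  expect_equal(meanMutants(z), 0)
})

test_that("mutant supply matches the LD model at d = 0", {
  # the raw mean of a Luria-Delbruck sample is jackpot-dominated, so compare
  # the winsorised mean E[min(X, 100)] and the zero fraction instead
  prof <- oneIntervalProfile(10, 1e4, 0)
  m <- 1
  sim <- perCultureMutants(
    simulatedEvolvability(prof, m / (1e4 - 10), nSims = 2e4,
                          settings = SimulationSettings(seed = 1)))
  set.seed(2)
  ld <- rluria(2e4, m, kmax = 2e4)
  expect_equal(mean(pmin(sim, 100)), mean(pmin(ld, 100)), tolerance = 0.05)
  expect_equal(mean(sim == 0), exp(-1), tolerance = 0.02)
})

test_that("no-death counterfactual is distribution-identical on a d = 0 profile", {
  prof <- GrowthProfile(c(0, 6, 24), c(10, 500, 1e4), c(0, 0))
  mu <- 1e-4
  withD <- simulatedEvolvability(prof, mu, nSims = 1e4,
                                 settings = SimulationSettings(seed = 3))
  noD <- counterfactualNoDeath(prof, mu, nSims = 1e4,
                               settings = SimulationSettings(seed = 4))
  p <- wilcox.test(perCultureMutants(withD), perCultureMutants(noD),
                   exact = FALSE)$p.value
  expect_gt(p, 0.01)
})

test_that("turnover adds mutants: with-death exceeds no-death at d = 0.8", {
  prof <- oneIntervalProfile(100, 1e5, 0.8)
  mu <- 2e-6
  withD <- simulatedEvolvability(prof, mu, nSims = 4000,
                                 settings = SimulationSettings(seed = 5))
  noD <- counterfactualNoDeath(prof, mu, nSims = 4000,
                               settings = SimulationSettings(seed = 6))
  expect_gt(meanMutants(withD), meanMutants(noD))
  tc <- turnoverContribution(withD, noD, seed = 7)
  expect_gt(tc$ratio, 1)
  expect_gt(tc$ciLow, 1)
})

test_that("turnover contribution handles trivial and degenerate inputs", {
  s <- EvolvabilitySummary(c(10, 30, 20), source = "simulated_with_death")
  n <- EvolvabilitySummary(c(10, 30, 20), source = "simulated_no_death")
  expect_equal(turnoverContribution(s, n, seed = 1)$ratio, 1)
  q <- EvolvabilitySummary(c(40, 40), source = "simulated_with_death")
  r <- EvolvabilitySummary(c(10, 10), source = "simulated_no_death")
  expect_equal(turnoverContribution(q, r, seed = 1)$ratio, 4)
  zero <- EvolvabilitySummary(rep(0, 5), source = "simulated_no_death")
  expect_error(turnoverContribution(s, zero), "zero")
  expect_equal(meanMutants(simulatedEvolvability(
    oneIntervalProfile(), 0, nSims = 100,
    settings = SimulationSettings(seed = 2))), 0)
})

test_that("mutant supply is linear in mu and tracks total divisions", {
  prof <- oneIntervalProfile(100, 1e5, 0.5)
  mus <- c(1e-6, 2e-6, 4e-6, 8e-6)
  means <- vapply(seq_along(mus), function(i)
    meanMutants(simulatedEvolvability(prof, mus[i], nSims = 4000,
                                      settings = SimulationSettings(seed = 10 + i))),
    numeric(1))
  fit <- lm(means ~ mus)
  expect_gt(summary(fit)$r.squared, 0.99)
  # doubling divisions at fixed mu doubles expected supply (approximately)
  prof2 <- oneIntervalProfile(100, 1e5, 0.75)  # 4x the divisions of d = 0
  m1 <- meanMutants(simulatedEvolvability(oneIntervalProfile(100, 1e5, 0), 4e-6,
                                          nSims = 8000,
                                          settings = SimulationSettings(seed = 20)))
  m2 <- meanMutants(simulatedEvolvability(prof2, 1e-6, nSims = 8000,
                                          settings = SimulationSettings(seed = 21)))
  # mu x a with divisions / a leaves expected supply roughly invariant
  expect_equal(m2 / m1, 1, tolerance = 0.35)
})
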