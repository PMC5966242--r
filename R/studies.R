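# Packaged reproducible simulation studies: the overestimation study (how
# badly the classic estimator inflates the rate as death deepens) and the
# corrected-vs-uncorrected comparison on synthetic fixtures with known ground
# truth. Desk-scale defaults (final size 1e5, mu 1e-5) keep m near 1, as in
# typical assays, while running in seconds; the full experimental scale
# (1e9, 1e-9) is available through the arguments.

#' Overestimation of the classic estimator under death
#'
#' For each relative death rate d, simulates `nSim` fluctuation assays of
#' `cultures` parallel cultures growing through a single-interval profile at
#' constant d (known true mutation rate `mu`), estimates each assay with the
#' classic death-free MLE, and summarises the ratio of estimate to truth.
#' With no death the ratio should centre on 1; with death it inflates roughly
#' like 1/(1 - d), since that is the factor by which divisions are
#' underestimated.
#'
#' @param deathRates death rates to profile, each in `[0, 0.95]`.
#' @param nSim assays per death rate (default 200).
#' @param cultures parallel cultures per assay (default 24).
#' @param mu true mutation rate per division (default 1e-5, desk scale).
#' @param finalSize final population per culture (default 1e5, desk scale).
#' @param initialSize inoculum (default 100).
#' @param platingFraction plating fraction (default 1).
#' @param seed RNG seed; the study is bit-reproducible given the seed.
#' @return data.frame, one row per death rate: ratio quantiles (5%, 25%,
#'   median, 75%, 95%) and the true expected mutational events m.
#' @export
runOverestimationStudy <- function(deathRates = c(0, 0.2, 0.4, 0.6, 0.8),
                                   nSim = 200, cultures = 24, mu = 1e-5,
                                   finalSize = 1e5, initialSize = 100,
                                   platingFraction = 1, seed = 1) {
  stopifnot(all(deathRates >= 0), all(deathRates <= 0.95))
  rows <- lapply(seq_along(deathRates), function(j) {
    d <- deathRates[j]
    profile <- GrowthProfile(c(0, 24), c(initialSize, finalSize), d)
    counts <- simulateCultures(profile, mu, nSim * cultures,
                               SimulationSettings(seed = .subSeed(seed, j)))
    counts <- .withSeed(.subSeed(seed, 1000L + j),
                        .thinCounts(counts, platingFraction))
    assay <- rep(seq_len(nSim), each = cultures)
    ratios <- vapply(seq_len(nSim), function(a) {
      ds <- FluctuationDataset(counts[assay == a],
                               finalSize = finalSize * platingFraction,
                               initialSize = min(initialSize, finalSize * platingFraction / 2),
                               platingFraction = 1)
      rateValue(uncorrectedRate(ds)) / mu
    }, numeric(1))
    q <- quantile(ratios, c(0.05, 0.25, 0.5, 0.75, 0.95), names = FALSE)
    data.frame(deathRate = d, trueM = mu * (finalSize - initialSize) / (1 - d),
               q05 = q[1], q25 = q[2], median = q[3], q75 = q[4], q95 = q[5])
  })
  do.call(rbind, rows)
}

#' Corrected-vs-uncorrected comparison on a synthetic fixture
#'
#' Runs the full pipeline on one synthetic treatment regime with known ground
#' truth: fit the retention parameter on the untreated fixture, invert the
#' treated segregation series into a death-rate profile, estimate the
#' mutation rate with the classic (naive, death-free) estimator and with the
#' simulation-based corrected estimator, and report both together with their
#' fold change versus an untreated assay.
#'
#' @param fixtureName one of `"norfloxacin_like"`, `"h2o2_like"`,
#'   `"kanamycin_like"`, `"untreated"`.
#' @param seed RNG seed for fixture generation and inference.
#' @param simsPerRate simulated cultures per candidate rate (default 5000).
#' @return list with elements `fixture` (the generated fixture), `profile`
#'   (the estimated [GrowthProfile-class]), `uncorrected` and `corrected`
#'   [RateEstimate-class]s, `trueMu`, and `foldChange` (corrected and
#'   uncorrected fold changes versus untreated).
#' @export
runCorrectionComparison <- function(fixtureName, seed = 1, simsPerRate = 5000) {
  untr <- makeFixture("untreated", seed = .subSeed(seed, 1L))
  param <- fitSegregationParameter(untr$segregation)
  runOne <- function(fx) {
    prof <- consensusProfile(fx$segregation, param)
    unc <- uncorrectedRate(asFullyPlated(fx$dataset))
    corr <- estimateRate(fx$dataset, prof,
                         InferenceSettings(simsPerRate = simsPerRate,
                                           seed = .subSeed(seed, 5L)))
    list(profile = prof, uncorrected = unc, corrected = corr)
  }
  untreatedRun <- runOne(untr)
  if (fixtureName == "untreated") {
    fx <- untr; run <- untreatedRun
  } else {
    fx <- makeFixture(fixtureName, seed = .subSeed(seed, 2L))
    run <- runOne(fx)
  }
  list(fixture = fx, profile = run$profile,
       uncorrected = run$uncorrected, corrected = run$corrected,
       trueMu = fx$trueMu,
       foldChange = list(
         corrected = foldChange(run$corrected, untreatedRun$corrected),
         uncorrected = foldChange(run$uncorrected, untreatedRun$uncorrected)))
}
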