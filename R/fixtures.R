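# Synthetic-fixture generator emulating the experimental regimes: paired
# plasmid-segregation time series (with plate-count sampling noise) and
# fluctuation-assay mutant counts, generated on the experimental 0/3/6/24 h
# sampling grid with ground truth bundled so every downstream test is
# closed-loop.
#
# Regimes:
#   untreated        no death, sizes strictly increasing (anchors the
#                    retention-parameter fit)
#   norfloxacin_like persistent substantial death in all phases of growth and
#                    a strongly reduced final size
#   h2o2_like        death only once the culture reaches stationary phase;
#                    final size unaffected
#   kanamycin_like   early decline (d > 1) then recovery with continued
#                    death, final size close to untreated

.FIXTURE_REGIMES <- list(
  untreated = list(
    sizes = c(5e5, 1e7, 2e8, 2e9), d = c(0, 0, 0), mu = 1e-9),
  norfloxacin_like = list(
    sizes = c(5e5, 2e6, 1e7, 5e7), d = c(0.5, 0.6, 0.7), mu = 6e-9),
  h2o2_like = list(
    sizes = c(5e5, 1e7, 1.5e9, 2e9), d = c(0, 0, 0.9), mu = 2e-9),
  kanamycin_like = list(
    sizes = c(5e5, 1e5, 5e4, 1e9), d = c(2.5, 2, 0.3), mu = 1e-9))

.FIXTURE_TIMES <- c(0, 3, 6, 24)

# One plate: Poisson colony count at a dilution auto-chosen to target
# `target` colonies (never plating more than the whole culture). Returns the
# estimated cell count.
.plateEstimate <- function(cells, target = 300) {
  dil <- min(target / cells, 1)
  max(rpois(1, cells * dil), 1) / dil
}

#' Generate a synthetic treatment fixture with known ground truth
#'
#' Builds, for one treatment regime, (i) the true [GrowthProfile-class] on the
#' 0/3/6/24 h grid, (ii) replicate plasmid-segregation series obtained by
#' running the retention recursion F_g = F_0 ((1+res)/2)^g along the true
#' dynamics and adding per-plate Poisson sampling noise (dilutions chosen to
#' target a few hundred colonies per plate), and (iii) a fluctuation dataset
#' simulated under the true profile at the regime's true mutation rate with
#' binomial plating thinning. Deterministic given `seed`.
#'
#' @param regime `"untreated"`, `"norfloxacin_like"`, `"h2o2_like"` or
#'   `"kanamycin_like"`.
#' @param seed RNG seed.
#' @param nCultures parallel cultures in the fluctuation dataset (default 24).
#' @param nSegReplicates replicate segregation series (default 4).
#' @param platingFraction selective-plate fraction (default 0.2: 200 uL of a
#'   1 mL culture).
#' @param res true residual plasmid replication rate (default 0.1).
#' @param trueMu override the regime's true mutation rate per division.
#' @param f0 plasmid-bearing fraction at time zero (default 0.99).
#' @param targetColonies expected colonies per segregation plate (default 300).
#' @return list with `regime`, `trueProfile`, `trueMu`, `trueRes`, `trueF`
#'   (noise-free fractions), `segregation` (list of noisy
#'   [SegregationSeries-class]), and `dataset` ([FluctuationDataset-class]).
#' @export
makeFixture <- function(regime = c("untreated", "norfloxacin_like",
                                   "h2o2_like", "kanamycin_like"),
                        seed = 1, nCultures = 24, nSegReplicates = 4,
                        platingFraction = 0.2, res = 0.1, trueMu = NULL,
                        f0 = 0.99, targetColonies = 300) {
  regime <- match.arg(regime)
  spec <- .FIXTURE_REGIMES[[regime]]
  if (is.null(trueMu)) trueMu <- spec$mu
  profile <- GrowthProfile(.FIXTURE_TIMES, spec$sizes, spec$d)
  sigma <- log2((1 + res) / 2)
  g <- log2(spec$sizes[-1] / spec$sizes[-length(spec$sizes)]) / (1 - spec$d)
  trueF <- f0 * 2^(sigma * cumsum(c(0, g)))
  .withSeed(seed, {
    segregation <- lapply(seq_len(nSegReplicates), function(r) {
      nHat <- vapply(spec$sizes, .plateEstimate, numeric(1),
                     target = targetColonies)
      pHat <- vapply(spec$sizes * trueF, .plateEstimate, numeric(1),
                     target = targetColonies)
      pHat <- pmin(pHat, nHat * 0.9999)
      SegregationSeries(.FIXTURE_TIMES, nHat, pHat)
    })
    dataset <- simulateFluctuationAssay(profile, trueMu, nCultures,
                                        platingFraction)
    list(regime = regime, trueProfile = profile, trueMu = trueMu,
         trueRes = res, trueF = trueF, segregation = segregation,
         dataset = dataset)
  })
}
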