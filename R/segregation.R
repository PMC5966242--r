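# Plasmid-segregation algebra: converting marker-loss and CFU data into
# generations elapsed and relative death rates.
#
# Once plasmid replication is switched off, the plasmid-bearing fraction F
# decays per generation g as F_g = F_0 * ((1 + res)/2)^g, where res is the
# residual replication rate of the plasmid relative to cell division. On a
# log2 scale the decay factor is sigma = log2((1 + res)/2). In an untreated
# culture death is assumed absent, so g equals log2 of the fold-growth in
# total count, which anchors the fit of sigma. In a treated culture, g
# measured from F and the observed net growth together give the relative
# death rate d = 1 - log2(Nfinal/Ninitial)/g.

#' Fit the plasmid-retention parameter from untreated segregation series
#'
#' Fits the per-generation log2 retention factor sigma = log2((1 + res)/2) by
#' least squares of y = log2(F_t/F_0) on x = log2(N_t/N_0) with the intercept
#' fixed at zero (i.e. anchored at the first timepoint), pooling all
#' timepoints of all supplied untreated replicate series jointly. Untreated
#' cultures are assumed death-free, so x is the generation count.
#'
#' @param untreated a `SegregationSeries` or a list of them (replicates).
#' @param minColonies intervals whose implied plate counts fall below this are
#'   flagged low-confidence in the diagnostics (default 10).
#' @return a [SegregationParameter-class] with fit diagnostics.
#' @examples
#' s <- SegregationSeries(c(0, 3), total = c(1e6, 2e6),
#'                        plasmidBearing = c(0.9e6, 0.9e6))
#' fitSegregationParameter(s)  # one generation, exact halving: res = 0
#' @export
fitSegregationParameter <- function(untreated, minColonies = 10) {
  if (is(untreated, "SegregationSeries")) untreated <- list(untreated)
  stopifnot(length(untreated) >= 1,
            all(vapply(untreated, is, logical(1), "SegregationSeries")))
  x <- y <- numeric(0)
  for (s in untreated) {
    if (length(s@times) < 2 || any(diff(s@total) <= 0))
      .stopf("cannot anchor generations without growth")
    F <- plasmidFraction(s)
    x <- c(x, log2(s@total[-1] / s@total[1]))
    y <- c(y, log2(F[-1] / F[1]))
  }
  if (all(y >= 0)) .stopf("no segregation signal")
  sigma <- sum(x * y) / sum(x * x)
  if (sigma >= 0) .stopf("no segregation signal")
  clamped <- FALSE
  if (sigma < -1) { sigma <- -1; clamped <- TRUE }
  res <- min(max(2^(sigma + 1) - 1, 0), 1 - 1e-12)
  fitted <- sigma * x
  lowConf <- any(vapply(untreated, function(s)
    any(s@plasmidBearing < minColonies), logical(1)))
  SegregationParameter(res, diagnostics = list(
    nPoints = length(x), rss = sum((y - fitted)^2), clamped = clamped,
    lowConfidence = lowConf))
}

#' Generations elapsed between two plasmid-bearing fractions
#'
#' Inverts the retention recursion: g = log2(F_final/F_initial) / sigma.
#'
#' @param fInitial,fFinal plasmid-bearing fractions in (0, 1], with
#'   `fFinal <= fInitial` (the fraction can only decay).
#' @param param a fitted [SegregationParameter-class].
#' @return generation count g >= 0 (dimensionless); 0 iff the fraction is
#'   unchanged.
#' @examples
#' p <- SegregationParameter(res = 0)
#' generationsBetween(0.4, 0.1, p)  # two halvings -> 2 generations
#' @export
generationsBetween <- function(fInitial, fFinal, param) {
  stopifnot(is(param, "SegregationParameter"))
  if (fInitial <= 0 || fInitial > 1 || fFinal <= 0)
    .stopf("plasmid fractions must lie in (0, 1]")
  if (fFinal > fInitial)
    .stopf("plasmid fraction increased")
  log2(fFinal / fInitial) / param@sigma
}

#' Relative death rate over one interval
#'
#' Computes d = 1 - log2(N_final/N_initial)/g, with g inferred from the
#' plasmid-bearing fractions via [generationsBetween()]. The returned rate is
#' clamped to `[0, cap]` (negative raw values indicate measurement noise; the
#' cap mirrors the convention of truncating extreme rates at 5); the raw
#' unclamped value is reported alongside for diagnostics.
#'
#' @param nInitial,nFinal total viable counts (cells) bounding the interval.
#' @param fInitial,fFinal plasmid-bearing fractions bounding the interval.
#' @param param a fitted [SegregationParameter-class].
#' @param cap upper truncation for the reported rate (default 5).
#' @return list with elements `rate` (clamped) and `raw`, plus `generations`.
#' @examples
#' p <- SegregationParameter(res = 0)
#' # two generations, only a twofold net increase: half the divisions hidden
#' relativeDeathRate(1e6, 2e6, 0.4, 0.1, p)$rate  # 0.5
#' @export
relativeDeathRate <- function(nInitial, nFinal, fInitial, fFinal, param, cap = 5) {
  stopifnot(nInitial > 0, nFinal > 0, cap > 0)
  g <- generationsBetween(fInitial, fFinal, param)
  if (g == 0) {
    if (nFinal != nInitial) .stopf("divisions inconsistent with size change")
    return(list(rate = 0, raw = 0, generations = 0))
  }
  raw <- 1 - log2(nFinal / nInitial) / g
  list(rate = max(0, min(cap, raw)), raw = raw, generations = g)
}

#' Assemble a GrowthProfile from a treated segregation series
#'
#' Applies [relativeDeathRate()] to every interval of `series`, producing the
#' per-interval (population size, relative death rate) representation used by
#' the simulator and estimator. Where clamping to `[0, cap]` would break sign
#' consistency with the observed size change (noise pushing a growing interval
#' to d >= 1, or a declining one to d <= 1), the rate is nudged to the nearest
#' consistent value and the interval flagged in `metadata$clampedIntervals`.
#'
#' @param series a `SegregationSeries` for the treated condition.
#' @param param a fitted [SegregationParameter-class].
#' @param cap upper truncation for death rates (default 5).
#' @return a [GrowthProfile-class]; `metadata` carries per-interval
#'   diagnostics (`generations`, `rawDeathRates`, `clampedIntervals`).
#' @export
profileFromSegregation <- function(series, param, cap = 5) {
  stopifnot(is(series, "SegregationSeries"), is(param, "SegregationParameter"))
  F <- plasmidFraction(series)
  N <- series@total
  K <- length(N) - 1
  d <- raw <- g <- numeric(K)
  clampedIv <- logical(K)
  for (k in seq_len(K)) {
    r <- relativeDeathRate(N[k], N[k + 1], F[k], F[k + 1], param, cap = cap)
    d[k] <- r$rate; raw[k] <- r$raw; g[k] <- r$generations
    dN <- N[k + 1] - N[k]
    if (dN > 0 && d[k] >= 1) { d[k] <- 1 - 1e-6; clampedIv[k] <- TRUE }
    if (dN < 0 && d[k] <= 1) { d[k] <- 1 + 1e-6; clampedIv[k] <- TRUE }
    if (dN == 0 && abs(d[k] - 1) < .EPS_D1) d[k] <- 1
    if (abs(raw[k] - d[k]) > 1e-12) clampedIv[k] <- TRUE
  }
  GrowthProfile(series@times, N, d, metadata = list(
    generations = g, rawDeathRates = raw,
    clampedIntervals = which(clampedIv)))
}

#' Consensus profile from replicate segregation series
#'
#' Inverts each replicate series into a death-rate profile via
#' [profileFromSegregation()], then combines them on the shared time grid:
#' geometric-mean population sizes and equal-weight mean death rates, with
#' rates re-clamped where averaging breaks sign consistency with the averaged
#' sizes.
#'
#' @param seriesList list of replicate `SegregationSeries` on one time grid.
#' @param param a fitted [SegregationParameter-class].
#' @param cap upper truncation for death rates (default 5).
#' @return a [GrowthProfile-class]; `metadata$replicates` keeps the
#'   per-replicate profiles and `metadata$seDeathRates` the standard errors.
#' @export
consensusProfile <- function(seriesList, param, cap = 5) {
  if (is(seriesList, "SegregationSeries")) seriesList <- list(seriesList)
  profs <- lapply(seriesList, profileFromSegregation, param = param, cap = cap)
  if (length(profs) == 1) return(profs[[1]])
  agg <- aggregateDeathRates(profs)
  sizes <- exp(colMeans(log(do.call(rbind, lapply(profs, popSizes)))))
  d <- agg$meanDeathRate
  dN <- diff(sizes)
  d[dN > 0 & d >= 1] <- 1 - 1e-6
  d[dN < 0 & d <= 1] <- 1 + 1e-6
  GrowthProfile(profs[[1]]@times, sizes, d, metadata = list(
    replicates = profs, seDeathRates = agg$seDeathRate))
}

#' Average death-rate profiles across biological replicates
#'
#' Equal-weight mean of per-interval death rates across replicate profiles on
#' a shared time grid, with the standard error of the mean across replicates.
#'
#' @param profiles list of [GrowthProfile-class] objects on identical time grids.
#' @return data.frame with one row per interval: `intervalStart`,
#'   `intervalEnd`, `meanDeathRate`, `seDeathRate`, `nReplicates`.
#' @export
aggregateDeathRates <- function(profiles) {
  stopifnot(length(profiles) >= 1,
            all(vapply(profiles, is, logical(1), "GrowthProfile")))
  t0 <- profiles[[1]]@times
  if (!all(vapply(profiles, function(p) isTRUE(all.equal(p@times, t0)), logical(1))))
    .stopf("profiles must share one time grid")
  D <- do.call(rbind, lapply(profiles, deathRates))
  data.frame(
    intervalStart = t0[-length(t0)], intervalEnd = t0[-1],
    meanDeathRate = colMeans(D),
    seDeathRate = apply(D, 2, sd) / sqrt(nrow(D)),
    nReplicates = nrow(D))
}
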