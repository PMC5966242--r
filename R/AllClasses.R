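#' @useDynLib deathFluct, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
#' @importFrom stats optimize uniroot runif rbinom rpois rnbinom quantile
#'   median wilcox.test t.test sd qnorm
#' @importFrom utils read.csv write.csv
NULL

.EPS_D1 <- 1e-9   # tolerance for treating a relative death rate as exactly 1

#' GrowthProfile: piecewise population dynamics of one culture condition
#'
#' A `GrowthProfile` stores the representation used throughout the package for
#' the population dynamics of a growing (possibly dying) bacterial culture: an
#' ordered vector of timepoints, the population size at each timepoint, and one
#' relative death rate per interval between successive timepoints. The
#' relative death rate d is the average number of death events per division
#' event over the interval (dimensionless); d < 1 means net growth, d > 1 net
#' decline, and d = 1 is only consistent with an unchanged population size.
#'
#' @slot times numeric, strictly increasing timepoints (hours).
#' @slot sizes numeric, population size (cells) at each timepoint; all > 0.
#' @slot deathRates numeric, relative death rate per interval; length
#'   `length(times) - 1`, all >= 0.
#' @slot initialSize numeric(1), inoculum size (cells); defaults to `sizes[1]`.
#' @slot metadata list, free-form diagnostics (e.g. raw uncapped death rates).
#'
#' @seealso [profileFromSegregation()], [simulateCulture()], [intervalDivisions()]
#' @export
setClass("GrowthProfile",
  representation(times = "numeric", sizes = "numeric", deathRates = "numeric",
                 initialSize = "numeric", metadata = "list"))

setValidity("GrowthProfile", function(object) {
  msg <- character()
  nT <- length(object@times)
  if (nT < 2) msg <- c(msg, "need at least two timepoints")
  if (any(diff(object@times) <= 0)) msg <- c(msg, "times must be strictly increasing")
  if (length(object@sizes) != nT) msg <- c(msg, "sizes must match times in length")
  if (any(object@sizes <= 0)) msg <- c(msg, "all sizes must be > 0")
  if (length(object@deathRates) != nT - 1)
    msg <- c(msg, "need one death rate per interval (length(times) - 1)")
  if (any(object@deathRates < 0)) msg <- c(msg, "death rates must be >= 0")
  if (length(object@initialSize) != 1 || object@initialSize <= 0)
    msg <- c(msg, "initialSize must be a single positive number")
  if (length(msg) == 0) {
    dN <- diff(object@sizes)
    d <- object@deathRates
    bad <- dN * (1 - d) < 0
    if (any(bad))
      msg <- c(msg, paste0("sign inconsistency in interval(s) ",
                           paste(which(bad), collapse = ", "),
                           ": a population can only shrink if d > 1 and grow if d < 1"))
    crit <- abs(d - 1) < .EPS_D1 & abs(dN) > 0
    if (any(crit))
      msg <- c(msg, "d = 1 is only permitted on intervals with no size change")
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn GrowthProfile-class constructor.
#' @param times,sizes,deathRates,initialSize,metadata see slots.
#' @export
GrowthProfile <- function(times, sizes, deathRates, initialSize = sizes[1],
                          metadata = list()) {
  new("GrowthProfile", times = as.numeric(times), sizes = as.numeric(sizes),
      deathRates = as.numeric(deathRates), initialSize = as.numeric(initialSize),
      metadata = metadata)
}

#' SegregationSeries: paired total and plasmid-bearing counts over time
#'
#' Viable-count (CFU) time series for one culture: the total population and the
#' subpopulation still carrying a conditionally replicating plasmid. Once
#' plasmid replication is switched off, the plasmid is diluted at cell
#' division, so the declining plasmid-bearing fraction F = plasmidBearing/total
#' counts the generations elapsed independently of net population growth.
#'
#' @slot times numeric, strictly increasing timepoints (hours).
#' @slot total numeric, total viable count at each timepoint (cells).
#' @slot plasmidBearing numeric, plasmid-bearing viable count (cells),
#'   0 < plasmidBearing <= total.
#'
#' @seealso [fitSegregationParameter()], [profileFromSegregation()]
#' @export
setClass("SegregationSeries",
  representation(times = "numeric", total = "numeric", plasmidBearing = "numeric"))

setValidity("SegregationSeries", function(object) {
  msg <- character()
  nT <- length(object@times)
  if (nT < 2) msg <- c(msg, "need at least two timepoints")
  if (any(diff(object@times) <= 0)) msg <- c(msg, "times must be strictly increasing")
  if (length(object@total) != nT || length(object@plasmidBearing) != nT)
    msg <- c(msg, "total and plasmidBearing must match times in length")
  else {
    if (any(object@total <= 0)) msg <- c(msg, "total counts must be > 0")
    if (any(object@plasmidBearing <= 0) || any(object@plasmidBearing > object@total))
      msg <- c(msg, "need 0 < plasmidBearing <= total at every timepoint")
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn SegregationSeries-class constructor.
#' @param times,total,plasmidBearing see slots.
#' @export
SegregationSeries <- function(times, total, plasmidBearing) {
  new("SegregationSeries", times = as.numeric(times), total = as.numeric(total),
      plasmidBearing = as.numeric(plasmidBearing))
}

#' SegregationParameter: fitted per-generation plasmid retention factor
#'
#' Holds the per-generation log2 retention factor sigma = log2((1 + res)/2)
#' and the residual relative plasmid replication rate res in [0, 1). With no
#' residual replication (res = 0) the plasmid-bearing fraction halves every
#' generation (sigma = -1); res > 0 slows the decay.
#'
#' @slot sigma numeric(1), per-generation log2 retention factor, in [-1, 0).
#' @slot res numeric(1), residual relative replication rate, in [0, 1).
#' @slot diagnostics list, fit diagnostics (residuals, points used, clamping).
#'
#' @export
setClass("SegregationParameter",
  representation(sigma = "numeric", res = "numeric", diagnostics = "list"))

setValidity("SegregationParameter", function(object) {
  msg <- character()
  if (length(object@sigma) != 1 || length(object@res) != 1)
    msg <- c(msg, "sigma and res must be scalars")
  else {
    if (object@res < 0 || object@res >= 1) msg <- c(msg, "res must lie in [0, 1)")
    if (object@sigma >= 0) msg <- c(msg, "sigma must be < 0 for a usable segregation signal")
    if (abs(object@sigma - log2((1 + object@res) / 2)) > 1e-8)
      msg <- c(msg, "sigma must equal log2((1 + res)/2)")
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn SegregationParameter-class constructor from `res`.
#' @param res residual relative replication rate in [0, 1).
#' @param diagnostics optional list of fit diagnostics.
#' @export
SegregationParameter <- function(res, diagnostics = list()) {
  new("SegregationParameter", sigma = log2((1 + res) / 2), res = as.numeric(res),
      diagnostics = diagnostics)
}

#' FluctuationDataset: mutant counts across parallel cultures
#'
#' The observable outcome of one fluctuation assay: the number of resistant
#' colonies counted on the selective plate for each parallel culture, the final
#' total population size per culture, the inoculum, and the fraction of each
#' culture's volume that was plated (observed counts are a binomial thinning of
#' each culture's true mutant number).
#'
#' @slot counts numeric, one non-negative integer mutant count per culture.
#' @slot finalSize numeric(1), final total population per culture (cells).
#' @slot initialSize numeric(1), inoculum (cells), >= 1 and < finalSize.
#' @slot platingFraction numeric(1), fraction of culture volume plated, (0, 1].
#'
#' @export
setClass("FluctuationDataset",
  representation(counts = "numeric", finalSize = "numeric",
                 initialSize = "numeric", platingFraction = "numeric"))

setValidity("FluctuationDataset", function(object) {
  msg <- character()
  if (length(object@counts) < 1) msg <- c(msg, "need at least one culture")
  if (any(object@counts < 0) || any(object@counts != floor(object@counts)))
    msg <- c(msg, "counts must be non-negative integers")
  if (object@platingFraction <= 0 || object@platingFraction > 1)
    msg <- c(msg, "platingFraction must lie in (0, 1]")
  if (object@initialSize < 1) msg <- c(msg, "initialSize must be >= 1")
  if (object@finalSize <= object@initialSize)
    msg <- c(msg, "finalSize must exceed initialSize")
  if (length(msg)) msg else TRUE
})

#' @describeIn FluctuationDataset-class constructor.
#' @param counts,finalSize,initialSize,platingFraction see slots.
#' @export
FluctuationDataset <- function(counts, finalSize, initialSize = 1,
                               platingFraction = 1) {
  new("FluctuationDataset", counts = as.numeric(counts),
      finalSize = as.numeric(finalSize), initialSize = as.numeric(initialSize),
      platingFraction = as.numeric(platingFraction))
}

#' RateEstimate: a mutation-rate estimate with uncertainty interval
#'
#' Point estimate of the mutation rate (mutations per division), its
#' uncertainty interval, whether the estimate corrects for death
#' (`"corrected"`) or assumes a death-free Luria-Delbruck model
#' (`"uncorrected"`), and the implied expected number of mutational events per
#' culture, m.
#'
#' @slot rate numeric(1), mutations per division, >= 0.
#' @slot ciLow,ciHigh numeric(1), uncertainty interval, ciLow <= rate <= ciHigh.
#' @slot method character(1), `"uncorrected"` or `"corrected"`.
#' @slot mHat numeric(1), expected mutational events per culture at `rate`.
#' @slot details list, estimator diagnostics (grid, log-likelihoods, flags).
#'
#' @export
setClass("RateEstimate",
  representation(rate = "numeric", ciLow = "numeric", ciHigh = "numeric",
                 method = "character", mHat = "numeric", details = "list"))

setValidity("RateEstimate", function(object) {
  msg <- character()
  if (!object@method %in% c("uncorrected", "corrected"))
    msg <- c(msg, "method must be 'uncorrected' or 'corrected'")
  if (object@rate < 0) msg <- c(msg, "rate must be >= 0")
  if (object@ciLow > object@rate + 1e-12 || object@ciHigh < object@rate - 1e-12)
    msg <- c(msg, "need ciLow <= rate <= ciHigh")
  if (length(msg)) msg else TRUE
})

#' @describeIn RateEstimate-class constructor.
#' @param rate,ciLow,ciHigh,method,mHat,details see slots.
#' @export
RateEstimate <- function(rate, ciLow = rate, ciHigh = rate,
                         method = c("corrected", "uncorrected"),
                         mHat = NA_real_, details = list()) {
  method <- match.arg(method)
  new("RateEstimate", rate = as.numeric(rate), ciLow = as.numeric(ciLow),
      ciHigh = as.numeric(ciHigh), method = method, mHat = as.numeric(mHat),
      details = details)
}

#' EvolvabilitySummary: absolute mutant supply of a condition
#'
#' Evolvability is quantified as the absolute number of mutants at a neutral
#' reporter locus in the final population (whole-culture scale, i.e. observed
#' plate counts divided by the plating fraction). The `source` tag records
#' whether the numbers are observed plate data or simulations with/without
#' death.
#'
#' @slot meanMutants numeric(1), mean absolute mutant count per culture.
#' @slot perCulture numeric, the underlying per-culture whole-culture counts.
#' @slot source character(1), one of `"observed"`, `"simulated_no_death"`,
#'   `"simulated_with_death"`.
#'
#' @export
setClass("EvolvabilitySummary",
  representation(meanMutants = "numeric", perCulture = "numeric",
                 source = "character"))

setValidity("EvolvabilitySummary", function(object) {
  msg <- character()
  if (!object@source %in% c("observed", "simulated_no_death", "simulated_with_death"))
    msg <- c(msg, "unknown source tag")
  if (any(object@perCulture < 0) || object@meanMutants < 0)
    msg <- c(msg, "mutant counts must be >= 0")
  if (abs(object@meanMutants - mean(object@perCulture)) >
      1e-8 * max(1, object@meanMutants))
    msg <- c(msg, "meanMutants must equal mean(perCulture)")
  if (length(msg)) msg else TRUE
})

#' @describeIn EvolvabilitySummary-class constructor.
#' @param perCulture,source see slots; `meanMutants` is computed.
#' @export
EvolvabilitySummary <- function(perCulture, source) {
  new("EvolvabilitySummary", meanMutants = mean(perCulture),
      perCulture = as.numeric(perCulture), source = source)
}

#' SimulationSettings: algorithm, seed and scale of the stochastic simulator
#'
#' @slot algorithm character(1), `"hybrid"` (fast clone-based) or `"gillespie"`
#'   (exact event-by-event oracle, guarded to small populations).
#' @slot seed integer(1) or NA, RNG seed; a fixed seed makes outputs identical.
#' @slot scale numeric(1) >= 1, optional population downscaling for desk runs:
#'   sizes are divided by `scale` and the mutation rate multiplied by `scale`,
#'   preserving the expected number of mutational events m.
#'
#' @export
setClass("SimulationSettings",
  representation(algorithm = "character", seed = "numeric", scale = "numeric"))

setValidity("SimulationSettings", function(object) {
  msg <- character()
  if (!object@algorithm %in% c("hybrid", "gillespie"))
    msg <- c(msg, "algorithm must be 'hybrid' or 'gillespie'")
  if (object@scale < 1) msg <- c(msg, "scale must be >= 1")
  if (length(msg)) msg else TRUE
})

#' @describeIn SimulationSettings-class constructor.
#' @param algorithm,seed,scale see slots.
#' @export
SimulationSettings <- function(algorithm = c("hybrid", "gillespie"),
                               seed = NA_integer_, scale = 1) {
  algorithm <- match.arg(algorithm)
  new("SimulationSettings", algorithm = algorithm,
      seed = as.numeric(seed), scale = as.numeric(scale))
}

#' LDDistribution: truncated Luria-Delbruck mutant-count distribution
#'
#' Probabilities p_0..p_kmax of observing k mutants in one culture under the
#' classic (death-free, fully plated) Luria-Delbruck model with expected number
#' of mutational events m, computed by the Ma-Sandri-Sarkar recursion. The
#' probability mass beyond kmax is reported as `tailMass`.
#'
#' @slot m numeric(1), expected mutational events per culture.
#' @slot probs numeric, p_0..p_kmax.
#' @slot kmax integer(1), truncation index.
#' @slot tailMass numeric(1), 1 - sum(probs).
#'
#' @seealso [mssPmf()], [mleM()]
#' @export
setClass("LDDistribution",
  representation(m = "numeric", probs = "numeric", kmax = "numeric",
                 tailMass = "numeric"))

setValidity("LDDistribution", function(object) {
  msg <- character()
  if (length(object@probs) != object@kmax + 1)
    msg <- c(msg, "probs must have kmax + 1 entries")
  if (any(object@probs < -1e-15)) msg <- c(msg, "probabilities must be >= 0")
  if (sum(object@probs) > 1 + 1e-9) msg <- c(msg, "probabilities must sum to <= 1")
  if (abs(object@probs[1] - exp(-object@m)) > 1e-9)
    msg <- c(msg, "p_0 must equal exp(-m)")
  if (length(msg)) msg else TRUE
})

#' InferenceSettings: controls for the simulation-based rate estimator
#'
#' @slot rateGrid numeric, strictly increasing log-spaced candidate mutation
#'   rates (per division); empty means auto-centre on a pilot estimate.
#' @slot simsPerRate numeric(1), simulated cultures per candidate rate (>= 1000).
#' @slot distance character(1), `"empirical_loglik"` or `"wasserstein"`.
#' @slot seed numeric(1), RNG seed; common random numbers across grid points.
#' @slot smoothing numeric(1), additive pseudocount for the empirical pmf.
#'
#' @seealso [estimateRate()], [empiricalPmf()]
#' @export
setClass("InferenceSettings",
  representation(rateGrid = "numeric", simsPerRate = "numeric",
                 distance = "character", seed = "numeric", smoothing = "numeric"))

setValidity("InferenceSettings", function(object) {
  msg <- character()
  if (length(object@rateGrid)) {
    if (any(diff(object@rateGrid) <= 0)) msg <- c(msg, "rateGrid must be strictly increasing")
    if (length(object@rateGrid) < 20) msg <- c(msg, "rateGrid needs >= 20 points")
    span <- log10(max(object@rateGrid) / min(object@rateGrid))
    if (span < 3 - 1e-9) msg <- c(msg, "rateGrid must span >= 3 orders of magnitude")
  }
  if (object@simsPerRate < 1000) msg <- c(msg, "simsPerRate must be >= 1000")
  if (!object@distance %in% c("empirical_loglik", "wasserstein"))
    msg <- c(msg, "distance must be 'empirical_loglik' or 'wasserstein'")
  if (object@smoothing < 0) msg <- c(msg, "smoothing must be >= 0")
  if (length(msg)) msg else TRUE
})

#' @describeIn InferenceSettings-class constructor.
#' @param rateGrid,simsPerRate,distance,seed,smoothing see slots.
#' @export
InferenceSettings <- function(rateGrid = numeric(0), simsPerRate = 5000,
                              distance = c("empirical_loglik", "wasserstein"),
                              seed = NA_integer_, smoothing = 0.5) {
  distance <- match.arg(distance)
  new("InferenceSettings", rateGrid = as.numeric(rateGrid),
      simsPerRate = as.numeric(simsPerRate), distance = distance,
      seed = as.numeric(seed), smoothing = as.numeric(smoothing))
}
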