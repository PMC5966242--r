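# Stochastic simulation of mutant counts in a fluctuation culture growing
# under an arbitrary GrowthProfile.
#
# Model: mutation is a per-division event (rate mu per division, independent
# of wall-clock time). Over an interval with net size change deltaN and
# relative death rate d, the number of divisions is B = deltaN / (1 - d):
# each division adds one cell, each death removes one, and d deaths occur per
# division. Time units are internal bookkeeping only: within an interval the
# per-capita birth rate is fixed at 1, death rate d, and the interval
# duration is solved from the net growth, tau = ln(N_end/N_start) / (1 - d).
# Results depend only on the sizes and death rates, not on this choice.
#
# The fast "hybrid" algorithm draws mutational events per interval from
# Poisson(mu * B), places each uniformly over the interval's divisions, and
# propagates the resulting clone to the final timepoint as a linear
# birth-death process with birth rate 1 and death rate d_k per interval
# (neutral mutants). The "gillespie" oracle simulates every single division
# and death event explicitly and is used for verification on small instances.

#' Real divisions behind an observed net size change
#'
#' With relative death rate d, a net increase of deltaN cells requires
#' B = deltaN / (1 - d) actual divisions: death events must be compensated by
#' extra replication, each giving an extra opportunity to mutate. A declining
#' interval (d > 1) still requires divisions. At d = 1 the division count is
#' not recoverable from sizes alone; it is only accepted with deltaN = 0,
#' returning 0.
#'
#' @param nStart,nEnd population sizes (cells) bounding the interval.
#' @param d relative death rate over the interval (>= 0).
#' @return the number of divisions, >= 0.
#' @examples
#' intervalDivisions(1, 2, 0.8)   # one net cell gained needs 5 divisions
#' intervalDivisions(200, 100, 2) # decline can still hide 100 divisions
#' @export
intervalDivisions <- function(nStart, nEnd, d) {
  stopifnot(nStart > 0, nEnd > 0, d >= 0)
  dN <- nEnd - nStart
  if (abs(d - 1) < .EPS_D1) {
    if (dN != 0) .stopf("d = 1 is inconsistent with a net size change")
    return(0)
  }
  if (dN * (1 - d) < 0)
    .stopf("sign mismatch: d %s 1 cannot produce this size change",
           if (d < 1) "<" else ">")
  dN / (1 - d)
}

#' Total divisions over a growth profile
#'
#' Sum of [intervalDivisions()] over all intervals of a profile; the
#' denominator of a death-aware mutation-rate estimate.
#'
#' @param profile a [GrowthProfile-class].
#' @return total division count.
#' @export
totalDivisions <- function(profile) {
  stopifnot(is(profile, "GrowthProfile"))
  N <- profile@sizes
  sum(vapply(seq_along(profile@deathRates), function(k)
    intervalDivisions(N[k], N[k + 1], profile@deathRates[k]), numeric(1)))
}

# Extinction probability alpha and geometric parameter beta of a linear
# birth-death process (birth rate 1, death rate d) run for time t, started
# from one cell: P(0) = alpha, P(n | n > 0) = (1 - beta) beta^(n-1).
.bdParams <- function(t, d) {
  if (abs(d - 1) < 1e-9) {
    a <- t / (1 + t)
    return(list(alpha = a, beta = a))
  }
  r <- 1 - d
  E <- exp(r * t)
  denom <- E - d
  list(alpha = pmin(pmax(d * (E - 1) / denom, 0), 1),
       beta  = pmin(pmax((E - 1) / denom, 0), 1))
}

# Propagate clone sizes z (vector) through time t (vector or scalar) under
# death ratio d. Exact sampling via binomial survivors + negative binomial
# excess; deterministic expectation for very large clones (relative
# fluctuation ~ 1/sqrt(z)).
.bdStep <- function(z, t, d) {
  if (!length(z)) return(z)
  t <- rep_len(t, length(z))
  out <- numeric(length(z))
  pos <- z > 0 & t > 0
  out[z > 0 & t <= 0] <- z[z > 0 & t <= 0]
  if (!any(pos)) return(out)
  zp <- z[pos]; tp <- t[pos]
  p <- .bdParams(tp, d)
  big <- zp > 1e7
  if (any(big)) {
    gr <- if (abs(d - 1) < 1e-9) 1 else exp((1 - d) * tp[big])
    out[pos][big] <- round(zp[big] * gr)
  }
  if (any(!big)) {
    zs <- zp[!big]
    surv <- rbinom(length(zs), size = zs, prob = 1 - p$alpha[!big])
    tot <- numeric(length(zs))
    s <- surv > 0
    if (any(s)) {
      beta <- p$beta[!big][s]
      mu_nb <- surv[s] * beta / (1 - beta)
      huge <- !is.finite(mu_nb) | mu_nb > 1e7
      extra <- numeric(sum(s))
      if (any(!huge))
        extra[!huge] <- rnbinom(sum(!huge), size = surv[s][!huge],
                                prob = 1 - beta[!huge])
      if (any(huge)) extra[huge] <- round(mu_nb[huge])
      tot[s] <- surv[s] + extra
    }
    out[pos][!big] <- tot
  }
  out
}

# Per-interval bookkeeping shared by the simulator: divisions B, duration tau.
.profileIntervals <- function(sizes, d) {
  K <- length(sizes) - 1
  dN <- diff(sizes)
  B <- tau <- numeric(K)
  for (k in seq_len(K)) {
    if (abs(d[k] - 1) < .EPS_D1) { B[k] <- 0; tau[k] <- 0 }
    else {
      B[k] <- dN[k] / (1 - d[k])
      tau[k] <- log(sizes[k + 1] / sizes[k]) / (1 - d[k])
    }
  }
  list(B = B, tau = tau)
}

#' Simulate mutant counts for many independent fluctuation cultures
#'
#' Vectorised core of the hybrid clone-based algorithm (see
#' [simulateCulture()]); returns one final mutant count per culture.
#'
#' @param profile a [GrowthProfile-class].
#' @param mu mutation rate per division (0 <= mu << 1).
#' @param n number of independent cultures.
#' @param settings a [SimulationSettings-class]; `algorithm = "gillespie"`
#'   routes every culture through the exact oracle.
#' @return numeric vector of n mutant counts at the final timepoint.
#' @export
simulateCultures <- function(profile, mu, n, settings = SimulationSettings()) {
  stopifnot(is(profile, "GrowthProfile"), is(settings, "SimulationSettings"))
  if (mu < 0) .stopf("mutation rate must be >= 0")
  validObject(profile)
  if (settings@algorithm == "gillespie")
    return(.withSeed(settings@seed,
                     .gillespieCountsCore(profile, mu, n, settings@scale)[, 1]))
  .withSeed(settings@seed, .hybridCounts(profile, mu, n, settings@scale))
}

.hybridCounts <- function(profile, mu, n, scale = 1) {
  sizes <- profile@sizes / scale
  mu <- mu * scale
  d <- profile@deathRates
  K <- length(d)
  iv <- .profileIntervals(sizes, d)
  m <- mu * sum(iv$B)
  counts <- numeric(n)
  M <- rpois(n, m)
  E <- sum(M)
  if (E == 0) return(counts)
  cult <- rep.int(seq_len(n), M)
  orig <- sample.int(K, E, replace = TRUE,
                     prob = if (K > 1) iv$B else NULL)
  u <- runif(E)
  dN <- diff(sizes)
  Nu <- sizes[orig] + u * dN[orig]
  # remaining bookkeeping time inside the origin interval
  trem <- ifelse(abs(d[orig] - 1) < .EPS_D1, 0,
                 log(sizes[orig + 1] / Nu) / (1 - d[orig]))
  z <- rep(1, E)
  for (k in seq_len(K)) {
    here <- orig == k
    after <- orig < k
    if (any(here)) z[here] <- .bdStep(z[here], trem[here], d[k])
    if (any(after)) z[after] <- .bdStep(z[after], iv$tau[k], d[k])
  }
  agg <- rowsum(z, cult)
  counts[as.integer(rownames(agg))] <- agg[, 1]
  pmin(counts, sizes[K + 1])
}

#' Simulate a single fluctuation culture
#'
#' Runs the clone-based hybrid algorithm (or the exact Gillespie oracle,
#' per `settings@algorithm`) for one culture growing under `profile` and
#' returns the mutant count at the final timepoint. Mutants are neutral:
#' clones experience the same per-interval birth and death rates as the wild
#' type. Deterministic given `settings@seed`.
#'
#' @inheritParams simulateCultures
#' @return a single mutant count.
#' @export
simulateCulture <- function(profile, mu, settings = SimulationSettings()) {
  simulateCultures(profile, mu, 1L, settings)
}

.gillespieCountsCore <- function(profile, mu, n, scale = 1) {
  sizes <- round(profile@sizes / scale)
  if (any(sizes < 1)) .stopf("scale too large: sizes fall below one cell")
  d <- profile@deathRates
  if (sizes[length(sizes)] > 1e5)
    .stopf("gillespie oracle is guarded to final sizes <= 1e5")
  dN <- diff(sizes)
  B <- numeric(length(dN))
  for (k in seq_along(dN)) {
    if (abs(d[k] - 1) < .EPS_D1) {
      if (dN[k] != 0) .stopf("d = 1 is inconsistent with a net size change")
      B[k] <- 0
    } else {
      if (dN[k] * (1 - d[k]) < 0) .stopf("sign mismatch in interval %d", k)
      B[k] <- round(dN[k] / (1 - d[k]))
    }
  }
  D <- B - dN  # exact conservation: divisions - deaths = deltaN
  .gillespieRuns(n, sizes[1], B, D, mu * scale)
}

#' Exact event-by-event oracle for one culture
#'
#' Simulates every single-cell division and death explicitly: per interval,
#' B_k division events and d_k B_k death events are interleaved uniformly at
#' random, conditioned on the population never going extinct, so the
#' trajectory hits the profile's sizes exactly. Each wild-type division
#' mutates one daughter with probability mu. Slow by design; guarded to final
#' sizes <= 1e5. Used to validate the hybrid algorithm.
#'
#' @inheritParams simulateCultures
#' @return a single mutant count.
#' @seealso [gillespieCounts()] for many runs with division/death bookkeeping.
#' @export
gillespieOracle <- function(profile, mu, settings = SimulationSettings(algorithm = "gillespie")) {
  stopifnot(is(profile, "GrowthProfile"))
  if (mu < 0) .stopf("mutation rate must be >= 0")
  .withSeed(settings@seed, .gillespieCountsCore(profile, mu, 1L, settings@scale))[, 1]
}

#' Many oracle runs with division/death bookkeeping
#'
#' @inheritParams simulateCultures
#' @return data.frame with columns `mutants`, `divisions`, `deaths`; every row
#'   satisfies divisions - deaths = (final size - initial size) exactly.
#' @export
gillespieCounts <- function(profile, mu, n,
                            settings = SimulationSettings(algorithm = "gillespie")) {
  stopifnot(is(profile, "GrowthProfile"))
  if (mu < 0) .stopf("mutation rate must be >= 0")
  m <- .withSeed(settings@seed, .gillespieCountsCore(profile, mu, n, settings@scale))
  data.frame(mutants = m[, 1], divisions = m[, 2], deaths = m[, 3])
}

#' Simulate a full fluctuation assay
#'
#' Draws `nCultures` independent cultures under `profile` and thins each
#' culture's mutant count binomially with the plating fraction (only a
#' fraction of each culture's volume reaches the selective plate).
#'
#' @inheritParams simulateCultures
#' @param nCultures number of parallel cultures (>= 1).
#' @param platingFraction fraction of culture volume plated, (0, 1].
#' @return a [FluctuationDataset-class] with the profile's final size.
#' @export
simulateFluctuationAssay <- function(profile, mu, nCultures, platingFraction = 1,
                                     settings = SimulationSettings()) {
  stopifnot(nCultures >= 1, platingFraction > 0, platingFraction <= 1)
  counts <- simulateCultures(profile, mu, nCultures, settings)
  plated <- .withSeed(.subSeed(settings@seed, 777L),
                      .thinCounts(counts, platingFraction))
  FluctuationDataset(plated, finalSize = finalSize(profile) / settings@scale,
                     initialSize = max(1, profile@initialSize / settings@scale),
                     platingFraction = platingFraction)
}

.thinCounts <- function(counts, p) {
  if (p >= 1) return(counts)
  small <- counts <= 2^31 - 2
  out <- numeric(length(counts))
  out[small] <- rbinom(sum(small), size = as.integer(counts[small]), prob = p)
  out[!small] <- round(counts[!small] * p)
  out
}

#' Downscale a profile for desk-scale simulation
#'
#' Divides all population sizes by `scale`; pairing this with a mutation rate
#' multiplied by `scale` preserves the expected number of mutational events
#' m = mu * sum(B_k). A good approximation whenever per-interval division
#' counts remain much larger than 1.
#'
#' @param profile a [GrowthProfile-class].
#' @param scale factor >= 1.
#' @return the rescaled [GrowthProfile-class].
#' @export
scaleProfile <- function(profile, scale) {
  stopifnot(scale >= 1)
  GrowthProfile(profile@times, profile@sizes / scale, profile@deathRates,
                initialSize = max(1, profile@initialSize / scale),
                metadata = profile@metadata)
}
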