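# Evolvability as absolute mutant supply: the number of mutants at a neutral
# reporter locus in the final population, at whole-culture scale. The
# no-death counterfactual isolates the contribution of turnover: the same
# final population size reached with the same mutation rate but without
# death, as if the treatment were purely bacteriostatic.

#' Observed evolvability of a fluctuation dataset
#'
#' Rescales plate counts to whole-culture scale (counts / plating fraction)
#' and summarises their mean.
#'
#' @param dataset a [FluctuationDataset-class].
#' @param perMl if TRUE, additionally divide by the culture volume implied by
#'   `finalSize` being a whole-culture count; default FALSE (absolute counts).
#' @param volumeMl culture volume in mL, used only when `perMl = TRUE`.
#' @return an [EvolvabilitySummary-class] with `source = "observed"`.
#' @examples
#' d <- FluctuationDataset(c(1, 3), finalSize = 1e9, platingFraction = 0.2)
#' meanMutants(observedEvolvability(d))  # (5 + 15)/2 = 10
#' @export
observedEvolvability <- function(dataset, perMl = FALSE, volumeMl = 1) {
  stopifnot(is(dataset, "FluctuationDataset"))
  per <- dataset@counts / dataset@platingFraction
  if (perMl) per <- per / volumeMl
  EvolvabilitySummary(per, source = "observed")
}

#' Simulated evolvability under a growth profile
#'
#' Simulates `nSims` cultures at the estimated rate under `profile`, full
#' plating, and summarises the absolute mutant counts.
#'
#' @param profile a [GrowthProfile-class].
#' @param rate a [RateEstimate-class] (or a bare numeric rate).
#' @param nSims replicate simulations (default 100).
#' @param settings a [SimulationSettings-class].
#' @param source tag for the summary (default `"simulated_with_death"`).
#' @return an [EvolvabilitySummary-class].
#' @export
simulatedEvolvability <- function(profile, rate, nSims = 100,
                                  settings = SimulationSettings(),
                                  source = "simulated_with_death") {
  mu <- if (is(rate, "RateEstimate")) rate@rate else as.numeric(rate)
  counts <- simulateCultures(profile, mu, nSims, settings)
  EvolvabilitySummary(counts, source = source)
}

#' No-death counterfactual evolvability
#'
#' Answers "how many mutants would the culture have produced had the same
#' final population size been reached without any death?": the profile is
#' replaced by its death-free counterpart running from initial to final size
#' (d = 0 throughout, so divisions = net size change), keeping the mutation
#' rate. This mimics a purely bacteriostatic treatment.
#'
#' @param profile the measured [GrowthProfile-class].
#' @param rate the corrected [RateEstimate-class] (or numeric rate).
#' @param nSims replicate simulations (default 100).
#' @param settings a [SimulationSettings-class].
#' @return an [EvolvabilitySummary-class] with `source = "simulated_no_death"`.
#' @export
counterfactualNoDeath <- function(profile, rate, nSims = 100,
                                  settings = SimulationSettings()) {
  stopifnot(is(profile, "GrowthProfile"))
  N <- profile@sizes
  t <- profile@times
  if (N[length(N)] <= N[1])
    .stopf("no-death counterfactual needs net growth from first to last timepoint")
  nodeath <- GrowthProfile(times = c(t[1], t[length(t)]),
                           sizes = c(N[1], N[length(N)]), deathRates = 0,
                           initialSize = profile@initialSize)
  simulatedEvolvability(nodeath, rate, nSims, settings,
                        source = "simulated_no_death")
}

#' Contribution of turnover to evolvability
#'
#' Ratio of mean mutant supply with death to the no-death counterfactual,
#' with a bootstrap percentile confidence interval on the ratio of means.
#' A ratio above 1 means the hidden divisions that compensate death add
#' mutants beyond what the net growth alone explains.
#'
#' @param withDeath,noDeath [EvolvabilitySummary-class] objects at matching
#'   mutation rate and final size.
#' @param nBoot bootstrap resamples (default 1000).
#' @param seed RNG seed for the bootstrap.
#' @return list with `ratio`, `ciLow`, `ciHigh`.
#' @export
turnoverContribution <- function(withDeath, noDeath, nBoot = 1000, seed = NA) {
  stopifnot(is(withDeath, "EvolvabilitySummary"), is(noDeath, "EvolvabilitySummary"))
  if (noDeath@meanMutants == 0) .stopf("no-death mean mutant supply is zero")
  w <- withDeath@perCulture
  nd <- noDeath@perCulture
  ratio <- mean(w) / mean(nd)
  boots <- .withSeed(seed, vapply(seq_len(nBoot), function(b) {
    mw <- mean(sample(w, replace = TRUE))
    mn <- mean(sample(nd, replace = TRUE))
    if (mn == 0) NA_real_ else mw / mn
  }, numeric(1)))
  boots <- boots[is.finite(boots)]
  list(ratio = ratio,
       ciLow = quantile(boots, 0.025, names = FALSE),
       ciHigh = quantile(boots, 0.975, names = FALSE))
}

#' Compare evolvability of two conditions
#'
#' Convenience wrapper around `t.test` (default, mirroring common practice on
#' replicate means) or `wilcox.test` on per-culture mutant supplies.
#'
#' @param a,b [EvolvabilitySummary-class] objects.
#' @param test `"t"` or `"wilcoxon"`.
#' @return the `htest` object.
#' @export
compareEvolvability <- function(a, b, test = c("t", "wilcoxon")) {
  test <- match.arg(test)
  if (test == "t") t.test(a@perCulture, b@perCulture)
  else wilcox.test(a@perCulture, b@perCulture, exact = FALSE)
}
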