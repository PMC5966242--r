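---
title: "Estimating mutation rates when stress kills: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating mutation rates when stress kills: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(deathFluct)
```

## The problem

The fluctuation test infers a mutation rate from the distribution of mutant
counts across parallel cultures. Every classic calculator (the
Ma–Sandri–Sarkar maximum-likelihood machinery and its descendants) assumes
the culture only grows: the final population size $N$ then approximates the
number of cell divisions, and the rate is $\mu = m/N$, with $m$ the inferred
number of mutational events.

Sub-inhibitory stress breaks that assumption. A culture can grow *net* while
cells die at a substantial relative rate. With a relative death rate $d$
(death events per division event), a net gain of $\Delta N$ cells requires

$$B = \frac{\Delta N}{1 - d}$$

actual divisions: at $d = 0.8$, one observed net cell hides five DNA
replications, each an extra opportunity to mutate. Ignoring death therefore
systematically inflates the estimated mutation rate, and the deeper the
death, the larger the inflation. `deathFluct` implements the full corrected
stack: measuring $d$ from plasmid segregation, simulating mutant counts
under arbitrary growth-and-death dynamics, inferring a death-corrected rate
by simulation-based likelihood matching, and quantifying what turnover does
to a population's mutant supply ("evolvability").

## Measuring death from plasmid segregation

A conditionally replicating plasmid (replication switched off by removing
the inducer) is diluted at each division. With residual relative replication
$res \in [0, 1)$, the plasmid-bearing fraction $F$ decays per generation $g$
as

$$F_g = F_0 \left(\frac{1 + res}{2}\right)^g,$$

so $g = \log_2(F_\mathrm{final}/F_\mathrm{initial}) / \sigma$ with
$\sigma = \log_2((1+res)/2)$. The generation count from marker decay, set
against the observed net growth, yields the relative death rate

$$d = 1 - \frac{\log_2(N_\mathrm{final}/N_\mathrm{initial})}{g}.$$

`fitSegregationParameter()` estimates $\sigma$ from untreated cultures
(assumed death-free, so $g$ equals the $\log_2$ fold-growth), by least
squares of $\log_2 F_t/F_0$ on $\log_2 N_t/N_0$ with the intercept anchored
at the first timepoint, pooling all replicates jointly — one global fit uses
all plates and is robust to a single noisy one. Whether $\sigma$ is refit
per experimental batch or shared is the caller's choice; we default to
per-batch fitting (each batch's own untreated series) since plasmid
behaviour can drift with medium and day.

Numerical conventions, chosen once:

* **Negative raw $d$** (a treated culture apparently dying less than the
  untreated fit implies) is measurement noise; it is clamped to 0 and the
  raw value kept in the diagnostics. Clamping is conservative: it
  under-corrects and can never inflate the correction.
* **Extreme $d$** is truncated at a configurable cap, default 5, following
  the convention of reporting death rates above 5 as 5.
* **Sign consistency.** A profile interval must satisfy
  $(\Delta N)(1 - d) \ge 0$. When noise pushes an estimated $d$ across 1,
  it is nudged to the nearest consistent value and the interval flagged
  (`metadata$clampedIntervals`).
* **$d = 1$ exactly** (constant size, pure turnover) is representable but
  contributes zero countable divisions: the division count of a stationary
  interval is not identifiable from sizes alone. Our segregation fixtures
  avoid exact stationarity for this reason; truly stationary phases with
  turnover are a stated limitation, and populations in deep stationary
  phase give little segregation signal anyway.
* Plate counts below about 10 colonies flag an interval as low-confidence.

## Simulating fluctuation cultures under arbitrary dynamics

Mutation here is an event per *division*, not per unit time (the standard
Luria–Delbrück assumption), so wall-clock time is pure bookkeeping. The
simulator fixes the per-capita birth rate at 1 within each interval, solves
the interval duration from the net growth,
$\tau_k = \ln(N_{k+1}/N_k)/(1-d_k)$, and checks that results are invariant
to this choice (splitting an interval on the same exponential path leaves
the mutant-count distribution unchanged).

The fast **hybrid** algorithm draws the number of mutational events in
interval $k$ from $\mathrm{Poisson}(\mu B_k)$, places each uniformly over
the interval's divisions (uniform over divisions, not over time), and
propagates the resulting clone to the final timepoint as a linear
birth–death process with birth rate 1 and death rate $d_k$ per interval —
mutants are neutral. Clone propagation uses the exact extinction/geometric
law of the linear birth–death process; clones above $10^7$ cells follow
their deterministic expectation (relative fluctuation below
$1/\sqrt{10^7}$). Declining intervals ($d > 1$) need no special handling:
the same formulas describe subcritical clones. Double and back mutation are
neglected ($\mu \ll 1$).

The **Gillespie oracle** (`gillespieOracle()`, `gillespieCounts()`)
simulates every single division and death: per interval, $B_k$ division and
$d_k B_k$ death events interleaved uniformly at random, conditioned (by
rejection) on non-extinction, so divisions − deaths = $\Delta N$ holds
exactly in every run. It is guarded to final sizes of at most $10^5$ and
exists to validate the hybrid algorithm; the two agree to total-variation
distance well below 0.02 on small instances across $d \in \{0, 0.5, 0.9,
2\}$.

At $d = 0$ the hybrid model is exactly the Lea–Coulson formulation, and its
empirical distribution matches the analytic Ma–Sandri–Sarkar pmf
(chi-square goodness of fit over $10^5$ simulations).

Partial plating is a *binomial thinning* of each culture's mutant count —
the sampling reality — rather than a deterministic rescaling.

For desk-scale work, dividing all sizes by a factor while multiplying $\mu$
by the same factor preserves the expected number of events $m = \mu \sum
B_k$; the approximation is good whenever per-interval division counts stay
much larger than 1 (tested at total-variation distance below 0.02).

## The corrected estimator

No analytic mutant-count distribution exists for arbitrary piecewise
dynamics, so the corrected estimator is simulation-based. For each candidate
rate on a log-spaced grid it simulates `simsPerRate` plated cultures under
the measured profile, builds a smoothed empirical pmf, and scores the
observed counts. Design choices the underlying idea leaves open, and how we
resolved them:

* **Distance.** Default is the smoothed empirical log-likelihood rather
  than an $\epsilon$-threshold accept/reject scheme: it uses every culture,
  needs no tolerance schedule, and yields a likelihood-ratio interval (grid
  points within 1.92 log-likelihood units). A trimmed 1-D Wasserstein
  distance with a bootstrap interval is available as an alternative
  (`distance = "wasserstein"`); its top quantiles are trimmed because the
  sample maximum of a heavy-tailed distribution grows with sample size, and
  comparing a large simulated sample with 24 observed cultures at the
  extremes would bias the match downward.
* **Prior and point estimate.** Uniform on log rate over the grid; the
  reported estimate is the MAP, equivalently the grid-restricted MLE,
  refined by a three-point parabola in $\log_{10}$ rate around the grid
  maximum so the answer is not quantised to the grid spacing.
* **Grid.** Auto-centred on a pilot classic estimate (read against the
  plated subpopulation), spanning ±1.5 orders of magnitude with 41 points.
  An optimum on the boundary is flagged and returned.
* **Monte-Carlo control.** Common random numbers across grid points (every
  candidate rate reuses the same seed), which makes the likelihood profile
  smooth in the rate; 5000 simulations per rate by default, the level at
  which the corrected estimate reproduces the classic MLE within 20% on
  essentially every death-free assay of 24 cultures.
* **Jackpot handling.** Simulated and observed counts above the 95th
  percentile of the pilot simulation are pooled into a shared tail bin, so
  a single jackpot culture cannot dominate; an additive pseudocount (0.5)
  smooths empty bins.

Two calibration facts are worth knowing. First, at $d = 0$ and full plating
the corrected estimator reproduces the classic MLE (this is tested, and is
the package's central self-check). Second, the *naive* classic reading of
partially plated data — fit the plated counts, divide by the plated
subpopulation — overestimates the rate even without death, because jackpot
clones survive thinning better than singletons; the corrected estimator
models thinning exactly and does not share this bias. The classic
`uncorrectedRate()` therefore refuses partially plated data outright, and
the naive recast (`asFullyPlated()`) exists only to reproduce what the
standard tools would report.

The classic machinery itself (`mssPmf()`, `mleM()`) uses the standard
recursion $p_0 = e^{-m}$, $p_k = (m/k)\sum_{i<k} p_i/(k-i+1)$, a bounded
1-D likelihood maximisation, and a profile-likelihood interval; counts above
`kmax` (default capped at 1500) are pooled into a tail bin. The denominator
of $\mu = m/N$ is the final size, following the usual approximation that
the inoculum is negligible.

Joint inference of $d$ and $\mu$ from mutant counts alone is deliberately
unsupported: the two are not identifiable from one count distribution;
$d$ must come from segregation (or equivalent) data.

## Evolvability and the no-death counterfactual

Evolvability is quantified as the absolute number of mutants at a neutral
reporter locus in the final population — whole-culture scale, so observed
plate counts are divided by the plating fraction (a per-mL variant is
available). The no-death counterfactual asks what the same culture would
have produced had its final size been reached without death, as under a
purely bacteriostatic treatment: a single death-free interval from initial
to final size. For a profile that already has $d = 0$ throughout, this
counterfactual is distribution-identical to the original (the clone-size
law depends only on the ratio of final to at-mutation size), which is
tested; for profiles with interior decline it is the only consistent
reading, since interior sizes cannot be preserved without death.
`turnoverContribution()` reports the ratio of mean supplies with a
bootstrap interval. Note that sample means of Luria–Delbrück-tailed counts
converge slowly (the clone-size law has a $1/z^2$ tail), so ratios of
empirical means sit below their population counterparts at moderate
simulation counts; the bootstrap interval reflects this honestly. Both $t$
tests (the conventional choice on replicate means) and rank-sum tests are
offered for condition comparisons.

## Synthetic fixtures and what they do and do not show

`makeFixture()` generates closed-loop test data on the experimental
0/3/6/24 h sampling grid, with ground truth bundled: the true profile, true
$res$ (default 0.1), and true $\mu$. The regimes emulate the three
qualitative behaviours of sub-MIC treatments:

* `untreated` — no death, final size $2 \times 10^9$ cells, $\mu = 10^{-9}$
  per division;
* `norfloxacin_like` — persistent death in all phases ($d$ = 0.5/0.6/0.7),
  final size reduced by well over an order of magnitude, $\mu = 6\times
  10^{-9}$ (a sixfold elevation over untreated);
* `h2o2_like` — purely bacteriostatic growth, death only in stationary
  phase ($d$ = 0/0/0.9), final size unaffected, $\mu = 2\times 10^{-9}$;
* `kanamycin_like` — decline through 6 h ($d > 1$), then recovery with
  continued death ($d$ = 2.5/2/0.3), final size near untreated,
  $\mu = 10^{-9}$ (no elevation).

Segregation plate counts are Poisson per plate at dilutions auto-chosen to
target ~300 colonies; total and plasmid-bearing counts come from separate
plates at separate dilutions, which is why the noise model is two
independent Poisson draws rather than one multinomial split — equivalent at
these colony numbers. Mutant counts are simulated by the hybrid algorithm
at the true $\mu$ with 24 cultures and plating fraction 0.2 (200 µL of a
1 mL culture).

What passing on these fixtures does *not* show about real data:
the fixtures have no filamentation or multi-chromosome cells, no
mutagenesis in non-dividing cells, no subpopulation heterogeneity, no
fitness cost of the reporter mutation, and death rates constant within each
interval. All of these are assumptions of the method itself, inherited by
the fixtures; the fixtures validate the inference machinery, not those
assumptions.

## Problem sizes used in the packaged checks

The packaged studies default to desk scale — final size $10^5$, $\mu =
10^{-5}$, 24 cultures, 200 assays per death rate — which keeps $m \approx
1$ as in typical assays while the whole suite runs in minutes; the
experimental scale ($10^9$ cells, $\mu = 10^{-9}$) is reachable through the
same arguments, and the hybrid simulator's cost is essentially independent
of population size. Distributional comparisons use $10^4$–$10^5$
simulations; estimator-recovery checks use 20–50 assays per condition.

One empirical note from the overestimation study: the classic estimator's
median inflation at $d = 0.8$ is around 2.4, *below* the hidden-division
factor $1/(1-d) = 5$. The shortfall is real, not a bug: under death many
mutational events found clones that go extinct before plating, which
removes part of the extra signal the hidden divisions would otherwise
contribute. The monotone increase of the inflation with $d$, and its
magnitude, are validated against the event-by-event oracle rather than
against any published figure.

## Worked example

```{r example, eval = FALSE}
# death-rate profile from segregation data
untreated <- makeFixture("untreated", seed = 1)
treated <- makeFixture("kanamycin_like", seed = 1)
param <- fitSegregationParameter(untreated$segregation)
profile <- consensusProfile(treated$segregation, param)

# corrected and naive estimates
corrected <- estimateRate(treated$dataset, profile,
                          InferenceSettings(seed = 2))
naive <- uncorrectedRate(asFullyPlated(treated$dataset))

# what turnover contributed to the mutant supply
withD <- simulatedEvolvability(profile, corrected, nSims = 1000,
                               settings = SimulationSettings(seed = 3))
noD <- counterfactualNoDeath(profile, corrected, nSims = 1000,
                             settings = SimulationSettings(seed = 4))
turnoverContribution(withD, noD, seed = 5)
```

## Known limitations

* Stationary-phase turnover ($d = 1$ at constant size) contributes no
  countable divisions; the method needs net size change or marker decay to
  see division activity, and is not applicable to starving or spatially
  structured populations.
* The segregation signal degrades once the plasmid-bearing fraction falls
  near the plating detection limit; very high death rates over long
  intervals exhaust the marker.
* Death rates are assumed homogeneous within an interval and across the
  population.
* The corrected estimator's interval reflects simulation and likelihood
  uncertainty on the rate grid, not uncertainty in the death-rate profile
  itself; profile uncertainty can be propagated by re-running the estimator
  over replicate profiles.
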