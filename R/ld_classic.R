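# Classic (death-free) fluctuation-test machinery: the Luria-Delbruck
# mutant-count distribution via the Ma-Sandri-Sarkar (MSS) recursion, and
# maximum-likelihood estimation of the expected number of mutational events m.
# This is the "uncorrected" estimator that the death-aware machinery is
# compared against.

.DEFAULT_KMAX <- 1500

#' Luria-Delbruck mutant-count probabilities (Ma-Sandri-Sarkar recursion)
#'
#' Computes p_0..p_kmax of the number of mutants in one culture under the
#' classic model, from p_0 = exp(-m) and
#' p_k = (m/k) * sum_{i=0}^{k-1} p_i / (k - i + 1). The only free parameter is
#' m, the expected number of mutational events per culture.
#'
#' @param m expected mutational events per culture (>= 0).
#' @param kmax truncation index (>= 0); mass beyond kmax is in `tailMass`.
#' @return an [LDDistribution-class].
#' @examples
#' pmf <- mssPmf(1, 10)
#' ldProbs(pmf)[1:2]  # exp(-1), exp(-1)/2
#' @export
mssPmf <- function(m, kmax = 100) {
  stopifnot(m >= 0, kmax >= 0)
  probs <- .mssProbs(m, as.integer(kmax))
  new("LDDistribution", m = as.numeric(m), probs = probs,
      kmax = as.numeric(kmax), tailMass = max(0, 1 - sum(probs)))
}

#' Sample mutant counts from the Luria-Delbruck distribution
#'
#' Inverse-cdf sampling from [mssPmf()]; draws falling in the truncated tail
#' are reported as `kmax + 1`.
#'
#' @param n number of draws.
#' @param m expected mutational events per culture.
#' @param kmax truncation index for the pmf (default 5000).
#' @return integer-valued numeric vector of mutant counts.
#' @export
rluria <- function(n, m, kmax = 5000) {
  pmf <- mssPmf(m, kmax)
  cdf <- cumsum(pmf@probs)
  findInterval(runif(n), cdf) # counts; values > kmax collapse to kmax + 1
}

# Log-likelihood of counts under MSS(m), pooling counts > kmax into the tail.
.mssLoglik <- function(counts, m, kmax) {
  if (m <= 0) return(if (all(counts == 0)) 0 else -Inf)
  pmf <- .mssProbs(m, as.integer(kmax))
  tail <- max(1e-300, 1 - sum(pmf))
  inb <- counts <= kmax
  sum(log(pmax(pmf[counts[inb] + 1], 1e-300))) + sum(!inb) * log(tail)
}

#' Maximum-likelihood estimate of the number of mutational events
#'
#' One-dimensional bounded maximisation of the MSS log-likelihood over m >= 0,
#' with a profile-likelihood confidence interval at the chi-square threshold
#' (log-likelihood drop of 1.92, i.e. 95%). Counts above `kmax` are pooled
#' into a tail bin of mass 1 - sum(p), so single jackpot cultures cannot
#' dominate the fit.
#'
#' @param counts non-empty vector of non-negative mutant counts.
#' @param kmax pmf truncation; defaults to min(1500, max(counts)) but never
#'   below 10.
#' @return list with `m` (the MLE), `ciLow`, `ciHigh`, `loglik`, `kmax`.
#'   With all-zero counts, `m = 0` and the upper bound solves the p_0
#'   likelihood.
#' @export
mleM <- function(counts, kmax = NULL) {
  stopifnot(length(counts) >= 1, all(counts >= 0))
  C <- length(counts)
  if (is.null(kmax)) kmax <- max(10, min(.DEFAULT_KMAX, max(counts)))
  if (all(counts == 0))
    return(list(m = 0, ciLow = 0, ciHigh = 1.92 / C, loglik = 0, kmax = kmax))
  f <- function(logm) .mssLoglik(counts, exp(logm), kmax)
  hi <- log(max(2 * (mean(counts) + 1), 10))
  opt <- optimize(f, interval = c(log(1e-4), hi), maximum = TRUE,
                  tol = 1e-7)
  mhat <- exp(opt$maximum)
  llmax <- opt$objective
  drop <- function(m) .mssLoglik(counts, m, kmax) - llmax + 1.92
  ciLow <- tryCatch({
    if (drop(1e-6) > 0) 0 else uniroot(drop, c(1e-6, mhat), tol = 1e-8)$root
  }, error = function(e) 0)
  ciHigh <- tryCatch({
    ub <- mhat * 10
    while (drop(ub) > 0 && ub < 1e6) ub <- ub * 10
    uniroot(drop, c(mhat, ub), tol = 1e-8)$root
  }, error = function(e) Inf)
  list(m = mhat, ciLow = ciLow, ciHigh = ciHigh, loglik = llmax, kmax = kmax)
}

#' Classic (uncorrected) mutation-rate estimate
#'
#' The death-free estimator: mu = m / N_final, with m from [mleM()] on the
#' observed counts. It deliberately refuses partially plated data: binomial
#' thinning distorts the Luria-Delbruck distribution, and partially plated
#' assays should go through the simulation-based corrected estimator (or
#' through [asFullyPlated()] when the naive classic number itself is wanted).
#'
#' @param dataset a [FluctuationDataset-class] with `platingFraction == 1`.
#' @param fit optional precomputed [mleM()] result for `mutantCounts(dataset)`.
#' @return a [RateEstimate-class] with `method = "uncorrected"`.
#' @export
uncorrectedRate <- function(dataset, fit = NULL) {
  stopifnot(is(dataset, "FluctuationDataset"))
  if (dataset@platingFraction < 1)
    .stopf(paste("classic estimator assumes full plating;",
                 "use the corrected (simulation-based) estimator for",
                 "partially plated data"))
  if (is.null(fit)) fit <- mleM(dataset@counts)
  N <- dataset@finalSize
  RateEstimate(rate = fit$m / N, ciLow = fit$ciLow / N,
               ciHigh = min(fit$ciHigh / N, Inf), method = "uncorrected",
               mHat = fit$m, details = list(kmax = fit$kmax, loglik = fit$loglik))
}

#' Recast a partially plated assay as a fully plated one
#'
#' The naive reading of partially plated data used by classic calculators:
#' the plated counts are treated as a complete assay of the plated
#' subpopulation, so the final size becomes `finalSize * platingFraction` and
#' the plating fraction 1. Used to compute the "uncorrected" baseline in the
#' correction-comparison study.
#'
#' @param dataset a [FluctuationDataset-class].
#' @return a [FluctuationDataset-class] with `platingFraction = 1`.
#' @export
asFullyPlated <- function(dataset) {
  stopifnot(is(dataset, "FluctuationDataset"))
  FluctuationDataset(dataset@counts,
                     finalSize = dataset@finalSize * dataset@platingFraction,
                     initialSize = min(dataset@initialSize,
                                       dataset@finalSize * dataset@platingFraction / 2),
                     platingFraction = 1)
}
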