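#include <Rcpp.h>
using namespace Rcpp;

// Exact event-by-event simulation of a fluctuation culture conditioned on the
// observed per-interval division/death budget. Per interval k the schedule
// holds B[k] single-cell divisions and D[k] single-cell deaths, interleaved
// uniformly at random; trajectories that hit population zero are rejected and
// redrawn (conditioning on non-extinction). Each wild-type division mutates
// one daughter with probability mu; mutants are neutral.
//
// Returns an nruns x 3 matrix: final mutant count, realized divisions,
// realized deaths (the latter two satisfy divisions - deaths = deltaN by
// construction, every run).
// [[Rcpp::export(name = ".gillespieRuns")]]
NumericMatrix gillespie_runs(int nruns, double n0, NumericVector B,
                             NumericVector D, double mu) {
  int K = B.size();
  NumericMatrix out(nruns, 3);
  double totB = 0.0, totD = 0.0;
  for (int k = 0; k < K; ++k) { totB += B[k]; totD += D[k]; }
  for (int run = 0; run < nruns; ++run) {
    double wt = 0.0, mut = 0.0;
    bool ok = false;
    while (!ok) {
      wt = n0; mut = 0.0; ok = true;
      for (int k = 0; k < K && ok; ++k) {
        double b = B[k], dd = D[k];
        while (b + dd > 0.5) {
          double tot = wt + mut;
          if (tot < 0.5) { ok = false; break; }
          bool isDivision = unif_rand() * (b + dd) < b;
          bool pickMutant = unif_rand() * tot < mut;
          if (isDivision) {
            if (pickMutant) mut += 1.0;
            else if (unif_rand() < mu) mut += 1.0;
            else wt += 1.0;
            b -= 1.0;
          } else {
            if (pickMutant) mut -= 1.0; else wt -= 1.0;
            dd -= 1.0;
          }
        }
        if (wt + mut < 0.5) ok = false;
      }
    }
    out(run, 0) = mut;
    out(run, 1) = totB;
    out(run, 2) = totD;
  }
  return out;
}

// Ma-Sandri-Sarkar recursion for the Luria-Delbruck mutant-count pmf:
// p_0 = exp(-m); p_k = (m/k) * sum_{i=0}^{k-1} p_i / (k - i + 1).
// [[Rcpp::export(name = ".mssProbs")]]
NumericVector mss_probs(double m, int kmax) {
  NumericVector p(kmax + 1);
  p[0] = std::exp(-m);
  for (int k = 1; k <= kmax; ++k) {
    double s = 0.0;
    for (int i = 0; i < k; ++i) s += p[i] / (double)(k - i + 1);
    p[k] = m / k * s;
  }
  return p;
}
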