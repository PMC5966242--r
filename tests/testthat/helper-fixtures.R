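# Shared builders for the test suite.

# Single-interval profile: inoculum -> final size at constant death rate.
oneIntervalProfile <- function(n0 = 10, nf = 1e4, d = 0, tEnd = 24) {
  GrowthProfile(c(0, tEnd), c(n0, nf), d)
}

# Forward-simulate a noise-free segregation series from known res and
# per-interval death rates (the deterministic retention recursion).
forwardSegregation <- function(times, sizes, d, res, f0 = 0.99) {
  sigma <- log2((1 + res) / 2)
  g <- log2(sizes[-1] / sizes[-length(sizes)]) / (1 - d)
  F <- f0 * 2^(sigma * cumsum(c(0, g)))
  SegregationSeries(times, sizes, sizes * F)
}

# Total-variation distance between two empirical count samples.
tvDistance <- function(a, b) {
  K <- max(a, b)
  0.5 * sum(abs(tabulate(a + 1, K + 1) / length(a) -
                tabulate(b + 1, K + 1) / length(b)))
}
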