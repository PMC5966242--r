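Package: deathFluct
Title: Death-Corrected Mutation-Rate Estimation from Fluctuation Assays
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for estimating bacterial mutation rates from fluctuation
    assays when the stress under study also kills cells. Per-interval relative
    death rates are estimated from plasmid-segregation time series; mutant-count
    distributions are simulated under arbitrary birth-death population dynamics
    (with an exact event-by-event oracle); death-corrected mutation rates are
    inferred by simulation-based (approximate Bayesian) likelihood matching; and
    evolvability is quantified as absolute mutant supply with and without
    population turnover. Includes the classic Luria-Delbruck machinery
    (Ma-Sandri-Sarkar probabilities and maximum-likelihood estimation of the
    expected number of mutational events) as the uncorrected baseline, packaged
    simulation studies, CSV/JSON input-output, and a synthetic-fixture
    generator emulating persistent-death, stationary-phase-death and
    decline-then-recovery treatment regimes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
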