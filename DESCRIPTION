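Package: plasmidrescue
Title: Evolutionary Rescue of Bacterial Populations via Heterozygosity on
    Multicopy Plasmids
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Stochastic theory of evolutionary rescue of declining bacterial
    populations through heterozygosity maintained on multicopy plasmids.
    Implements the segregation kernels for regular (deterministic doubling)
    and random (Polya urn) plasmid replication, multitype branching-process
    extinction and establishment probabilities, population-level rescue
    probabilities and rescue-time distributions from the inhomogeneous
    Poisson approximation, spectral analysis of the expected-progeny matrix
    with closed-form critical thresholds on copy number and heterozygote
    fitness, a plasmid cointegration (multimer formation) extension, and an
    exact Gillespie simulator that cross-validates the analytic quantities.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
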