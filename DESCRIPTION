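Package: xhaplo
Title: Single-Locus Haplotype Genealogies, Diversity Statistics, and
    Coalescent Dating for X-Linked Resequencing Data
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for the population-genetic analysis of a single
    non-recombining DNA segment typed as full haplotypes: reading and
    writing haplotype tables with per-population counts, outgroup-based
    ancestral-allele polarization, four-gamete compatibility testing with
    CpG recurrence resolution, rooted perfect-phylogeny (gene tree)
    construction, the standard scaled-mutation-rate estimators and
    neutrality tests (Watterson, Tajima, Fu, Fay and Wu, Ewens-Watterson,
    Slatkin, Chakraborty), phylogenetically calibrated mutation dating by
    the rho statistic with Saillard standard errors, Griffiths-Tavare
    importance-sampling coalescent likelihood (constant size and
    exponential growth) for maximum-likelihood theta, TMRCA and mutation
    ages, and an infinite-sites coalescent simulator with growth,
    bottleneck and island-model demographies for null distributions and
    estimator-behaviour experiments.  Ships a worked 11-kb X-chromosome
    (MTMR8 region) haplotype table as an example data set.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
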