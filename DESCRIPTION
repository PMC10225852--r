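Package: convcor
Title: Detecting Parallel Polygenic Adaptation from Temporal Allele-Frequency Covariance
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting shared (parallel) polygenic responses to
    selection in spatially replicated temporal population-genomic samples.
    Computes convergent-correlation statistics on per-locus allele-frequency
    change between time points with locus-bootstrap confidence intervals,
    Weir-Cockerham F_ST (spatial and temporal), genotype- and locus-level
    VCF filtering, a forward-time two-population Wright-Fisher simulator
    with recombination, migration, a recessive deleterious distribution of
    fitness effects and quantitative-trait loci under stabilizing selection
    (with population-size rescaling for desk-scale runs), and a fast
    synthetic five-cohort generator with known truth for calibration.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    vcfR,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
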