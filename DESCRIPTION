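Package: herbisweep
Title: Forward Simulation and Sweep Theory for Herbicide Target-Site
    Resistance Evolution
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for studying how target-site herbicide resistance (TSR)
    evolves in weed populations such as blackgrass (Alopecurus myosuroides).
    Implements a diploid Wright-Fisher forward simulator of a
    herbicide-target locus (ACCase-like template) with a gamma distribution
    of deleterious fitness effects, origin-tracked TSR mutations, burn-in to
    mutation-selection-drift balance and a herbicide-selection phase;
    analytic probabilities of adaptation from standing genetic variation
    versus de novo mutation; replicate classification and aggregation;
    population-genetic summary statistics (Watterson's theta, nucleotide
    diversity, effective population size); and amplicon-haplotype utilities
    that call TSR codon substitutions, deduplicate haplotypes and count
    independent mutational origins, exercised on synthetic haplotype panels.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    jsonlite,
    S4Vectors,
    IRanges,
    Biostrings
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
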