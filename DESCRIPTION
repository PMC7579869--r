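Package: foundertrace
Title: Founder-Mutation Haplotype Analysis and Allele Age Estimation
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for founder-mutation haplotype studies on
    phased SNP-array data: marker and sample quality control with an exact
    Hardy-Weinberg test, detection of the conserved core haplotype and
    pairwise shared segments around a focal mutation, shared-segment genetic
    distances with UPGMA phylogenies, allele age estimation from
    recombination-driven haplotype decay (moment estimator and Bayesian MCMC
    under a star-genealogy approximation, with demographic growth-rate
    arithmetic), and midpoint-weighted chromosome ancestry summaries for
    carrier versus non-carrier comparisons. Includes a synthetic-data
    generator that emulates the decay of a single founder haplotype over
    generations so that every stage can be exercised end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    pracma,
    stats,
    tools,
    utils,
    vcfR,
    yaml
Suggests:
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
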