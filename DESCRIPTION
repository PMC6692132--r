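Package: mutfit
Title: Fitness Effects of Point Mutations from Competition Assays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates relative fitness of single-nucleotide mutants from
    head-to-head competition colony counts, builds distributions of fitness
    effects (DFE) for synonymous and nonsynonymous mutations, compares them
    with a permutation-bootstrapped Kolmogorov-Smirnov test, characterises
    the beneficial tail by Generalised Pareto likelihood with a likelihood
    ratio test against the exponential, computes codon-level covariates
    (CAI, tAI, start-distance, mRNA windows) with permutation-of-residuals
    regression inference, relates fitness to presence of mutations across a
    phylogeny via Fitch parsimony over randomly resolved polytomies, and
    ships a synthetic-data generator reproducing the statistical structure
    of the competition-assay study design so the whole pipeline is testable
    end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    ape,
    jsonlite,
    yaml,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    knitr,
    rmarkdown
Config/testthat/edition: 3
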