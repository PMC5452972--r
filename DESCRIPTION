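Package: siteRates
Title: Site-Specific Evolutionary Rates from Codon and Amino-Acid Alignments
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and inference of site-specific evolutionary rates in
    protein-coding sequences. Simulates codon alignments along balanced
    phylogenies under site-specific Muse-Gaut (dN/dS) and Halpern-Bruno
    mutation-selection models, infers per-site dN/dS by one-rate fixed-effects
    likelihood (FEL1) and site-specific relative amino-acid rates by
    empirical-Bayes posterior means under a discretized gamma prior, and
    quantifies agreement between the two rate measures (correlation, RMSD of
    mean-normalized scores) across grids of sequence divergence and taxon
    number.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    ape,
    Biostrings,
    phangorn
Suggests:
    testthat (>= 3.0.0),
    Matrix,
    withr,
    jsonlite
Config/testthat/edition: 3
biocViews: Phylogenetics, Software, StatisticalMethod
RoxygenNote: 7.3.3
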