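Package: compostGH
Title: Glycoside Hydrolase Discovery from Thermophilic Compost Metagenomes
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for targeted discovery of glycoside hydrolases
    (GHs) from a feedstock-adapted compost community. Provides SSU rRNA
    amplicon community profiling (relative abundance, rank-abundance
    comparison, Bray-Curtis dissimilarity, fold enrichment with a detection
    floor), profile-HMM identification of GH domains on six-frame-translated
    assembly contigs with read-depth weighting and functional-group
    aggregation, recovery of candidate full-length enzymes by translated
    local alignment with homopolymer frameshift detection and single-base
    correction, composting respiration mass balances (CO2 evolution and O2
    uptake rates with numerical integration), and ash-conserving
    lignocellulose composition-loss accounting. A synthetic-data module
    generates every input with known ground truth so all stages run and are
    testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    pracma
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vegan,
    jsonlite,
    optparse
Config/testthat/edition: 3
biocViews: Metagenomics, Microbiome, Annotation, Alignment, HiddenMarkovModel
RoxygenNote: 7.3.3
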