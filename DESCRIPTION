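Package: secoscreen
Title: Profile-HMM Screening and Genome-Resolved Analysis of Bacterial
    Steroid Catabolism in Metagenomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects and characterizes the potential of microbial
    communities to degrade steroids via the aerobic 9,10-seco pathway,
    starting from assembled metagenome contigs. Provides assembly quality
    gating, six-frame gene calling, a self-contained profile hidden Markov
    model engine for screening predicted proteins against a configurable
    set of steroid-degradation protein families (keyed on the ring-opening
    oxygenases KshA and HsaC), genome-equivalent normalization of hit
    counts, lowest-common-ancestor taxonomy with report-rank rollup,
    tetranucleotide-frequency contig binning with single-copy-marker
    completeness and contamination estimates, reciprocal-best-hit pathway
    completeness scoring against reference steroid degraders, neighbor
    joining phylogenies with bootstrap support and best-hit novelty bands
    for key enzymes, and a seeded synthetic-community generator with
    ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    ape,
    cluster,
    jsonlite,
    methods,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    mclust,
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
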