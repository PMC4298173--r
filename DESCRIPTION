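Package: mldtools
Title: Match Length Distributions for Genome Evolution Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for computing and modelling match length distributions
    (MLDs), the histograms of maximal exact match lengths obtained from the
    self-alignment of a genome or the comparative alignment of two genomes.
    Enumerates maximal exact matches with a suffix-array engine, evaluates
    analytic MLD models (iid baseline, stick-breaking decay of a duplicated
    pair, Yule branching of segmental duplications, retroduplicated pseudogene
    families, and heterogeneous-rate divergence between species), simulates
    neutral genome evolution under point mutation and three segmental
    duplication modes with a kinetic Monte Carlo scheme, and fits power-law
    tail exponents on log-binned match counts, covering the characteristic
    alpha = -3, -4 and -5 tail regimes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
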