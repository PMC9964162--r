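Package: gh51kit
Title: Motif, Domain-Profile and Phylogenetic Characterization of GH51
    Arabinofuranosidases
Version: 0.1.0
Authors@R:
    person("gh51kit", "maintainers", email = "gh51kit@example.org",
           role = c("aut", "cre"))
Description: An in silico pipeline for characterizing plant glycoside
    hydrolase family 51 (GH51) alpha-L-arabinofuranosidases from protein
    sequences and multiple alignments. Validates family membership by
    degenerate catalytic motifs (G-N-E/Q and S-E-Y-x-V), classifies the
    catalytic acid/base position (E versus Q/D substitutions and the G-S-N
    variant), excises the N-terminal CBM4-like domain between conserved
    L-x-V-D and S-x-x-P anchor motifs, builds and scans a profile hidden
    Markov model of the domain, aggregates cross-kingdom domain-prevalence
    statistics with Wilson confidence intervals, trims ambiguous alignment
    blocks, computes neighbor-joining phylogenies with column-resampling
    bootstrap support and clade/catalysis congruence, and computes global
    pairwise alignments with percent identity. Ships a reproducible
    synthetic-family generator so every stage is testable without
    downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    Biostrings,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
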