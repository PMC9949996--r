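Package: ovrfsim
Title: Simulation of Nucleotide Sequence Evolution in Genomes with
    Overlapping Reading Frames
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Gillespie-style exact stochastic simulation of nucleotide
    substitutions along a rooted phylogeny for linear or circular genomes
    carrying any arrangement of open reading frames, including overlapping
    ones. Per-site substitution rates combine an HKY-like mutation model
    (transition bias, stationary frequencies, discretized gamma or lognormal
    mutation-rate categories) with multiplicative dN/dS selection effects
    across all reading-frame contexts of a site. Candidate substitutions are
    organised in a hierarchical event-probability tree that supports
    rate-proportional sampling and incremental updates, with deep copies at
    internal nodes of the phylogeny. Includes readers for FASTA, GenBank,
    YAML run configurations and Newick trees, Shannon-entropy diagnostics of
    the output alignments, and deterministic fixture generators for genomes,
    overlap layouts and random trees.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    ape,
    Biostrings,
    yaml,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
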