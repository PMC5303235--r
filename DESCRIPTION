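Package: copromito
Title: Co-Assembly and Authentication of Mitochondrial Genomes from Mixed Ancient-DNA Read Pools
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: A tested re-implementation of a coprolite palaeogenomics workflow:
    competitive assignment of short ancient reads to a mitochondrial genome
    panel, simultaneous iterative reference-guided consensus assembly of a
    predator and a prey mitogenome from one mixed read pool, deamination-damage
    profiling for authentication, annotation transfer with coding-sequence
    validation under the vertebrate mitochondrial code, difference-count
    neighbor-joining phylogenetics with bootstrap, pseudo-haploid SNP
    genotyping with classical multidimensional scaling, and combination of
    replicate radiocarbon measurements. Ships a synthetic ancient-read
    generator (lognormal fragment lengths, terminal G-to-A/C-to-T damage,
    uniform error) so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Biostrings,
    BiocGenerics,
    ape,
    stats,
    utils,
    tools,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    cluster,
    vegan,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
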