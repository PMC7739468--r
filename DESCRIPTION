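Package: cregulon
Title: Comparative Genomics Reconstruction of Prokaryotic Regulons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Gene-centered comparative genomics of bacterial transcriptional
    regulons. Combines aligned transcription-factor binding-site collections
    into phylogenetically weighted mixture motifs, scans predicted operon
    promoters with position-specific scoring matrices, computes Bayesian
    posterior probabilities of regulation per operon and gene, predicts
    operons with a genome-adaptive intergenic-distance threshold, detects
    orthologous gene groups as cliques of reciprocal best hits, and infers
    ancestral regulation states on the transcription-factor phylogeny by
    bootstrapped discrete-state reconstruction. Includes a synthetic-genome
    generator so the whole workflow is testable without network access.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    igraph,
    jsonlite,
    phangorn,
    stats,
    tools,
    utils,
    grDevices,
    graphics
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
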