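Package: brxrscan
Title: Discovery of WYL-Domain Regulators and Their Phage Defence Neighbourhoods
Version: 0.1.0
Authors@R:
    person("Artifact", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A comparative-genomics pipeline for locating BrxR-family
    (WYL-domain) transcriptional regulators in annotated bacterial genomes
    and characterising their genomic context. Provides protein homology
    search with Karlin-Altschul E-value statistics, strand-aware 50-kb
    neighbourhood association against a phage defence marker panel,
    defence-island composition and co-occurrence summaries,
    mismatch-tolerant inverted-repeat discovery on upstream sequences, and
    quantification of electrophoretic mobility shift assays (fractional
    saturation and dissociation-constant estimation by nonlinear
    regression). Includes deterministic synthetic-data generators with
    machine-readable truth tables for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Rcpp,
    jsonlite,
    methods,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    GenomicRanges,
    rtracklayer,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
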