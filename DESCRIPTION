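Package: editscan
Title: Detection of Depletion-Sensitive C-to-U RNA Editing Sites and
    Nucleolar Screen Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A pipeline for discovering candidate C-to-U RNA editing
    sites from replicated RNA-seq pileups using an exact binomial test
    against a sequencing-error null, replicate-concordance filtering and
    tiering of depletion-sensitive sites, UC dinucleotide motif density
    profiling along transcripts with analytic random baselines,
    position-frequency matrices of edit-site sequence context, Fisher
    exact gene-set over-representation against declared proteome
    baselines, and high-content nucleolar screen statistics (percent
    effect, percent inhibition, DNA-content cell-cycle binning, and
    ratio analysis of multiple pre-rRNA precursors). A synthetic-data
    generator produces references, planted edit sites, pileups,
    annotations, gene sets and screen wells with the statistical
    structure the downstream stages assume.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Biostrings,
    GenomicRanges,
    IRanges,
    rtracklayer,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
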