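Package: snvspike
Title: Interspecies Spike-In Normalization of RNA-Seq Using SNV Internal Standards
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for normalizing human RNA-seq experiments with RNA from a
    closely related species (chimpanzee) spiked in as a locus-by-locus internal
    standard. Informative interspecies single-nucleotide variants (SNVs) are
    discovered from single-species pileups, species alleles are discriminated
    and counted at those positions in mixed samples, and human reads are
    normalized by chimpanzee reads per locus or per transcript. Conventional
    count normalizers (upper quartile, relative log expression, trimmed mean of
    M-values) are provided as comparison baselines, together with evaluation
    statistics (coefficient of variation, replicate agreement, coverage
    flattening, discordance counts). A built-in simulator generates paired
    divergent transcriptomes, spiked mixtures, and biased read placements with
    full ground truth, including 3'-biased degradation and library-preparation
    bias profiles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    data.table,
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    DESeq2,
    optparse
Config/testthat/edition: 3
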