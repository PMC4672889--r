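Package: fracseq
Title: Polysome Fractionation RNA-Seq Occupancy and Degenerate Motif Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of polysome-fractionated RNA-seq experiments in which
    total, mRNP and polysome RNA are sequenced per individual. Provides ERCC
    spike-in anchored normalization, per-individual fraction/total occupancy
    statistics, genotype-level t-tests with high-confidence target calling,
    polysome:mRNP translational-activity ratios, a simplified total-RNA
    differential stage, and a from-scratch degenerate motif scanner
    (consensus to PWM, exact score p-values by dynamic programming,
    Benjamini-Hochberg q-values) for Y-box recognition sequences in 3'UTRs.
    A negative-binomial synthetic-data generator with planted
    loss-of-repression effects and planted motif instances supports
    end-to-end testing without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
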