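Package: epistrans
Title: Epistasis Analysis of Single- and Double-Mutant Transcriptomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies genetic interactions between two transcriptional
    regulators from four-genotype expression profiles (wild type, two single
    mutants, double mutant). For each gene the observed double-mutant
    expression ratio is compared with the multiplicative expectation from the
    single mutants, yielding a per-gene epistasis statistic, distribution-level
    significance tests against a control gene set, and a redundancy screen.
    Includes differential-expression ratio estimation with threshold-based gene
    selection, transcription-factor binding integration (co-occupancy and
    overlap enrichment, ChIP fold-enrichment normalization), signature
    concordance statistics, a synthetic-data generator with known regulatory
    architecture for validation, and an end-to-end pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
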