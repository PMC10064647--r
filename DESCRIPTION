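Package: mgstress
Title: Methylome-Transcriptome Integration for Epigenetic Repression Signatures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline from Infinium-style methylation array intensities and a
    gene-expression table to differentially methylated CpGs, epigenetically
    repressed genes and pathways, a refined stress gene signature, per-patient
    signature scores and survival stratification. Includes beta/M-value
    statistics with peak-based probe-type correction, preranked gene-set
    enrichment with permutation-based NES and FDR, signature scoring by negated
    mean z-scored expression, Kaplan-Meier / log-rank cohort stratification,
    and a synthetic-data generator with planted ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    survival,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
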