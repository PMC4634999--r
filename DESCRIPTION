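Package: mosaicscan
Title: Mosaic Low Allele-Fraction Variant Detection for TSC1/TSC2
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Detection and quantification of low allele-fraction mosaic
    mutations from deep targeted sequencing of the tuberous sclerosis
    genes TSC1 and TSC2. Implements orientation-aware pileup calling with
    tiered allele-fraction thresholds and artifact filters, genomic
    deletion detection from discordant paired-end insert sizes, exact
    20-mer allele quantification in deep amplicon pools against a control
    panel, intronic variant classification relative to splice elements
    with allelic-distortion scoring, and cohort genotype-phenotype
    statistics. Ships synthetic-read generators reproducing the study
    regimes (0.1-50% allele fraction at 500-5,000x depth) so every stage
    is testable without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
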