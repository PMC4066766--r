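Package: pyrimox
Title: Isotope-Dilution Quantification of Hydroxyl-Radical Oxidation
    Products of Methylated and Unmethylated Pyrimidines in DNA
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Workflow for targeted LC-MS/MS (multiple reaction monitoring)
    quantification of hydroxyl-radical-induced oxidation products of
    5-methylcytosine, cytosine and thymine in DNA: isotope-dilution peak-area
    quantification normalized to lesions per million DNA bases, correction of
    deamination occurring during enzymatic digestion, linear dose-response rate
    estimation with replicate aggregation, product-distribution and mechanistic
    pathway analysis, methylation-sensitivity statistics, and two-state van't
    Hoff analysis of UV duplex melting curves. Includes a seeded synthetic-data
    generator emulating the statistical structure of radiolysis experiments so
    the full pipeline is testable without instrument data, and bundled
    reference rate tables for five oligonucleotide duplexes, calf-thymus DNA
    and irradiated cells.
License: MIT
Encoding: UTF-8
Imports:
    graphics,
    jsonlite,
    minpack.lm,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
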