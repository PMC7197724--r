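Package: triofish
Title: Trio Exome Variant Prioritization and Zebrafish Larval Assay Analysis
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested, reusable implementation of three linked analyses used
    in functional genetics studies of monogenic seizure disorders: (1) trio
    whole-exome variant prioritization under dominant (de novo) and recessive
    (homozygous, compound-heterozygous, X-linked hemizygous) inheritance
    models with rarity and population-database exclusion rules, followed by a
    transparent conservation/deleteriousness evidence tally; (2) zebrafish
    larval motility analysis of per-well tracking exports (swim speed, total
    distance, dark/light/dark protocol segmentation, two-group t-tests,
    pentylenetetrazol fold-change response); and (3) relative qPCR
    quantification of transcripts by the Livak 2^-ddCt method with
    technical-replicate collapsing and biological-replicate statistics. Each
    stage is paired with a seeded synthetic-data generator with known ground
    truth so the full pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    vcfR
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
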