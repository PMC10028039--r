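Package: piscreen
Title: Pyrrole-Imidazole Polyamide Drug-Sensitivity Screening
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for hairpin pyrrole-imidazole (PI) polyamide based
    drug-sensitivity screens. Models hairpin polyamide backbones and derives
    their degenerate DNA duplex recognition motifs from minor-groove pairing
    rules, scans genomes for binding sites on both strands, runs a
    multi-compound differential-expression screen with compound-exclusivity
    (Venn) selection, and narrows candidates through hypergeometric pathway
    enrichment, intragenic binding-site and Kaplan-Meier survival filters.
    Includes four-parameter logistic dose-response (IC50) fitting with
    combination-shift analysis, molecular-formula monoisotopic mass utilities
    for conjugate QC, and seeded synthetic-data generators that emit every
    input the pipeline consumes together with ground-truth records for
    recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Biostrings,
    GenomicRanges,
    IRanges,
    limma,
    survival,
    minpack.lm,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
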