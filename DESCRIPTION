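Package: epigraft
Title: MSAP Epigenotyping, Epiallele Inheritance Tracking and siRNA
    Matching for Grafting-Induced DNA Methylation Studies
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing grafting-induced DNA methylation changes
    scored by methylation-sensitive amplified polymorphism (MSAP). Classifies
    dual-digest (HpaII/MspI) band presence calls into the four canonical
    methylation states, computes total and fully methylated ratios, classifies
    per-locus methylation pattern transitions between a reference plant and a
    progeny population, partitions differentially methylated fragments (DMFs)
    into uniform and distinctive groups, and tracks per-generation inheritance
    ratios of uniform DMFs across selfed generations. Also includes a bisulfite
    clone caller with CG/CHG/CHH context assignment and conversion-aware
    alignment, a small-RNA differential-expression filter with exact-substring
    matching of siRNAs to DMF sequences, and synthetic-data generators with
    machine-readable ground truth for end-to-end pipeline testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
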