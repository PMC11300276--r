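Package: nanoforge
Title: Design and In Silico Quality Control of Synthetic Humanized Nanobody Libraries
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Toolkit for designing synthetic humanized nanobody (VHH)
    phage-display libraries and analysing the assays used to characterise
    selected binders. Covers IMGT-anchored region annotation, repertoire
    curation and positional statistics, scaffold humanization toward a human
    germline, degenerate-codon optimization against target amino-acid
    distributions, primer/fragment planning with in-silico library sampling
    and clone-defect quality control, and fitting of circular-dichroism melt
    curves, ELISA binding curves, positivity ratios and wound-healing rates.
    Seeded synthetic-data generators make the whole pipeline testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
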