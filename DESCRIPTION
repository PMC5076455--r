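Package: geroscope
Title: Pathway Activation Scoring and Geroprotector Ranking from Gene Expression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Quantifies signaling-pathway activation (PAS) from case-reference
    gene-expression comparisons and ranks candidate geroprotector compounds by
    a pathway-level GeroScore that rewards drugs predicted to push an aged
    expression signalome back toward the young state. Includes case-reference
    differential expression with Student's t-tests and Benjamini-Hochberg FDR
    control, per-sample and per-group pathway activation profiles, a
    drug-target scoring engine, plate-matched vehicle-control design
    construction for compound-perturbation screens, and a synthetic-data
    module with planted effects for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
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
RoxygenNote: 7.3.3
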