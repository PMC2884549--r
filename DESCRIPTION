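Package: temaline
Title: Transposable-Element Dynamics in Mutation-Accumulation Lines
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Forward simulation and analysis of DNA-transposon copy dynamics
    in mutation-accumulation (MA) lines of a cyclical parthenogen. Provides
    closed-form Mendelian expectations for insertion fate under clonal
    propagation, selfing and outcrossing; a forward simulator of MA cohorts
    with excision, homologue-templated reconstitution, germline transposition,
    somatic insertions and emulation of triplicate transposon-display (TD)
    peak tables; scoring of TD peaks into presence/absence matrices with
    calls of losses, germline gains and putative somatic gains; and
    estimation of loss, transposition and somatic gain rates with
    treatment comparisons (t-tests, ANCOVA, regression on copy number).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
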