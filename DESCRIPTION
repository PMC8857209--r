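Package: retrozyme
Title: Enzymatic Reaction SMILES, Dataset Curation and Biocatalytic
    Retrosynthesis Planning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for representing enzyme-catalysed reactions as enzymatic
    reaction SMILES (reaction SMILES extended with an Enzyme Commission number
    on the reactant side), tokenising them for sequence models with a
    hierarchical EC token scheme, curating multi-source reaction collections
    with the four standard filter rules, building product-disjoint
    train/validation/test splits and weighted multitask corpora, scoring
    single-step forward and backward predictors (top-k, round-trip, EC-only
    accuracy, per-class breakdowns, class confusion matrices), and planning
    multi-step retrosynthetic routes by beam search over backward
    disconnections with forward-confidence and complexity-reweighted step
    scores terminating in a stock of available compounds. Single-step
    predictors are pluggable; deterministic lookup and template stubs plus a
    synthetic fixture generator make every component testable without any
    trained model.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml,
    ChemmineOB
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
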