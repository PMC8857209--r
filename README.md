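# retrozyme

An R toolkit for planning enzyme-catalysed synthesis with data-driven
single-step predictors.  It is aimed at cheminformaticians and method
developers who want the machinery around a biocatalytic
sequence-to-sequence model — representation, dataset curation, evaluation
protocol and multi-step route search — as reusable, testable components,
with the model itself left pluggable.

The core objects and procedures:

* **Enzymatic reaction SMILES.**  A reaction SMILES extended with an Enzyme
  Commission number on the reactant side, `A|5.4.99>>B`, parsed and
  serialised losslessly (`parseReactionSmiles()`, `formatReactionSmiles()`).
* **Hierarchical EC tokenisation.**  Atom-level SMILES tokens plus one
  bracketed token per EC level with prefixes `v`/`u`/`t`/`s` and cumulative
  field paths — EC 5.4.99 becomes `[v5] [u5.4] [t5.4.99]` — under token
  schemes EC0–EC4 (`tokenizeEnzymatic()`, `detokenize()`,
  `writeTokenFiles()`).
* **Curation.**  Multi-source records are canonicalised (OpenBabel
  canonical SMILES throughout) and filtered by four rules — (1) drop
  products that are also reactants, (2) strip known cofactors/byproducts
  from multi-product reactions, (3) drop products with fewer than 4 heavy
  atoms, (4) keep exactly-one-product reactions — then deduplicated on the
  canonical extended reaction SMILES at the chosen scheme (`curate()`).
* **Product-disjoint splits** (no product occurs in more than one of
  train/valid/test, default 90/5/5) and **9:1 weighted multitask corpora**
  for joint training with a general-chemistry corpus
  (`productDisjointSplit()`, `prepareMultitaskCorpus()`).
* **Evaluation.**  Top-k, EC-only and round-trip accuracy, per-class
  breakdowns, and the level-1 confusion matrix; EC-randomisation
  (within/across class) probes how much signal the EC token carries
  (`topkAccuracy()`, `roundTripAccuracy()`, `randomizeEC()`, ...).
* **Route planning.**  Beam search over backward disconnections with a
  forward round-trip filter and step scores
  `p_fwd * exp(-lambda * (mean(SC) - 1))`, where SC is a pluggable 1–5
  synthetic-complexity score; search stops when all leaves are in a stock
  of available compounds (`planRoutes()`).

Deterministic lookup/template predictor stubs and a synthetic fixture
generator (`makeRawRecords()`, `makeRouteScenario()`) exercise everything
without any trained model; external predictors plug in through
`functionForwardModel()` / `functionBackwardModel()`.

## Worked example

Curate a small raw reaction table (shipped with the package), then plan a
route on a planted scenario:

```r
library(retrozyme)

raw <- readReactionTable(system.file("extdata", "raw_reactions_12.tsv",
                                     package = "retrozyme"))
ds <- curate(raw, scheme = "EC3")
#> 1 unparseable record(s) skipped
curatedRecords(ds)$rxn_smiles
#> [1] "CC(=O)O.CCO|3.1.1>>CCOC(=O)C"   "CCCO|1.1.1>>CCC=O"
#> [3] "CCOC(=O)C.O|3.1.1>>CC(=O)O"     "CC(=O)O.CCCN|6.3.2>>CCCNC(=O)C"
#> [5] "CCC=O.NCC(=O)O|2.6.1>>CCCN"     "CCCO|1.1.2>>CCC=O"
#> [7] "OC(=O)CCC(=O)O|4.1.1>>CCC(=O)O"
```

Twelve raw records become seven curated ones: a cross-source duplicate pair
merges, a phosphate cofactor and two small products are stripped, a
self-product and two invalid reactions are removed, two EC4 variants merge
at EC3, and one unparseable record is skipped with a message.  Each record
is the canonical extended reaction SMILES: sorted canonical reactants, the
EC truncated to three levels, one product.

Tokenisation for a sequence model:

```r
tokenizeEnzymatic("CC(=O)OCC.O|3.1.1>>CC(=O)O", "EC3")
#>  [1] "C"        "C"        "("        "="        "O"        ")"
#>  [7] "O"        "C"        "C"        "."        "O"        "[v3]"
#> [13] "[u3.1]"   "[t3.1.1]" ">"        ">"        "C"        "C"
#> [19] "("        "="        "O"        ")"        "O"
```

Route planning against deterministic stub models with a planted three-step
route:

```r
sc <- makeRouteScenario(depth = 3, branching = 3, seed = 7)
routes <- planRoutes(sc$target, sc$backward, sc$forward, sc$stock,
                     plannerConfig(beamWidth = 10, maxDepth = 5))
routes[[1]]
#> Route to CCCCCCCCCO: depth 3, score 0.578, solved
#>   CCCCCCCCCO  <- EC 2.1.1 (score 0.834)
#>     CCCCCCCCO  <- EC 4.1.1 (score 0.833)
#>       CCCCCCCO  <- EC 7.1.1 (score 0.833)
#>         CCCCCCO [stock]
#>         CCCCOC(=O)C [stock]
#>       CCCOC(=O)C [stock]
#>     CCOC(=O)C [stock]
```

The planner recovered the planted chain: each step shows the proposed EC
class and the combined step score (forward confidence reweighted by
precursor complexity); the route score 0.578 is the product of the three
step scores, and every leaf is in the stock.  Routes serialise to JSON with
`serializeRoute()`.

A command-line wrapper ships at `inst/scripts/retrozyme` with subcommands
`fixtures`, `curate`, `split`, `make-corpus`, `evaluate` and `plan`
(including an interactive mode).

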