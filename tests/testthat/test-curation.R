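canonRxn <- function(txt) canonicalizeReaction(parseReactionSmiles(txt))

test_that("rule 1 removes products that appear among the reactants", {
    r <- canonRxn("CCO.O>>CC=O.O")
    expect_identical(products(rule1RemoveSelfProducts(r)),
                     canonicalize("CC=O"))
    r2 <- canonRxn("CCO>>CCO")
    expect_length(products(rule1RemoveSelfProducts(r2)), 0L)
    r3 <- canonRxn("CCO>>CC=O")
    expect_identical(products(rule1RemoveSelfProducts(r3)), products(r3))
})

test_that("rule 2 strips cofactors only from multi-product reactions", {
    cfg <- cofactorConfig(coenzymes = "OP(=O)(O)O")
    multi <- canonRxn("CCCO>>CCC=O.OP(=O)(O)O")
    expect_identical(products(rule2StripCofactors(multi, cfg)),
                     canonicalize("CCC=O"))
    # a single listed product is untouched: the rule is gated on >1 product
    single <- canonRxn("CCCO>>OP(=O)(O)O")
    expect_identical(products(rule2StripCofactors(single, cfg)),
                     canonicalize("OP(=O)(O)O"))
    unlisted <- canonRxn("CCCO>>CCC=O.CCCC=O")
    expect_identical(products(rule2StripCofactors(unlisted, cfg)),
                     products(unlisted))
    # the reactant side is never touched
    withReact <- canonRxn("OP(=O)(O)O.CCCO>>CCC=O.OP(=O)(O)O")
    expect_identical(reactants(rule2StripCofactors(withReact, cfg)),
                     reactants(withReact))
})

test_that("rule 3 removes products below 4 heavy atoms, boundary included", {
    r <- canonRxn("CC(=O)OCC.O>>CC(=O)O.OCC.O")
    out <- rule3RemoveSmallProducts(r)
    expect_identical(products(out), canonicalize("CC(=O)O"))  # exactly 4 kept
    expect_length(products(rule3RemoveSmallProducts(canonRxn("C>>CCO"))), 0L)
})

test_that("rule 4 keeps exactly single-product reactions with reactants", {
    expect_true(rule4Keep(canonRxn("CCO.CC(=O)O>>CC(=O)OCC")))
    expect_false(rule4Keep(canonRxn("CCO>>CC=O.CCC=O")))
    expect_false(rule4Keep(canonRxn(">>CCCC")))
    expect_false(rule4Keep(canonRxn("CCO>>")))
})

test_that("the 12-record fixture curates to its hand-audited survivor set", {
    raw <- readReactionTable(raw12Path())
    expect_identical(nrow(raw), 12L)
    ds <- suppressMessages(curate(raw, scheme = "EC3"))
    expect_identical(attr(ds, "skipped"), 1L)   # the invalid record
    expect_setequal(curatedRecords(ds)$rxn_smiles, raw12ExpectedEC3())
    expect_length(ds, 7L)
    # provenance of the cross-source duplicate is merged
    esterKey <- raw12ExpectedEC3()[1L]
    recs <- curatedRecords(ds)
    expect_identical(recs$sources[recs$rxn_smiles == esterKey],
                     "alphadb;betadb")
})

test_that("curation is idempotent", {
    raw <- readReactionTable(raw12Path())
    once <- suppressMessages(curate(raw, scheme = "EC3"))
    twice <- curate(once, scheme = "EC3")
    expect_identical(sort(curatedRecords(twice)$rxn_smiles),
                     sort(curatedRecords(once)$rxn_smiles))
})

test_that("EC4 variants of one reaction merge under EC3 truncation", {
    raw <- data.frame(
        rxn_smiles = rep("CCO>>CC(=O)OCC", 2L),   # placeholder molecules
        ec = c("1.1.1.1", "1.1.1.2"), source = "x",
        stringsAsFactors = FALSE)
    expect_length(curate(raw, scheme = "EC4"), 2L)
    expect_length(curate(raw, scheme = "EC3"), 1L)
})

test_that("every curated record has one product with >= 4 heavy atoms", {
    ds <- curate(makeRawRecords(fixtureSpec(seed = 21L, nReactions = 40L)),
                 scheme = "EC2")
    prods <- datasetProducts(ds)
    expect_true(all(heavyAtomCount(prods) >= 4L))
    expect_false(any(grepl(".", prods, fixed = TRUE)))
})

test_that("product-disjoint splits have zero product overlap", {
    ds <- curate(makeRawRecords(fixtureSpec(seed = 8L, nReactions = 80L)),
                 scheme = "EC3")
    sp <- productDisjointSplit(ds, seed = 1L)
    expect_identical(sum(lengths(sp)), length(ds))
    expect_length(intersect(datasetProducts(sp$train),
                            datasetProducts(sp$test)), 0L)
    expect_length(intersect(datasetProducts(sp$train),
                            datasetProducts(sp$valid)), 0L)
    expect_length(intersect(datasetProducts(sp$valid),
                            datasetProducts(sp$test)), 0L)
})

test_that("records sharing a product land in the same split", {
    # two reactions with the same product, different reactants
    raw <- data.frame(
        rxn_smiles = c("CCO.CC(=O)O>>CC(=O)OCC", "CCCO>>CC(=O)OCC",
                       "OCCC>>O=CCC", "NCCC>>CCC=O", "OCCCC>>O=CCCC",
                       "OCC(C)C>>O=CC(C)C"),
        ec = c("3.1.1.1", "3.1.1.2", "1.1.1.1", "2.6.1.1", "1.1.1.2",
               "1.1.1.3"),
        source = "x", stringsAsFactors = FALSE)
    ds <- curate(raw, scheme = "EC3")
    for (seed in 1:10) {
        sp <- productDisjointSplit(ds, fractions = c(train = 0.5,
                                                     valid = 0.25,
                                                     test = 0.25),
                                   seed = seed)
        ester <- canonicalize("CC(=O)OCC")
        holds <- unname(vapply(sp, function(d)
            sum(datasetProducts(d) == ester), 0L))
        expect_identical(sort(holds, decreasing = TRUE)[1L], 2L)
        expect_identical(sum(holds > 0L), 1L)
    }
})

test_that("splits are deterministic given the seed", {
    ds <- curate(makeRawRecords(fixtureSpec(seed = 8L, nReactions = 50L)),
                 scheme = "EC3")
    a <- productDisjointSplit(ds, seed = 7L)
    b <- productDisjointSplit(ds, seed = 7L)
    c <- productDisjointSplit(ds, seed = 8L)
    expect_identical(lapply(a, curatedRecords), lapply(b, curatedRecords))
    expect_false(identical(lapply(a, curatedRecords),
                           lapply(c, curatedRecords)))
    expect_error(productDisjointSplit(
        curate(data.frame(rxn_smiles = c("OCCC>>O=CCC", "NCCC>>CCC=O"),
                          ec = c("1.1.1.1", "2.6.1.1"), source = "x"),
               scheme = "EC3")),
        "fewer distinct products")
})

test_that("multitask corpus weighting follows the declared proportions", {
    dir <- withr::local_tempdir()
    writeTwo <- function(name, n) {
        src <- file.path(dir, paste0(name, ".src"))
        tgt <- file.path(dir, paste0(name, ".tgt"))
        writeLines(sprintf("%s line %d", name, seq_len(n)), src)
        writeLines(sprintf("%s tgt %d", name, seq_len(n)), tgt)
        list(src = src, tgt = tgt)
    }
    corpora <- list(general = writeTwo("general", 200L),
                    enzymatic = writeTwo("enzymatic", 50L))
    out <- prepareMultitaskCorpus(corpora,
                                  c(general = 9L, enzymatic = 1L),
                                  sampleLines = 5000L, seed = 11L)
    expect_identical(out$manifest$weight, c(9L, 1L))
    frac <- mean(out$sample$corpus == "general")
    ci <- 2.576 * sqrt(0.9 * 0.1 / 5000)
    expect_lt(abs(frac - 0.9), ci)
    # single corpus, weight 1: manifest only, sample drawn from it alone
    one <- prepareMultitaskCorpus(corpora["general"], c(general = 1L),
                                  sampleLines = 10L, seed = 1L)
    expect_true(all(one$sample$corpus == "general"))
    expect_error(prepareMultitaskCorpus(corpora,
                                        c(general = 0L, enzymatic = 1L)),
                 "positive")
    # mismatched line counts
    bad <- corpora
    writeLines("x", bad$general$tgt)
    expect_error(prepareMultitaskCorpus(bad, c(general = 1L,
                                               enzymatic = 1L)),
                 "mismatched")
})

test_that("the training-config descriptor round-trips and takes overrides", {
    path <- withr::local_tempfile(fileext = ".yml")
    cfg <- emitTrainingConfig(path)
    expect_true(any(grepl("layers: 6", readLines(path), fixed = TRUE)))
    expect_identical(readTrainingConfig(path), cfg)
    over <- emitTrainingConfig(path,
                               overrides = list(training =
                                                    list(dropout = 0.2)))
    expect_identical(readTrainingConfig(path)$training$dropout, 0.2)
    expect_identical(over$model$layers, 6L)
})

test_that("curated datasets round-trip through TSV", {
    ds <- curate(makeRawRecords(fixtureSpec(seed = 2L, nReactions = 20L)),
                 scheme = "EC3")
    path <- withr::local_tempfile(fileext = ".tsv")
    writeCuratedDataset(ds, path)
    back <- readCuratedDataset(path, scheme = "EC3")
    expect_identical(curatedRecords(back), curatedRecords(ds))
})
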