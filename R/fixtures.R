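# Deterministic synthetic data: raw multi-source reaction records built from
# a closed template grammar, and planted retrosynthetic route scenarios with
# matched stub models and a stock set.  The generator emits its own ground
# truth (the curated survivor set, the planted route) alongside the data, so
# tests never derive expectations from the code under test.
#
# The grammar is tiny on purpose (a dozen aliphatic building blocks, seven
# template families mapped to the seven enzyme classes) so that brute-force
# oracles over the generated data run in well under a second.  Template
# families carry fixed EC level-3 paths consistent with their chemistry
# class purely as labels; no biochemical accuracy is claimed.

.FIX_ACIDS <- c("CC(=O)O", "CCC(=O)O", "CCCC(=O)O", "CC(C)C(=O)O",
                "OCC(=O)O", "CCCCC(=O)O")
.FIX_ALCOHOLS <- c("OCC", "OCCC", "OC(C)C", "OCCCC", "OCC(C)C", "OCCO")
.FIX_AMINES <- c("NCC", "NCCC", "NCCCC", "NCC(C)C")

# acid "R-C(=O)O" + alcohol "O-R'" -> ester "R-C(=O)O-R'"
.fixEster <- function(acid, alcohol)
    paste0(acid, sub("^O", "", alcohol))
# alcohol "O-C..." -> aldehyde "O=C..."
.fixAldehyde <- function(alcohol) sub("^OC", "O=C", alcohol)
# amine "N-C..." from the matching alcohol backbone
.fixAmine <- function(alcohol) sub("^O", "N", alcohol)
# acid "R-C(=O)O" + amine "N-R'" -> amide "R-C(=O)N-R'"
.fixAmide <- function(acid, amine)
    paste0(sub("O$", "", acid), amine)

#' Fixture generation parameters
#'
#' @param seed integer seed; all generation is deterministic given it.
#' @param nReactions number of base reactions to draw.
#' @param classMix probabilities over enzyme classes 1..7 (summing to 1).
#' @param cofactorRate probability that a reaction gains a strippable
#'   cofactor product (exercises rule 2).
#' @param smallProductRate probability of an extra product with fewer than 4
#'   heavy atoms (exercises rule 3).
#' @param duplicateRate probability that a record is emitted under a second
#'   source (exercises deduplication).
#' @param routeDepth depth of planted route scenarios derived from the spec.
#' @return a `fixtureSpec` list.
#' @export
fixtureSpec <- function(seed = 1L, nReactions = 60L,
                        classMix = rep(1 / 7, 7),
                        cofactorRate = 0.10, smallProductRate = 0.10,
                        duplicateRate = 0.15, routeDepth = 3L) {
    stopifnot(nReactions >= 1L, length(classMix) == 7L,
              abs(sum(classMix) - 1) < 1e-8, all(classMix >= 0),
              all(c(cofactorRate, smallProductRate, duplicateRate) >= 0),
              all(c(cofactorRate, smallProductRate, duplicateRate) <= 1),
              routeDepth >= 1L)
    structure(list(seed = as.integer(seed),
                   nReactions = as.integer(nReactions),
                   classMix = classMix, cofactorRate = cofactorRate,
                   smallProductRate = smallProductRate,
                   duplicateRate = duplicateRate,
                   routeDepth = as.integer(routeDepth)),
              class = "fixtureSpec")
}

# one clean single-product reaction per template family; class k in 1..7
.fixTemplate <- function(class1, pick) {
    acid <- .FIX_ACIDS[pick(length(.FIX_ACIDS))]
    alcohol <- .FIX_ALCOHOLS[pick(length(.FIX_ALCOHOLS))]
    # classes whose product is the (shortened) alcohol backbone need >= 4
    # heavy atoms in the product, so ethanol is excluded there
    alcoholBig <- .FIX_ALCOHOLS[-1L][pick(length(.FIX_ALCOHOLS) - 1L)]
    amine <- .FIX_AMINES[pick(length(.FIX_AMINES))]
    serial <- pick(5L)
    switch(class1,
        # 1: oxidation of a primary alcohol to the aldehyde
        list(reactants = alcoholBig, products = .fixAldehyde(alcoholBig),
             ec = sprintf("1.1.%d.%d", pick(3L), serial)),
        # 2: transamination of an aldehyde to the amine
        list(reactants = c(.fixAldehyde(alcoholBig), "NCC(=O)O"),
             products = .fixAmine(alcoholBig),
             ec = sprintf("2.%d.1.%d", c(6L, 7L)[pick(2L)], serial)),
        # 3: ester hydrolysis; the small alcohol leaving group is removed by
        # rule 3, leaving the acid as the single product
        list(reactants = c(.fixEster(acid, "OCC"), "O"),
             products = c(acid, "OCC"),
             ec = sprintf("3.1.%d.%d", pick(3L), serial)),
        # 4: decarboxylation of a malonate-like diacid
        list(reactants = paste0("OC(=O)C", sub("^C", "", acid)),
             products = c(acid, "O=C=O"),
             ec = sprintf("4.1.%d.%d", pick(2L), serial)),
        # 5: aldose-ketose isomerisation: terminal aldehyde + 2-OH chain
        # rearranges to the 1-ol-2-one form (same formula)
        list(reactants = paste0("O=CC(O)C", sub("^O", "", alcohol)),
             products = paste0("OCC(=O)C", sub("^O", "", alcohol)),
             ec = sprintf("5.3.%d.%d", pick(2L), serial)),
        # 6: amide ligation (water byproduct removed by rule 3)
        list(reactants = c(acid, amine),
             products = c(.fixAmide(acid, amine), "O"),
             ec = sprintf("6.3.%d.%d", pick(2L), serial)),
        # 7: translocase-labelled oxidation of an aldehyde to the acid
        list(reactants = .fixAldehyde(alcohol),
             products = paste0(sub("^O=C", "OC(=O)", .fixAldehyde(alcohol))),
             ec = sprintf("7.%d.1.%d", pick(2L), serial)))
}

#' Generate raw multi-source reaction records
#'
#' Draws `nReactions` base reactions from the template grammar with ECs at
#' all four levels across the seven classes, then injects, at the configured
#' rates: a strippable cofactor product (phosphate), an extra small product,
#' and duplicate emission under a second source.  Output is byte-identical
#' for a fixed seed.
#'
#' The returned object carries the generator's own ground truth in
#' `attr(x, "manifest")`: the expected curated survivor keys (canonical
#' extended reaction SMILES) at every token scheme EC0..EC4, computed from
#' the clean base reactions, not by the curation code.
#'
#' @param spec a [fixtureSpec()].
#' @return data.frame with columns `rxn_smiles`, `ec`, `source` plus the
#'   `manifest` attribute.
#' @export
makeRawRecords <- function(spec) {
    stopifnot(inherits(spec, "fixtureSpec"))
    withr_seed(spec$seed, {
        pick <- function(n) sample.int(n, 1L)
        sources <- c("alphadb", "betadb", "gammadb", "deltadb")
        rows <- list(); base <- list()
        for (i in seq_len(spec$nReactions)) {
            class1 <- sample.int(7L, 1L, prob = spec$classMix)
            tpl <- .fixTemplate(class1, pick)
            base[[i]] <- tpl
            products <- tpl$products
            if (stats::runif(1) < spec$cofactorRate)
                products <- c(products, "OP(=O)(O)O")
            if (stats::runif(1) < spec$smallProductRate)
                products <- c(products, "CO")
            src <- sources[pick(length(sources))]
            rxn <- paste0(paste(tpl$reactants, collapse = "."), ">>",
                          paste(products, collapse = "."))
            rows[[length(rows) + 1L]] <-
                data.frame(rxn_smiles = rxn, ec = tpl$ec, source = src,
                           stringsAsFactors = FALSE)
            if (stats::runif(1) < spec$duplicateRate) {
                other <- setdiff(sources, src)[pick(length(sources) - 1L)]
                rows[[length(rows) + 1L]] <-
                    data.frame(rxn_smiles = rxn, ec = tpl$ec, source = other,
                               stringsAsFactors = FALSE)
            }
        }
        records <- do.call(rbind, rows)
        # ground truth: clean single-product form of each base reaction,
        # canonicalised and keyed per scheme
        manifest <- lapply(stats::setNames(0:4, paste0("EC", 0:4)),
            function(k) {
                keys <- vapply(base, function(tpl) {
                    prods <- tpl$products[heavyAtomCount(tpl$products) >= 4L]
                    ec <- ECNumber(tpl$ec)
                    ec <- ECNumber(ecLevels(ec)[seq_len(k)])
                    lhs <- paste(sort(canonicalize(tpl$reactants),
                                      method = "radix"), collapse = ".")
                    if (!ecIsAbsent(ec))
                        lhs <- paste0(lhs, "|", ecText(ec))
                    paste0(lhs, ">>", canonicalize(prods[1L]))
                }, "")
                sort(unique(keys))
            })
        attr(records, "manifest") <- manifest
        records
    })
}

#' Construct a planted retrosynthetic route scenario
#'
#' Builds a reaction tree with exactly one solvable route of the given depth
#' terminating in a stock set, plus `branching - 1` decoy disconnections per
#' on-route molecule whose leaves are *not* in stock and cannot be expanded
#' further.  Returns matched deterministic stub models: a
#' [templateBackwardModel()] holding every (planted + decoy) disconnection,
#' and a forward lookup over the same reactions, so all proposals pass the
#' planner's round-trip filter and only stock membership separates the
#' planted route from the decoys.  The planted route is given the highest
#' rule priority, so it is also the expected rank-1 result.
#'
#' @param depth number of steps of the planted route (>= 1).
#' @param branching total disconnections per on-route molecule (>= 1).
#' @param seed integer seed (controls which building blocks are used).
#' @return list with `target`, `backward`, `forward`, `stock`,
#'   `plantedRoute` (molecule chain from target down), `decoys` (decoy leaf
#'   molecules) and `rules` (the backward rule table).
#' @export
makeRouteScenario <- function(depth = 3L, branching = 3L, seed = 1L) {
    stopifnot(depth >= 1L, branching >= 1L)
    # distinct molecule chains: on-route intermediates are linear alcohols of
    # decreasing length, side precursors are acids, decoys are amines
    chainLen <- depth + 2L
    mol <- function(prefix, len) paste0(prefix, strrep("C", len))
    onRoute <- vapply(seq_len(depth + 1L), function(i)
        mol("OC", chainLen + depth + 1L - i), "")   # target first
    sidePre <- vapply(seq_len(depth), function(i)
        mol("CC(=O)OC", i), "")
    decoyIdx <- 0L
    rules <- list(); fwdRows <- list()
    withr_seed(seed, {
        for (i in seq_len(depth)) {
            product <- onRoute[i]
            planted <- c(onRoute[i + 1L], sidePre[i])
            rules[[length(rules) + 1L]] <- data.frame(
                product = product,
                precursors = paste(planted, collapse = "."),
                ec = sprintf("%d.1.1", sample.int(7L, 1L)),
                priority = branching + 1, stringsAsFactors = FALSE)
            for (b in seq_len(branching - 1L)) {
                decoyIdx <- decoyIdx + 1L
                decoy <- mol("NC", chainLen + decoyIdx)
                rules[[length(rules) + 1L]] <- data.frame(
                    product = product,
                    precursors = decoy,
                    ec = sprintf("%d.2.1", sample.int(7L, 1L)),
                    priority = branching - b + 0.5,
                    stringsAsFactors = FALSE)
            }
        }
    })
    rules <- do.call(rbind, rules)
    backward <- templateBackwardModel(rules)
    # forward lookup: every rule inverted, exact match
    fwdTable <- data.frame(
        rxn_smiles = paste0(
            vapply(strsplit(rules$precursors, ".", fixed = TRUE),
                   function(p) paste(sort(canonicalize(p),
                                          method = "radix"), collapse = "."),
                   ""),
            "|", rules$ec, ">>", canonicalize(rules$product)),
        ec = rules$ec, sources = "scenario", stringsAsFactors = FALSE)
    forward <- lookupForwardModel(
        new("CuratedDataset", scheme = "EC3",
            records = fwdTable[!duplicated(fwdTable$rxn_smiles), ,
                               drop = FALSE]))
    stock <- canonicalize(c(onRoute[depth + 1L], sidePre))
    list(target = canonicalize(onRoute[1L]), backward = backward,
         forward = forward, stock = stock,
         plantedRoute = canonicalize(onRoute),
         decoys = canonicalize(rules$precursors[
             !grepl(".", rules$precursors, fixed = TRUE) &
                 startsWith(rules$precursors, "NC")]),
         rules = rules)
}

#' Write a fixture directory
#'
#' Materialises a fixture set for CLI use: the raw record TSV, the
#' ground-truth manifest JSON, the stub backward rule table and the stock
#' list of a planted route scenario.
#'
#' @param dir output directory (created if missing).
#' @param spec a [fixtureSpec()].
#' @return invisibly, the paths written.
#' @export
writeFixtureDirectory <- function(dir, spec = fixtureSpec()) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    records <- makeRawRecords(spec)
    paths <- list(
        raw = file.path(dir, "raw_records.tsv"),
        manifest = file.path(dir, "manifest.json"),
        rules = file.path(dir, "backward_rules.tsv"),
        stock = file.path(dir, "stock.smi"))
    utils::write.table(records, paths$raw, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    jsonlite::write_json(attr(records, "manifest"), paths$manifest,
                         pretty = TRUE)
    sc <- makeRouteScenario(depth = spec$routeDepth, branching = 3L,
                            seed = spec$seed)
    utils::write.table(sc$rules, paths$rules, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    writeLines(sc$stock, paths$stock)
    invisible(paths)
}
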