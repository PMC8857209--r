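# Shared builders: the hand-audited 12-record curation fixture, inverse
# forward/backward stub pairs, a corruptible forward wrapper, and a
# brute-force route enumerator used as the planner oracle.

raw12Path <- function()
    system.file("extdata", "raw_reactions_12.tsv", package = "retrozyme")

# Expected EC3 survivors of the 12-record fixture, derived by hand from the
# four filter rules (see the fixture audit in test-curation.R).  Keys are
# assembled from canonicalize() on hand-written molecules -- not from the
# curation code under test.
raw12ExpectedEC3 <- function() {
    key <- function(reactants, ec, product)
        paste0(paste(sort(canonicalize(reactants), method = "radix"),
                     collapse = "."),
               "|", ec, ">>", canonicalize(product))
    c(key(c("CC(=O)O", "OCC"), "3.1.1", "CC(=O)OCC"),
      key("CCCO", "1.1.1", "CCC=O"),
      key(c("CC(=O)OCC", "O"), "3.1.1", "CC(=O)O"),
      key(c("CC(=O)O", "NCCC"), "6.3.2", "CC(=O)NCCC"),
      key(c("O=CCC", "NCC(=O)O"), "2.6.1", "NCCC"),
      key("OCCC", "1.1.2", "O=CCC"),
      key("OC(=O)CCC(=O)O", "4.1.1", "CCC(=O)O"))
}

# inverse stub pair over a curated dataset: backward proposes exactly the
# recorded reactants+EC for each product, forward is the exact-match lookup
inverseStubPair <- function(dataset) {
    recs <- curatedRecords(dataset)
    parts <- lapply(recs$rxn_smiles, parseReactionSmiles)
    rules <- data.frame(
        product = vapply(parts, function(r) r@products[1L], ""),
        precursors = vapply(parts, function(r)
            paste(r@reactants, collapse = "."), ""),
        ec = recs$ec,
        priority = 1,
        stringsAsFactors = FALSE)
    list(backward = templateBackwardModel(rules),
         forward = lookupForwardModel(dataset))
}

# forward wrapper returning a wrong product for targets in `corrupt`
corruptedForward <- function(forward, corrupt) {
    functionForwardModel(function(reactants, ec, k) {
        res <- forwardPredict(forward, reactants, ec, k = k)
        if (nrow(res) && res$product[1L] %in% corrupt)
            res$product[1L] <- "C1CCCCCCCCC1"
        res
    })
}

# a toy planning instance with two solvable routes (and one decoy), used to
# compare beam search against exhaustive enumeration
toyPlanningInstance <- function() {
    rules <- data.frame(
        product    = c("OCCCCCC", "OCCCCCC", "OCCCCCC",
                       "OCCCCC", "NCCCCC", "OCCCC"),
        precursors = c("OCCCCC.CCCCCC", "NCCCCC", "NCCCCCCCCCC",
                       "OCCCC.CCCCC", "OCCCC", "CCCC"),
        ec = c("1.1.1", "2.6.1", "3.1.1", "1.1.1", "4.1.1", "5.3.1"),
        priority = c(3, 2, 1, 2, 1, 1),
        stringsAsFactors = FALSE)
    backward <- templateBackwardModel(rules)
    fwdTable <- data.frame(
        rxn_smiles = paste0(
            vapply(strsplit(rules$precursors, ".", fixed = TRUE),
                   function(p) paste(sort(canonicalize(p), method = "radix"),
                                     collapse = "."), ""),
            "|", rules$ec, ">>", canonicalize(rules$product)),
        ec = rules$ec, sources = "toy", stringsAsFactors = FALSE)
    forward <- lookupForwardModel(
        new("CuratedDataset", scheme = "EC3", records = fwdTable))
    list(target = "OCCCCCC", backward = backward, forward = forward,
         stock = c("CCCCCC", "CCCCC", "CCCC"))
}

# canonical structural key of a route tree (molecule + ordered children)
routeTreeKey <- function(node) {
    if (!length(node$children)) return(node$smiles)
    paste0(node$smiles, "(",
           paste(vapply(node$children, routeTreeKey, ""), collapse = ","),
           ")")
}

# exhaustive enumeration of all solved route trees up to maxDepth, built on
# expandMolecule() but independent of the beam-search machinery
bruteForceRoutes <- function(target, backward, forward, stock, maxDepth,
                             k = 3L, lambda = 0.25) {
    target <- canonicalize(target)
    stock <- canonicalize(stock)
    enumMol <- function(mol, anc, depthLeft) {
        if (mol %in% stock)
            return(list(list(smiles = mol, in_stock = TRUE,
                             children = list(), score = 1)))
        if (depthLeft == 0L)
            return(list())
        out <- list()
        for (step in expandMolecule(mol, backward, forward, k = k,
                                    lambda = lambda)) {
            if (any(step$precursors %in% c(anc, mol)))
                next
            subLists <- lapply(step$precursors, enumMol,
                               anc = c(anc, mol), depthLeft = depthLeft - 1L)
            if (any(lengths(subLists) == 0L))
                next
            combos <- do.call(expand.grid,
                              c(lapply(subLists, seq_along),
                                KEEP.OUT.ATTRS = FALSE))
            for (ci in seq_len(nrow(combos))) {
                children <- lapply(seq_along(subLists), function(j)
                    subLists[[j]][[combos[ci, j]]])
                sc <- step$combined_score *
                    prod(vapply(children, `[[`, 0.0, "score"))
                out[[length(out) + 1L]] <-
                    list(smiles = mol, in_stock = FALSE,
                         children = children, score = sc)
            }
        }
        out
    }
    enumMol(target, character(0), maxDepth)
}
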