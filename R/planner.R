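# Multi-step retrosynthetic route search.  The backward model proposes
# disconnections; each proposal must pass a round-trip filter (the forward
# model's rank-1 product on the proposed precursors and EC must regenerate
# the parent molecule) and is then scored by the forward confidence
# reweighted by the synthetic complexity of the precursors:
#
#   combined = p_forward * exp(-lambda * (mean(complexity) - 1))
#
# Routes are explored by level-synchronous beam search over whole partial
# routes: at each depth every unsolved leaf of every beam candidate is
# expanded, child routes are formed from all per-leaf candidate
# combinations, and the top beam_width by route score (product of step
# scores) are kept.  A branch terminates when all leaves are in the stock
# (solved) or at max_depth (abandoned).  A molecule may not reappear on its
# own ancestor path (cycle guard).

#' Heuristic synthetic-complexity score
#'
#' A pluggable proxy for a learned synthetic-complexity model, on the same
#' 1-5 scale: monotone increasing in heavy-atom count, ring count and
#' stereocentre count,
#' `1 + 3.2 * (1 - exp(-(n_heavy - 1)/25)) + 0.25 * n_rings +
#'  0.15 * n_stereo`, clamped to \[1,5\].  A single-heavy-atom acyclic
#' molecule scores exactly 1.  Any function mapping SMILES to \[1,5\] can
#' replace it in [scoreStep()]/[planRoutes()] (e.g. an adapter to a trained
#' complexity model).
#'
#' @param smiles character vector of single-molecule SMILES.
#' @return numeric vector of scores in \[1,5\].
#' @examples
#' complexityScore(c("C", "C1CCCCC1", "CC(=O)OCC"))
#' @export
complexityScore <- function(smiles) {
    vapply(smiles, function(s) {
        tok <- tokenizeMolecular(s)
        n <- sum(.isHeavyAtomToken(tok))
        ring <- sum(grepl("^[0-9]$|^%[0-9]{2}$", tok)) / 2
        stereo <- sum(grepl("@", tok, fixed = TRUE)) +
            sum(tok %in% c("/", "\\")) / 2
        min(5, max(1, 1 + 3.2 * (1 - exp(-(n - 1) / 25)) +
                      0.25 * ring + 0.15 * stereo))
    }, 0.0, USE.NAMES = FALSE)
}

#' Combined step score
#'
#' The score of a retrosynthetic step: the forward model's confidence in the
#' proposed reaction, reweighted by the synthetic complexity of the
#' precursors, `forwardConf * exp(-lambda * (mean(complexities) - 1))`.
#' With `lambda = 0` the score is the forward confidence; a step onto
#' minimally complex precursors (all scores 1) is never penalised; zero
#' forward confidence gives zero.  Monotone increasing in `forwardConf`,
#' decreasing in mean complexity.
#'
#' @param backwardConf backward-model confidence in \[0,1\] (recorded on the
#'   step, not part of the score).
#' @param forwardConf forward-model confidence in \[0,1\].
#' @param complexities numeric vector of precursor complexities in \[1,5\].
#' @param lambda non-negative complexity weight; default 0.25.
#' @return the combined score in \[0,1\].
#' @export
scoreStep <- function(backwardConf, forwardConf, complexities,
                      lambda = 0.25) {
    stopifnot(forwardConf >= 0, forwardConf <= 1, lambda >= 0,
              all(complexities >= 1), all(complexities <= 5))
    forwardConf * exp(-lambda * (mean(complexities) - 1))
}

#' Planner configuration
#'
#' @param beamWidth number of partial routes kept per search level.
#' @param maxDepth maximum number of steps on any root-to-leaf chain.
#' @param k backward proposals requested per expanded molecule.
#' @param lambda complexity weight of [scoreStep()].
#' @param seed integer; recorded for interface stability (the shipped
#'   predictors and tie-breaks are deterministic, so the search itself does
#'   not consume randomness).
#' @return a `plannerConfig` list.
#' @export
plannerConfig <- function(beamWidth = 5L, maxDepth = 6L, k = 3L,
                          lambda = 0.25, seed = 42L) {
    stopifnot(beamWidth >= 1L, maxDepth >= 1L, k >= 1L, lambda >= 0)
    structure(list(beamWidth = as.integer(beamWidth),
                   maxDepth = as.integer(maxDepth), k = as.integer(k),
                   lambda = lambda, seed = as.integer(seed)),
              class = "plannerConfig")
}

#' Read a stock (available compounds) file
#'
#' One SMILES per line, `#` comments allowed; molecules are canonicalised so
#' stock membership is an exact canonical-string test.
#'
#' @param path file path.
#' @return character vector of canonical SMILES.
#' @export
readStock <- function(path) {
    lines <- trimws(readLines(path))
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    unique(canonicalize(lines))
}

#' Expand a molecule into scored synthesis steps
#'
#' Requests the backward model's top-`k` disconnections of `product`, keeps
#' only proposals whose forward rank-1 prediction on (precursors, EC)
#' regenerates `product` (the round-trip filter), scores survivors with
#' [scoreStep()], and returns them sorted by combined score (ties broken
#' lexicographically on the serialised precursors).
#'
#' @param product canonical SMILES to disconnect.
#' @param backward,forward predictor models.
#' @param k backward proposals to request.
#' @param lambda complexity weight.
#' @param scorer complexity function, default [complexityScore()].
#' @return list of steps; each a list with `product`, `precursors`
#'   (character vector), `ec`, `backward_confidence`, `forward_confidence`,
#'   `complexity` (per precursor) and `combined_score`.
#' @export
expandMolecule <- function(product, backward, forward, k = 3L,
                           lambda = 0.25, scorer = complexityScore) {
    product <- canonicalize(product)
    props <- tryCatch(backwardPredict(backward, product, k = k),
                      error = function(e) {
                          message("backward failure on ", product, ": ",
                                  conditionMessage(e))
                          .emptyBackward() })
    steps <- list()
    for (i in seq_len(nrow(props))) {
        precursors <- strsplit(props$precursors[i], ".", fixed = TRUE)[[1]]
        fwd <- tryCatch(forwardPredict(forward, precursors,
                                       ECNumber(props$ec[i]), k = 1L),
                        error = function(e) .emptyForward())
        if (!nrow(fwd) || fwd$product[1L] != product)
            next                     # fails the round-trip filter
        cx <- scorer(precursors)
        steps[[length(steps) + 1L]] <- list(
            product = product, precursors = precursors, ec = props$ec[i],
            backward_confidence = props$confidence[i],
            forward_confidence = fwd$confidence[1L],
            complexity = cx,
            combined_score = scoreStep(props$confidence[i],
                                       fwd$confidence[1L], cx, lambda))
    }
    if (length(steps) > 1L) {
        key <- vapply(steps, function(s)
            paste(s$precursors, collapse = "."), "")
        score <- vapply(steps, `[[`, 0.0, "combined_score")
        steps <- steps[order(-score, key, method = "radix")]
    }
    steps
}

## internal partial-route machinery -----------------------------------------

.leafNode <- function(smiles, inStock)
    list(smiles = smiles, in_stock = inStock, step = NULL, children = list())

# paths to unsolved leaves; a path is an integer vector of child indices
.openLeaves <- function(node, stock, path = integer(0)) {
    if (!length(node$children)) {
        if (node$in_stock) return(list())
        return(list(path))
    }
    out <- list()
    for (i in seq_along(node$children))
        out <- c(out, .openLeaves(node$children[[i]], stock, c(path, i)))
    out
}

.nodeAt <- function(node, path) {
    for (i in path) node <- node$children[[i]]
    node
}

.ancestors <- function(node, path) {
    mols <- node$smiles
    for (i in path) { node <- node$children[[i]]; mols <- c(mols, node$smiles) }
    mols
}

.applyStep <- function(node, path, step, stock) {
    if (!length(path)) {
        node$step <- step[c("ec", "backward_confidence",
                            "forward_confidence", "complexity",
                            "combined_score")]
        node$children <- lapply(step$precursors, function(p)
            .leafNode(p, p %in% stock))
        return(node)
    }
    node$children[[path[1L]]] <-
        .applyStep(node$children[[path[1L]]], path[-1L], step, stock)
    node
}

.treeDepth <- function(node) {
    if (!length(node$children)) return(0L)
    1L + max(vapply(node$children, .treeDepth, 0L))
}

.treeLeaves <- function(node) {
    if (!length(node$children)) return(node$smiles)
    unlist(lapply(node$children, .treeLeaves))
}

.treeKey <- function(node) {
    if (!length(node$children)) return(node$smiles)
    paste0(node$smiles, "(",
           paste(vapply(node$children, .treeKey, ""), collapse = ","), ")")
}

.routeFromState <- function(target, state, stock) {
    leaves <- .treeLeaves(state$tree)
    new("Route", target = target, tree = state$tree,
        score = state$score, depth = .treeDepth(state$tree),
        solved = all(leaves %in% stock))
}

#' Plan retrosynthetic routes by beam search
#'
#' Searches backwards from `target` until every leaf of a route is in
#' `stock` (solved) or `maxDepth` is reached.  See the package vignette for
#' the search discipline; returned routes are sorted by route score
#' (product of step scores), non-increasing.  If the target itself is in
#' stock, a single trivial zero-step route is returned with a message.
#'
#' @param target target molecule SMILES.
#' @param backward,forward predictor models.
#' @param stock character vector of available molecules (canonicalised
#'   internally), see [readStock()].
#' @param config a [plannerConfig()].
#' @param scorer complexity function, default [complexityScore()].
#' @return list of solved [Route-class] objects, best first (possibly
#'   empty).
#' @examples
#' sc <- makeRouteScenario(depth = 2, branching = 2, seed = 7)
#' routes <- planRoutes(sc$target, sc$backward, sc$forward, sc$stock,
#'                      plannerConfig(beamWidth = 4, maxDepth = 4))
#' @export
planRoutes <- function(target, backward, forward, stock,
                       config = plannerConfig(), scorer = complexityScore) {
    stopifnot(inherits(config, "plannerConfig"), length(stock) >= 1L)
    target <- canonicalize(target)
    stock <- unique(canonicalize(stock))
    if (target %in% stock) {
        message("target is already in stock; returning the trivial route")
        return(list(new("Route", target = target,
                        tree = .leafNode(target, TRUE), score = 1,
                        depth = 0L, solved = TRUE)))
    }
    beam <- list(list(tree = .leafNode(target, FALSE), score = 1))
    solved <- list()
    solvedKeys <- character(0)
    expCache <- new.env(parent = emptyenv())
    expandCached <- function(mol) {
        if (is.null(expCache[[mol]]))
            expCache[[mol]] <- expandMolecule(mol, backward, forward,
                                              k = config$k,
                                              lambda = config$lambda,
                                              scorer = scorer)
        expCache[[mol]]
    }
    for (depth in seq_len(config$maxDepth)) {
        nextBeam <- list()
        for (state in beam) {
            open <- .openLeaves(state$tree, stock)
            if (!length(open))
                next                     # already solved, handled below
            # candidate steps per open leaf, with the cycle guard
            perLeaf <- lapply(open, function(path) {
                anc <- .ancestors(state$tree, path)
                mol <- anc[length(anc)]
                Filter(function(s)
                    !any(s$precursors %in% anc), expandCached(mol))
            })
            if (any(lengths(perLeaf) == 0L))
                next                     # dead branch: an unexpandable leaf
            combos <- do.call(expand.grid,
                              c(lapply(perLeaf, seq_along),
                                KEEP.OUT.ATTRS = FALSE))
            for (ci in seq_len(nrow(combos))) {
                tree <- state$tree
                score <- state$score
                for (li in seq_along(open)) {
                    step <- perLeaf[[li]][[combos[ci, li]]]
                    tree <- .applyStep(tree, open[[li]], step, stock)
                    score <- score * step$combined_score
                }
                nextBeam[[length(nextBeam) + 1L]] <-
                    list(tree = tree, score = score)
            }
        }
        if (!length(nextBeam))
            break
        # collect newly solved routes, keep unsolved states in the beam
        open <- lapply(nextBeam, function(st) .openLeaves(st$tree, stock))
        isSolvedState <- lengths(open) == 0L
        for (st in nextBeam[isSolvedState]) {
            key <- .treeKey(st$tree)
            if (!key %in% solvedKeys) {
                solvedKeys <- c(solvedKeys, key)
                solved[[length(solved) + 1L]] <-
                    .routeFromState(target, st, stock)
            }
        }
        rest <- nextBeam[!isSolvedState]
        if (length(rest) > config$beamWidth) {
            scores <- vapply(rest, `[[`, 0.0, "score")
            keys <- vapply(rest, function(st) .treeKey(st$tree), "")
            rest <- rest[order(-scores, keys,
                               method = "radix")[seq_len(config$beamWidth)]]
        }
        beam <- rest
        if (!length(beam))
            break
    }
    if (length(solved) > 1L) {
        scores <- vapply(solved, function(r) r@score, 0.0)
        keys <- vapply(solved, function(r) .treeKey(r@tree), "")
        solved <- solved[order(-scores, keys, method = "radix")]
    }
    solved
}

## ---- Route accessors and serialisation ------------------------------------

#' Route accessors
#'
#' `routeLeaves()` returns the leaf molecules, `routeScore()` the product of
#' step scores, `routeDepth()` the longest step chain, `isSolved()` whether
#' every leaf was in the planning stock.
#'
#' @param x a [Route-class].
#' @return character vector / numeric / integer / logical.
#' @name routeLeaves
NULL

#' @rdname routeLeaves
setMethod("routeLeaves", "Route", function(x) .treeLeaves(x@tree))

#' @rdname routeLeaves
setMethod("routeScore", "Route", function(x) x@score)

#' @rdname routeLeaves
setMethod("routeDepth", "Route", function(x) x@depth)

#' @rdname routeLeaves
setMethod("isSolved", "Route", function(x) x@solved)

setMethod("show", "Route", function(object) {
    cat(sprintf("Route to %s: depth %d, score %.4g, %s\n", object@target,
                object@depth, object@score,
                if (object@solved) "solved" else "unsolved"))
    printNode <- function(node, indent) {
        marker <- if (!length(node$children)) {
            if (node$in_stock) " [stock]" else " [leaf]"
        } else sprintf("  <- EC %s (score %.3g)", node$step$ec,
                       node$step$combined_score)
        cat(strrep("  ", indent), node$smiles, marker, "\n", sep = "")
        for (ch in node$children) printNode(ch, indent + 1L)
    }
    printNode(object@tree, 1L)
})

.nodeToList <- function(node) {
    out <- list(molecule = node$smiles, in_stock = node$in_stock)
    if (!is.null(node$step))
        out$step <- list(ec = node$step$ec,
                         backward_confidence = node$step$backward_confidence,
                         forward_confidence = node$step$forward_confidence,
                         complexity = node$step$complexity,
                         combined_score = node$step$combined_score)
    out$children <- lapply(node$children, .nodeToList)
    out
}

.nodeFromList <- function(x) {
    node <- .leafNode(x$molecule, isTRUE(x$in_stock))
    if (!is.null(x$step))
        node$step <- list(ec = x$step$ec,
                          backward_confidence = x$step$backward_confidence,
                          forward_confidence = x$step$forward_confidence,
                          complexity = as.numeric(x$step$complexity),
                          combined_score = x$step$combined_score)
    node$children <- lapply(x$children, .nodeFromList)
    node
}

#' Serialise / parse a route as JSON
#'
#' Nested JSON: each node carries `molecule`, `in_stock`, an optional `step`
#' (ec, confidences, per-precursor complexity, combined score) and
#' `children`.  `parseRoute(serializeRoute(r))` reconstructs `r`.
#'
#' @param route a [Route-class].
#' @param json JSON text from `serializeRoute()`.
#' @return JSON text / a [Route-class].
#' @export
serializeRoute <- function(route) {
    stopifnot(is(route, "Route"))
    jsonlite::toJSON(list(target = route@target, score = route@score,
                          depth = route@depth, solved = route@solved,
                          tree = .nodeToList(route@tree)),
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' @rdname serializeRoute
#' @export
parseRoute <- function(json) {
    x <- jsonlite::fromJSON(json, simplifyVector = TRUE,
                            simplifyDataFrame = FALSE,
                            simplifyMatrix = FALSE)
    new("Route", target = x$target, tree = .nodeFromList(x$tree),
        score = as.numeric(x$score), depth = as.integer(x$depth),
        solved = isTRUE(x$solved))
}
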