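# Deterministic single-step predictor stubs and the EC-randomisation
# experiment.  The stubs stand behind the same contract an external
# sequence-model adapter must satisfy (ranks 1..k without gaps, confidences
# in [0,1] non-increasing, deterministic), so every evaluation and planning
# code path can be exercised without a trained model.

.fwdKey <- function(reactants, ecTxt)
    paste(paste(sort(reactants, method = "radix"), collapse = "."),
          ecTxt, sep = "|")

#' Exact-match forward lookup model
#'
#' Builds a forward predictor from a curated dataset: a query matches a
#' record when its sorted canonical reactants and its EC (at the dataset's
#' scheme) are identical to the record's.  Candidate products are ranked by
#' record multiplicity, then lexicographically; confidence is the normalised
#' multiplicity.
#'
#' @param dataset a [CuratedDataset-class].
#' @return a `LookupForwardModel`.
#' @seealso [forwardPredict()], [templateBackwardModel()]
#' @export
lookupForwardModel <- function(dataset) {
    stopifnot(is(dataset, "CuratedDataset"))
    index <- new.env(parent = emptyenv())
    recs <- curatedRecords(dataset)
    for (i in seq_len(nrow(recs))) {
        rxn <- parseReactionSmiles(recs$rxn_smiles[i])
        key <- .fwdKey(rxn@reactants, ecText(rxn@ec))
        tab <- index[[key]] %||% integer(0)
        prod <- rxn@products[1L]
        tab[prod] <- (if (prod %in% names(tab)) tab[[prod]] else 0L) + 1L
        index[[key]] <- tab
    }
    new("LookupForwardModel", index = index, scheme = dataset@scheme)
}

#' @rdname forwardPredict
setMethod("forwardPredict", "LookupForwardModel",
    function(object, reactants, ec = NULL, k = 5L) {
        reactants <- canonicalize(reactants)
        tab <- object@index[[.fwdKey(reactants, ecText(ECNumber(ec)))]]
        if (is.null(tab))
            return(.emptyForward())
        ord <- order(-tab, names(tab), method = "radix")
        n <- min(k, length(tab))
        conf <- as.numeric(tab[ord]) / sum(tab)
        data.frame(rank = seq_len(n), product = names(tab)[ord][seq_len(n)],
                   confidence = conf[seq_len(n)], stringsAsFactors = FALSE)
    })

.emptyForward <- function()
    data.frame(rank = integer(0), product = character(0),
               confidence = numeric(0), stringsAsFactors = FALSE)

.emptyBackward <- function()
    data.frame(rank = integer(0), precursors = character(0),
               ec = character(0), confidence = numeric(0),
               stringsAsFactors = FALSE)

#' Template backward model
#'
#' A backward predictor from deterministic rewrite rules: each rule maps a
#' canonical product to a set of precursors and an EC, with a positive
#' priority.  All rules whose product matches the query fire; candidates are
#' ranked by priority (ties broken lexicographically on the precursor
#' string) and confidences are priorities normalised over the applicable
#' rules.
#'
#' @param rules data.frame with columns `product`, `precursors` (dot-joined
#'   SMILES), `ec` (text), `priority` (positive numeric).
#' @return a `TemplateBackwardModel`.
#' @seealso [backwardPredict()], [lookupForwardModel()]
#' @export
templateBackwardModel <- function(rules) {
    rules$product <- canonicalize(rules$product)
    rules$precursors <- vapply(strsplit(rules$precursors, ".", fixed = TRUE),
        function(p) paste(sort(canonicalize(p), method = "radix"),
                          collapse = "."), "")
    new("TemplateBackwardModel", rules = rules)
}

#' @rdname backwardPredict
setMethod("backwardPredict", "TemplateBackwardModel",
    function(object, product, k = 5L) {
        product <- canonicalize(product)
        hits <- object@rules[object@rules$product == product, , drop = FALSE]
        if (!nrow(hits))
            return(.emptyBackward())
        hits <- hits[order(-hits$priority, hits$precursors,
                           method = "radix"), , drop = FALSE]
        n <- min(k, nrow(hits))
        data.frame(rank = seq_len(n),
                   precursors = hits$precursors[seq_len(n)],
                   ec = hits$ec[seq_len(n)],
                   confidence = (hits$priority / sum(hits$priority))[
                       seq_len(n)],
                   stringsAsFactors = FALSE)
    })

#' Function-backed predictor adapters
#'
#' Wrap an arbitrary R function as a forward or backward model — the
#' plug-in point for external single-step predictors.  The function receives
#' the query (`reactants, ec, k` / `product, k`) and must return a
#' prediction data.frame satisfying the single-step contract (validated with
#' [checkPredictionContract()] in tests, not on every call).
#'
#' @param fn the prediction function.
#' @return a `FunctionForwardModel` / `FunctionBackwardModel`.
#' @name functionModels
#' @export
functionForwardModel <- function(fn) new("FunctionForwardModel", fn = fn)

#' @rdname functionModels
#' @export
functionBackwardModel <- function(fn) new("FunctionBackwardModel", fn = fn)

#' @rdname forwardPredict
setMethod("forwardPredict", "FunctionForwardModel",
    function(object, reactants, ec = NULL, k = 5L)
        object@fn(reactants, ec, k))

#' @rdname backwardPredict
setMethod("backwardPredict", "FunctionBackwardModel",
    function(object, product, k = 5L) object@fn(product, k))

#' Validate the single-step prediction contract
#'
#' Checks that a prediction data.frame has ranks `1..k` without gaps and
#' confidences in \[0,1\] non-increasing with rank.  Used to validate
#' external predictor adapters.
#'
#' @param pred a prediction data.frame (forward or backward).
#' @return `TRUE`, invisibly; otherwise an error describing the violation.
#' @export
checkPredictionContract <- function(pred) {
    stopifnot(is.data.frame(pred))
    if (!all(c("rank", "confidence") %in% names(pred)))
        stop("prediction must have 'rank' and 'confidence' columns")
    if (nrow(pred)) {
        if (!identical(as.integer(pred$rank), seq_len(nrow(pred))))
            stop("ranks must be 1..k without gaps")
        if (any(pred$confidence < 0 | pred$confidence > 1))
            stop("confidences must lie in [0,1]")
        if (is.unsorted(rev(pred$confidence)))
            stop("confidences must be non-increasing in rank")
    }
    invisible(TRUE)
}

#' Randomise EC annotations of a test set
#'
#' Replaces each record's EC with one drawn uniformly from the ECs present
#' in the dataset, either sharing the record's level-1 class
#' (`"within_class"`) or belonging to a different class (`"across_class"`).
#' In within-class mode a record's own EC is excluded from the pool whenever
#' an alternative exists; a record whose class has no alternative EC is left
#' unchanged with a warning.  Substrates and products are untouched, so the
#' multiset of (reactants, product) pairs is preserved exactly.
#'
#' @param dataset a [CuratedDataset-class] whose records all carry an EC.
#' @param mode `"within_class"` or `"across_class"`.
#' @param seed integer seed; the same seed reproduces the same output.
#' @return a [CuratedDataset-class].
#' @export
randomizeEC <- function(dataset, mode = c("within_class", "across_class"),
                        seed = 42L) {
    mode <- match.arg(mode)
    stopifnot(is(dataset, "CuratedDataset"))
    recs <- curatedRecords(dataset)
    if (any(!nzchar(recs$ec)))
        stop("every record must carry an EC annotation")
    class1 <- vapply(strsplit(recs$ec, ".", fixed = TRUE),
                     function(x) x[1L], "")
    pool <- unique(data.frame(ec = recs$ec, class1 = class1,
                              stringsAsFactors = FALSE))
    newEC <- withr_seed(seed, vapply(seq_len(nrow(recs)), function(i) {
        if (mode == "within_class") {
            cand <- pool$ec[pool$class1 == class1[i] & pool$ec != recs$ec[i]]
            if (!length(cand)) {
                warning("no alternative EC in class ", class1[i],
                        "; record left unchanged")
                return(recs$ec[i])
            }
        } else {
            cand <- pool$ec[pool$class1 != class1[i]]
            if (!length(cand))
                stop("no EC outside class ", class1[i], " in the dataset")
        }
        cand[sample.int(length(cand), 1L)]
    }, ""))
    newSmiles <- vapply(seq_len(nrow(recs)), function(i)
        sub(paste0("\\|", gsub("\\.", "\\\\.", recs$ec[i]), ">>"),
            paste0("|", newEC[i], ">>"), recs$rxn_smiles[i]), "")
    out <- recs
    out$ec <- newEC
    out$rxn_smiles <- newSmiles
    new("CuratedDataset", scheme = dataset@scheme, records = out)
}
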