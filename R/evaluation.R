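# Accuracy metrics for single-step predictors: top-k (forward and backward),
# EC-only, round-trip, per-class breakdowns and the level-1 class confusion
# matrix.  Ground truth and predictions are compared as exact canonical
# strings (stereochemistry included); an ignoreStereo switch recomputes
# matches on stereo-stripped molecules, which is informative for isomerase
# chemistry where stereo assignment dominates the error modes.

#' Build evaluation records
#'
#' Runs a model over every record of a curated dataset and pairs the ranked
#' predictions with the ground truth.  `forwardEvalRecords()` queries the
#' forward model with (reactants, EC) and takes the product as truth;
#' `backwardEvalRecords()` queries the backward model with the product and
#' takes (precursor set, EC) as truth.
#'
#' @param dataset a [CuratedDataset-class].
#' @param model a forward / backward model.
#' @param k number of ranked candidates to request.
#' @return list of evaluation records; each has `truth` and a `predictions`
#'   data.frame.
#' @name evalRecords
#' @export
forwardEvalRecords <- function(dataset, model, k = 5L) {
    stopifnot(is(dataset, "CuratedDataset"))
    lapply(curatedRecords(dataset)$rxn_smiles, function(s) {
        rxn <- parseReactionSmiles(s)
        preds <- tryCatch(
            forwardPredict(model, rxn@reactants, rxn@ec, k = k),
            error = function(e) { message("forward model failure: ",
                                          conditionMessage(e))
                                  .emptyForward() })
        list(type = "forward",
             truth = list(product = rxn@products[1L], ec = ecText(rxn@ec)),
             predictions = preds)
    })
}

#' @rdname evalRecords
#' @export
backwardEvalRecords <- function(dataset, model, k = 5L) {
    stopifnot(is(dataset, "CuratedDataset"))
    lapply(curatedRecords(dataset)$rxn_smiles, function(s) {
        rxn <- parseReactionSmiles(s)
        preds <- tryCatch(
            backwardPredict(model, rxn@products[1L], k = k),
            error = function(e) { message("backward model failure: ",
                                          conditionMessage(e))
                                  .emptyBackward() })
        list(type = "backward",
             truth = list(
                 precursors = paste(sort(rxn@reactants, method = "radix"),
                                    collapse = "."),
                 ec = ecText(rxn@ec),
                 product = rxn@products[1L]),
             predictions = preds)
    })
}

#' Strip stereochemistry from SMILES
#'
#' Removes tetrahedral (`@`) and double-bond (`/`, `\`) stereo markers and
#' re-canonicalises.
#'
#' @param smiles character vector of single-molecule SMILES.
#' @return character vector of canonical stereo-free SMILES.
#' @export
stripStereo <- function(smiles) {
    s <- gsub("@", "", smiles, fixed = TRUE)
    s <- gsub("[/\\\\]", "", s)
    canonicalize(s)
}

.stripStereoSet <- function(dotted) {
    vapply(strsplit(dotted, ".", fixed = TRUE), function(p)
        paste(sort(stripStereo(p), method = "radix"), collapse = "."), "")
}

.recordHit <- function(rec, k, match = "full", ignoreStereo = FALSE) {
    preds <- utils::head(rec$predictions, k)
    if (!nrow(preds))
        return(FALSE)
    if (rec$type == "forward") {
        truth <- rec$truth$product
        got <- preds$product
        if (ignoreStereo) { truth <- stripStereo(truth)
                            got <- stripStereo(got) }
        return(any(got == truth))
    }
    ecOK <- preds$ec == rec$truth$ec
    if (match == "ec_only")
        return(any(ecOK))
    truthP <- rec$truth$precursors
    gotP <- preds$precursors
    if (ignoreStereo) { truthP <- .stripStereoSet(truthP)
                        gotP <- .stripStereoSet(gotP) }
    if (match == "precursors_only")
        return(any(gotP == truthP))
    any(ecOK & gotP == truthP)
}

#' Top-k prediction accuracy
#'
#' Fraction of records whose ground truth appears among the top `k`
#' predictions.  Forward records match on the exact canonical product;
#' backward records require both the precursor set (order-insensitive) and
#' the EC at the evaluation scheme to match — set `match = "precursors_only"`
#' to ignore the EC, or use [ecOnlyAccuracy()] for the EC-only variant.
#'
#' @param records list from [forwardEvalRecords()] / [backwardEvalRecords()].
#' @param k positive integer.
#' @param match `"full"` or `"precursors_only"` (backward records only).
#' @param ignoreStereo recompute matches on stereo-stripped strings.
#' @return accuracy in \[0,1\].
#' @export
topkAccuracy <- function(records, k, match = c("full", "precursors_only"),
                         ignoreStereo = FALSE) {
    match <- match.arg(match)
    stopifnot(k >= 1L)
    if (!length(records))
        stop("empty record list")
    mean(vapply(records, .recordHit, FALSE, k = k, match = match,
                ignoreStereo = ignoreStereo))
}

#' EC-only backward accuracy
#'
#' Like [topkAccuracy()] on backward records, but a prediction matches iff
#' its EC equals the true EC, ignoring precursors.  Always at least the full
#' backward accuracy at equal `k` (a strictly weaker predicate).
#'
#' @inheritParams topkAccuracy
#' @return accuracy in \[0,1\].
#' @export
ecOnlyAccuracy <- function(records, k) {
    stopifnot(k >= 1L)
    if (!length(records))
        stop("empty record list")
    if (any(vapply(records, function(r) r$type, "") != "backward"))
        stop("EC-only accuracy is defined for backward records")
    mean(vapply(records, .recordHit, FALSE, k = k, match = "ec_only"))
}

#' Round-trip accuracy
#'
#' For each target product, take the backward model's top-`k` proposals; a
#' proposal *round-trips* iff the forward model's rank-1 product on the
#' proposed (precursors, EC) equals the target.  A target counts as correct
#' iff any of its top-`k` proposals round-trips.  A model failure on a query
#' counts the record incorrect (logged).
#'
#' @param backward,forward models satisfying the predictor contract.
#' @param products character vector of target products.
#' @param k number of backward proposals to consider.
#' @return fraction of targets with at least one round-tripping proposal.
#' @export
roundTripAccuracy <- function(backward, forward, products, k = 1L) {
    stopifnot(k >= 1L, length(products) >= 1L)
    products <- canonicalize(products)
    mean(vapply(products, function(target) {
        props <- tryCatch(backwardPredict(backward, target, k = k),
                          error = function(e) {
                              message("backward failure on ", target, ": ",
                                      conditionMessage(e))
                              .emptyBackward() })
        if (!nrow(props)) return(FALSE)
        for (i in seq_len(nrow(props))) {
            fwd <- tryCatch(
                forwardPredict(forward,
                               strsplit(props$precursors[i], ".",
                                        fixed = TRUE)[[1]],
                               ECNumber(props$ec[i]), k = 1L),
                error = function(e) {
                    message("forward failure: ", conditionMessage(e))
                    .emptyForward() })
            if (nrow(fwd) && fwd$product[1L] == target)
                return(TRUE)
        }
        FALSE
    }, FALSE, USE.NAMES = FALSE))
}

#' Per-class accuracy breakdown
#'
#' Groups evaluation records by their true EC truncated to `level` (1 =
#' enzyme class, 3 = sub-subclass) and reports the sample count and top-k
#' accuracies for k in 1..5 per group.
#'
#' @param records evaluation records, every one carrying a true EC.
#' @param level 1 or 3.
#' @return data.frame with columns `group`, `n`, `top1`..`top5`.
#' @export
classBreakdown <- function(records, level = 1L) {
    stopifnot(level %in% c(1L, 3L))
    ecs <- vapply(records, function(r) r$truth$ec, "")
    if (any(!nzchar(ecs)))
        stop("every record must carry a true EC")
    key <- vapply(ecs, function(e) {
        lv <- ecLevels(ECNumber(e))
        ecText(ECNumber(lv[seq_len(min(level, length(lv)))]))
    }, "", USE.NAMES = FALSE)
    groups <- split(seq_along(records), key)
    out <- do.call(rbind, lapply(names(groups), function(g) {
        idx <- groups[[g]]
        accs <- vapply(1:5, function(k)
            topkAccuracy(records[idx], k), 0.0)
        data.frame(group = g, n = length(idx),
                   top1 = accs[1], top2 = accs[2], top3 = accs[3],
                   top4 = accs[4], top5 = accs[5],
                   stringsAsFactors = FALSE)
    }))
    out[order(out$group), , drop = FALSE]
}

#' Enzyme-class confusion matrix
#'
#' Cross-tabulates the true level-1 class of each backward record against
#' the class of its rank-1 predicted EC.  Records with no prediction fall in
#' the `"none"` column.  Row sums equal the per-class record counts.
#'
#' @param records backward evaluation records.
#' @return 7 x 8 integer matrix, rows classes 1..7, columns 1..7 plus
#'   `"none"`.
#' @export
confusionMatrixLevel1 <- function(records) {
    cm <- matrix(0L, nrow = 7L, ncol = 8L,
                 dimnames = list(true = as.character(1:7),
                                 predicted = c(as.character(1:7), "none")))
    for (r in records) {
        if (r$type != "backward")
            stop("confusion matrix is defined for backward records")
        trueC <- as.character(ecLevels(ECNumber(r$truth$ec))[1L])
        predC <- if (nrow(r$predictions))
            as.character(ecLevels(ECNumber(r$predictions$ec[1L]))[1L])
        else "none"
        cm[trueC, predC] <- cm[trueC, predC] + 1L
    }
    cm
}
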