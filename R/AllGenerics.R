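#' Run a forward single-step prediction
#'
#' @param object a [ForwardModel][PredictorModels].
#' @param reactants character vector of reactant SMILES.
#' @param ec an [ECNumber-class], EC text, or `NULL` for no EC conditioning.
#' @param k maximum number of ranked candidates.
#' @return data.frame with columns `rank`, `product`, `confidence`
#'   (possibly zero rows).
#' @seealso [backwardPredict()], [checkPredictionContract()]
#' @export
setGeneric("forwardPredict", function(object, reactants, ec = NULL, k = 5L)
    standardGeneric("forwardPredict"))

#' Run a backward single-step prediction
#'
#' @param object a [BackwardModel][PredictorModels].
#' @param product product SMILES.
#' @param k maximum number of ranked candidates.
#' @return data.frame with columns `rank`, `precursors` (dot-joined, sorted
#'   canonical SMILES), `ec` (text), `confidence` (possibly zero rows).
#' @seealso [forwardPredict()], [checkPredictionContract()]
#' @export
setGeneric("backwardPredict", function(object, product, k = 5L)
    standardGeneric("backwardPredict"))

#' Truncate an EC number to a given depth
#'
#' Keeps the first `level` fields of an EC number; `level = 0` yields the
#' absent EC.  Requesting more levels than are present is an error (levels
#' are never invented).
#'
#' @param ec an [ECNumber-class] or EC text such as `"5.4.99.16"`.
#' @param level integer 0..4.
#' @return an [ECNumber-class] (zero levels when `level = 0`).
#' @examples
#' truncateEC(ECNumber("5.4.99.16"), 3)
#' @export
setGeneric("truncateEC", function(ec, level) standardGeneric("truncateEC"))

#' @rdname curatedRecords
#' @export
setGeneric("curatedRecords", function(x) standardGeneric("curatedRecords"))

#' @rdname curatedRecords
#' @export
setGeneric("tokenScheme", function(x) standardGeneric("tokenScheme"))

#' @rdname ecLevels
#' @export
setGeneric("ecLevels", function(x) standardGeneric("ecLevels"))

#' @rdname ecLevels
#' @export
setGeneric("ecText", function(x) standardGeneric("ecText"))

#' @rdname routeLeaves
#' @export
setGeneric("routeLeaves", function(x) standardGeneric("routeLeaves"))

#' @rdname routeLeaves
#' @export
setGeneric("routeScore", function(x) standardGeneric("routeScore"))

#' @rdname routeLeaves
#' @export
setGeneric("routeDepth", function(x) standardGeneric("routeDepth"))

#' @rdname routeLeaves
#' @export
setGeneric("isSolved", function(x) standardGeneric("isSolved"))
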