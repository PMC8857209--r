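#' @import methods
NULL

#' Enzyme Commission number
#'
#' An EC number is a hierarchical identifier with one to four levels
#' (class.subclass.sub-subclass.serial).  Level 1 denotes the enzyme class
#' (1 oxidoreductases, 2 transferases, 3 hydrolases, 4 lyases, 5 isomerases,
#' 6 ligases, 7 translocases); deeper levels refine the catalysed chemistry.
#' A zero-length `levels` slot represents an absent EC annotation (the EC0
#' token scheme).
#'
#' @slot levels integer vector of length 0 to 4; contiguous from level 1,
#'   level-1 field in 1..7, all fields positive.
#' @seealso [ECNumber()], [truncateEC()], [ecLevels()]
#' @exportClass ECNumber
setClass("ECNumber", representation(levels = "integer"))

setValidity("ECNumber", function(object) {
    lv <- object@levels
    if (length(lv) > 4L)
        return("an EC number has at most 4 levels")
    if (anyNA(lv) || any(lv < 1L))
        return("EC fields must be positive integers")
    if (length(lv) >= 1L && (lv[1L] < 1L || lv[1L] > 7L))
        return(sprintf("EC class (level 1) must be in 1..7, got %d", lv[1L]))
    TRUE
})

#' Enzymatic reaction
#'
#' A reaction with reactants, optional reagents (the middle field of a
#' three-part reaction SMILES), an optional EC number, products and a
#' free-text provenance tag.  Serialises to an (enzymatic) reaction SMILES:
#' `reactants(|EC)?>reagents>products` or `reactants(|EC)?>>products`.
#'
#' @slot reactants,reagents,products character vectors of SMILES (possibly
#'   empty).
#' @slot ec an [ECNumber-class]; zero levels means no EC annotation.
#' @slot source free-text provenance tag (single string, may be `""`).
#' @seealso [parseReactionSmiles()], [formatReactionSmiles()]
#' @exportClass EnzymaticReaction
setClass("EnzymaticReaction",
    representation(reactants = "character", reagents = "character",
                   ec = "ECNumber", products = "character",
                   source = "character"))

setValidity("EnzymaticReaction", function(object) {
    if (length(object@source) != 1L)
        return("source must be a single string")
    if (anyNA(c(object@reactants, object@reagents, object@products)))
        return("molecule lists must not contain NA")
    TRUE
})

#' Curated reaction dataset
#'
#' A deduplicated set of single-product enzymatic reactions at a fixed EC
#' token scheme (EC0..EC4: EC annotations truncated to 0..4 levels).  Records
#' are stored as canonical extended reaction SMILES with lexicographically
#' sorted reactants; provenance of merged duplicates is kept as a
#' semicolon-joined source list.
#'
#' @slot scheme one of `"EC0".."EC4"`.
#' @slot records data.frame with columns `rxn_smiles` (canonical extended
#'   reaction SMILES), `ec` (dot-joined EC text, `""` when absent) and
#'   `sources`.
#' @seealso [curate()], [productDisjointSplit()], [curatedRecords()]
#' @exportClass CuratedDataset
setClass("CuratedDataset",
    representation(scheme = "character", records = "data.frame"))

setValidity("CuratedDataset", function(object) {
    if (!(object@scheme %in% paste0("EC", 0:4)))
        return("scheme must be one of EC0..EC4")
    need <- c("rxn_smiles", "ec", "sources")
    if (!all(need %in% names(object@records)))
        return(sprintf("records must have columns %s",
                       paste(need, collapse = ", ")))
    # uniqueness on the canonical extended reaction SMILES is established by
    # curate(); EC-randomised variants may legitimately collide, so it is
    # not enforced here
    TRUE
})

#' Single-step predictor models
#'
#' `ForwardModel` and `BackwardModel` are virtual classes for pluggable
#' single-step predictors.  A forward model maps (reactants, EC) to ranked
#' candidate products; a backward model maps a product to ranked candidate
#' (precursors, EC) disconnections.  Predictions obey the single-step
#' contract: ranks 1..k without gaps, confidences in \[0,1\] non-increasing
#' with rank, deterministic for fixed input.
#'
#' Shipped implementations: [lookupForwardModel()] (exact-match table lookup,
#' confidence = normalised record multiplicity), [templateBackwardModel()]
#' (deterministic product -> precursor rewrite rules, confidence = normalised
#' rule priority), and `functionForwardModel()`/`functionBackwardModel()`
#' adapters wrapping an arbitrary R function, the hook for external models.
#'
#' @name PredictorModels
#' @aliases ForwardModel-class BackwardModel-class
#'   LookupForwardModel-class TemplateBackwardModel-class
#'   FunctionForwardModel-class FunctionBackwardModel-class
#' @exportClass ForwardModel
#' @exportClass BackwardModel
#' @exportClass LookupForwardModel
#' @exportClass TemplateBackwardModel
#' @exportClass FunctionForwardModel
#' @exportClass FunctionBackwardModel
setClass("ForwardModel", representation("VIRTUAL"))

#' @rdname PredictorModels
setClass("BackwardModel", representation("VIRTUAL"))

#' @rdname PredictorModels
setClass("LookupForwardModel", contains = "ForwardModel",
    representation(index = "environment", scheme = "character"))

#' @rdname PredictorModels
setClass("TemplateBackwardModel", contains = "BackwardModel",
    representation(rules = "data.frame"))

setValidity("TemplateBackwardModel", function(object) {
    need <- c("product", "precursors", "ec", "priority")
    if (!all(need %in% names(object@rules)))
        return(sprintf("rules must have columns %s", paste(need, collapse = ", ")))
    if (any(object@rules$priority <= 0))
        return("rule priorities must be positive")
    TRUE
})

#' @rdname PredictorModels
setClass("FunctionForwardModel", contains = "ForwardModel",
    representation(fn = "function"))

#' @rdname PredictorModels
setClass("FunctionBackwardModel", contains = "BackwardModel",
    representation(fn = "function"))

#' Retrosynthetic route
#'
#' A tree of synthesis steps rooted at the target molecule.  Each internal
#' node records the disconnection applied to its molecule (precursors, EC,
#' backward/forward confidences, precursor complexities and the combined step
#' score); leaves are molecules left unexpanded.  A route is *solved* when
#' every leaf is in the stock it was planned against.  The route score is the
#' product of its step scores.
#'
#' @slot target canonical SMILES of the route target.
#' @slot tree nested list of nodes (`smiles`, `in_stock`, `step`, `children`).
#' @slot score numeric route score in \[0,1\].
#' @slot depth integer, longest step chain in the tree (0 for a trivial route).
#' @slot solved logical.
#' @seealso [planRoutes()], [serializeRoute()], [routeLeaves()]
#' @exportClass Route
setClass("Route",
    representation(target = "character", tree = "list", score = "numeric",
                   depth = "integer", solved = "logical"))
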