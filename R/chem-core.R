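# Molecule-level plumbing: one fixed canonical SMILES form (OpenBabel
# canonical SMILES through ChemmineOB), heavy-atom counting from the token
# stream, and the EC number type.

.canonCache <- new.env(parent = emptyenv())

.obCanonical <- function(smiles) {
    # one batch call; OpenBabel stops emitting at the first invalid entry,
    # so realign by the index carried in the SMILES title field
    src <- paste(sprintf("%s i%d", smiles, seq_along(smiles)), collapse = "\n")
    out <- ChemmineOB::convertFormat("SMI", "CAN", source = src)
    lines <- strsplit(out, "\n", fixed = TRUE)[[1]]
    lines <- lines[nzchar(lines)]
    res <- rep(NA_character_, length(smiles))
    if (length(lines)) {
        parts <- strsplit(lines, "\t", fixed = TRUE)
        idx <- as.integer(sub("^i", "", vapply(parts, `[`, "", 2L)))
        res[idx] <- vapply(parts, `[`, "", 1L)
    }
    res
}

#' Canonicalise SMILES
#'
#' Converts SMILES to a single fixed canonical form (OpenBabel canonical
#' SMILES).  Every comparison, deduplication and stock-membership test in the
#' package goes through this one canonicaliser, so "the same molecule written
#' differently" always collapses to one string.  Stereochemistry is preserved
#' verbatim; isomeric SMILES are not normalised away.  Idempotent: applying it
#' to its own output is the identity.
#'
#' Results are memoised per session, which makes repeated curation and
#' planning over a closed molecule alphabet cheap.
#'
#' @param smiles character vector of SMILES strings.
#' @return character vector of canonical SMILES, same length.
#' @examples
#' canonicalize(c("OCC", "CCO"))   # both map to the same string
#' @export
canonicalize <- function(smiles) {
    if (!is.character(smiles))
        stop("'smiles' must be a character vector")
    if (length(smiles) == 0L)
        return(character(0))
    if (anyNA(smiles) || any(!nzchar(smiles)))
        stop("SMILES must be non-empty strings")
    if (any(grepl("[[:space:]]", smiles)))
        stop("SMILES must not contain whitespace: ",
             smiles[grepl("[[:space:]]", smiles)][1L])
    res <- rep(NA_character_, length(smiles))
    hit <- vapply(smiles, function(s) !is.null(.canonCache[[s]]), FALSE)
    res[hit] <- vapply(smiles[hit], function(s) .canonCache[[s]], "")
    todo <- unique(smiles[!hit])
    if (length(todo)) {
        can <- .obCanonical(todo)
        bad <- is.na(can)
        if (any(bad)) {
            # batch conversion aborts at the first failure; retry the
            # unresolved ones one-by-one so only true parse errors remain
            for (i in which(bad))
                can[i] <- .obCanonical(todo[i])
            bad <- is.na(can)
        }
        if (any(bad))
            stop("invalid SMILES: ", paste(todo[bad], collapse = ", "))
        for (i in seq_along(todo))
            .canonCache[[todo[i]]] <- can[i]
        res[!hit] <- can[match(smiles[!hit], todo)]
    }
    res
}

#' Count heavy (non-hydrogen) atoms
#'
#' Counts the atoms of a molecule other than hydrogen, directly from the
#' SMILES token stream: every atom token counts except bracket atoms whose
#' element is hydrogen (`[H]`, isotopes, hydrogen ions).  The count is
#' invariant under rewriting the same molecule as a different SMILES string.
#'
#' @param smiles character vector of SMILES strings (single molecules).
#' @return integer vector of heavy-atom counts.
#' @examples
#' heavyAtomCount(c("O", "CC(=O)O", "CC(=O)OCC"))  # 1, 4, 6
#' @export
heavyAtomCount <- function(smiles) {
    vapply(smiles, function(s) {
        tok <- tokenizeMolecular(s)
        sum(.isHeavyAtomToken(tok))
    }, 0L, USE.NAMES = FALSE)
}

.ATOM_ORGANIC <- c("B", "C", "N", "O", "S", "P", "F", "Cl", "Br", "I",
                   "b", "c", "n", "o", "s", "p")

.isHeavyAtomToken <- function(tokens) {
    bracket <- startsWith(tokens, "[")
    # hydrogen bracket atoms: [H], [2H], [H+], ... ("Hg" etc. fail the match)
    isH <- bracket & grepl("^\\[[0-9]*H[0-9+-]*\\]$", tokens)
    (bracket & !isH) | tokens %in% .ATOM_ORGANIC
}

## ---- EC numbers -----------------------------------------------------------

#' Construct an EC number
#'
#' @param x dot-joined EC text (e.g. `"5.4.99"`), an integer vector of 0-4
#'   fields, or an existing [ECNumber-class].  `""`, `NA` and `NULL` give the
#'   absent EC (zero levels).
#' @return an [ECNumber-class].
#' @examples
#' ECNumber("1.14.13.7")
#' ECNumber(NULL)        # absent
#' @export
ECNumber <- function(x = NULL) {
    if (is(x, "ECNumber"))
        return(x)
    if (is.null(x) || (is.character(x) && length(x) == 1L &&
                       (is.na(x) || !nzchar(x))))
        return(new("ECNumber", levels = integer(0)))
    if (is.numeric(x)) {
        lv <- as.integer(x)
        if (any(lv != x)) stop("EC fields must be integers")
        return(new("ECNumber", levels = lv))
    }
    if (!is.character(x) || length(x) != 1L)
        stop("'x' must be EC text, an integer vector, or NULL")
    fields <- strsplit(x, ".", fixed = TRUE)[[1]]
    if (length(fields) == 0L || any(!grepl("^[0-9]+$", fields)))
        stop("malformed EC number: '", x, "'")
    new("ECNumber", levels = as.integer(fields))
}

#' EC number accessors
#'
#' `ecLevels()` returns the integer fields, `ecText()` the dot-joined text
#' (`""` for an absent EC), `ecIsAbsent()` tests for the absent EC.
#'
#' @param x an [ECNumber-class] (for `ecText`, also a list of them).
#' @return integer vector / character / logical.
#' @name ecLevels
#' @examples
#' ecLevels(ECNumber("2.7.1"))
#' ecText(ECNumber("2.7.1"))
NULL

#' @rdname ecLevels
setMethod("ecLevels", "ECNumber", function(x) x@levels)

#' @rdname ecLevels
setMethod("ecText", "ECNumber", function(x)
    paste(x@levels, collapse = "."))

#' @rdname ecLevels
#' @export
ecIsAbsent <- function(x) length(ecLevels(ECNumber(x))) == 0L

setMethod("show", "ECNumber", function(object) {
    if (ecIsAbsent(object)) cat("<EC absent>\n")
    else cat("EC", ecText(object), "\n")
})

#' @rdname truncateEC
setMethod("truncateEC", signature(ec = "ECNumber", level = "numeric"),
    function(ec, level) {
        level <- as.integer(level)
        if (level < 0L || level > 4L)
            stop("'level' must be in 0..4")
        if (level > length(ec@levels))
            stop(sprintf("cannot truncate EC '%s' (%d levels) to %d levels",
                         ecText(ec), length(ec@levels), level))
        new("ECNumber", levels = ec@levels[seq_len(level)])
    })

#' @rdname truncateEC
setMethod("truncateEC", signature(ec = "character", level = "numeric"),
    function(ec, level) truncateEC(ECNumber(ec), level))

.schemeLevel <- function(scheme) {
    m <- match(scheme, paste0("EC", 0:4))
    if (is.na(m)) stop("scheme must be one of EC0..EC4, got '", scheme, "'")
    m - 1L
}

## ---- enzymatic reactions --------------------------------------------------

#' Construct an enzymatic reaction
#'
#' @param reactants,reagents,products character vectors of SMILES.
#' @param ec EC text, [ECNumber-class] or `NULL`.
#' @param source free-text provenance tag.
#' @return an [EnzymaticReaction-class].
#' @examples
#' EnzymaticReaction(reactants = "CCO", ec = "1.1.1", products = "CC=O")
#' @export
EnzymaticReaction <- function(reactants = character(0),
                              reagents = character(0),
                              ec = NULL,
                              products = character(0),
                              source = "") {
    new("EnzymaticReaction",
        reactants = as.character(reactants),
        reagents = as.character(reagents),
        ec = ECNumber(ec),
        products = as.character(products),
        source = as.character(source))
}

#' Reaction accessors
#'
#' @param x an [EnzymaticReaction-class].
#' @return character vector of SMILES, or the [ECNumber-class].
#' @name reactants
#' @export
reactants <- function(x) x@reactants

#' @rdname reactants
#' @export
reagents <- function(x) x@reagents

#' @rdname reactants
#' @export
products <- function(x) x@products

#' @rdname reactants
#' @export
reactionEC <- function(x) x@ec

setMethod("show", "EnzymaticReaction", function(object) {
    cat("EnzymaticReaction:", formatReactionSmiles(object), "\n")
    if (nzchar(object@source)) cat("  source:", object@source, "\n")
})

.splitMolecules <- function(side)
    if (nzchar(side)) strsplit(side, ".", fixed = TRUE)[[1]] else character(0)

#' Parse a reaction SMILES or enzymatic reaction SMILES
#'
#' Accepts the two-part form `reactants>>products` and the three-part form
#' `reactants>reagents>products`, each with an optional `|EC` suffix on the
#' reactant side (e.g. `"CCO|1.1.1>>CC=O"`).  Both the ASCII pipe `|` and the
#' U+2223 divides character are accepted as the EC delimiter.  Molecules on
#' each side are split on `.`.
#'
#' @param text a single reaction SMILES string.
#' @param source optional provenance tag attached to the parsed record.
#' @return an [EnzymaticReaction-class].
#' @examples
#' parseReactionSmiles("CC(=O)O.OCC>OS(=O)(=O)O>CC(=O)OCC.O")
#' parseReactionSmiles("CCO|1.1.1>>CC=O")
#' @export
parseReactionSmiles <- function(text, source = "") {
    if (!is.character(text) || length(text) != 1L || is.na(text))
        stop("'text' must be a single string")
    text <- gsub("∣", "|", text)
    parts <- strsplit(text, ">", fixed = TRUE)[[1]]
    # strsplit drops a trailing empty field: "a>>" -> c("a",""); pad
    if (endsWith(text, ">")) parts <- c(parts, "")
    if (length(parts) != 3L)
        stop("malformed reaction SMILES (expected 'r>a>p' or 'r>>p', found ",
             length(parts) - 1L, " '>' separators): '", text, "'")
    lhs <- strsplit(parts[1L], "|", fixed = TRUE)[[1]]
    if (length(lhs) > 2L)
        stop("malformed reactant side (multiple '|') at position ",
             regexpr("|", parts[1L], fixed = TRUE), ": '", text, "'")
    ec <- if (length(lhs) == 2L) {
        tryCatch(ECNumber(lhs[2L]), error = function(e)
            stop("malformed EC field '", lhs[2L], "' in '", text, "'",
                 call. = FALSE))
    } else NULL
    EnzymaticReaction(
        reactants = .splitMolecules(if (length(lhs)) lhs[1L] else ""),
        reagents = .splitMolecules(parts[2L]),
        ec = ec,
        products = .splitMolecules(parts[3L]),
        source = source)
}

#' Serialise a reaction to (enzymatic) reaction SMILES
#'
#' The inverse of [parseReactionSmiles()]: emits the three-part form when
#' reagents are present, the two-part form otherwise, with the EC (when
#' present) appended to the reactant side using the ASCII `|` delimiter.
#'
#' @param rxn an [EnzymaticReaction-class].
#' @return a single string.
#' @examples
#' formatReactionSmiles(EnzymaticReaction(reactants = "CCO", ec = "1.1.1",
#'                                        products = "CC=O"))
#' @export
formatReactionSmiles <- function(rxn) {
    stopifnot(is(rxn, "EnzymaticReaction"))
    lhs <- paste(rxn@reactants, collapse = ".")
    if (!ecIsAbsent(rxn@ec))
        lhs <- paste0(lhs, "|", ecText(rxn@ec))
    mid <- paste(rxn@reagents, collapse = ".")
    rhs <- paste(rxn@products, collapse = ".")
    if (length(rxn@reagents)) paste0(lhs, ">", mid, ">", rhs)
    else paste0(lhs, ">>", rhs)
}

#' Fold reagents into reactants (two-part enzymatic form)
#'
#' The enzymatic reaction SMILES grammar `A|EC>>B` has no agents field;
#' converting a three-part reaction moves the middle field onto the reactant
#' side.
#'
#' @param rxn an [EnzymaticReaction-class].
#' @return an [EnzymaticReaction-class] with empty reagents.
#' @export
asEnzymatic <- function(rxn) {
    stopifnot(is(rxn, "EnzymaticReaction"))
    if (!length(rxn@reagents)) return(rxn)
    EnzymaticReaction(reactants = c(rxn@reactants, rxn@reagents),
                      ec = rxn@ec, products = rxn@products,
                      source = rxn@source)
}

#' Canonicalise all molecules of a reaction
#'
#' Applies [canonicalize()] to every reactant, reagent and product.  Molecule
#' order is preserved (deduplication keys sort reactants separately, see
#' [extendedReactionSmiles()]).
#'
#' @param rxn an [EnzymaticReaction-class].
#' @return an [EnzymaticReaction-class].
#' @export
canonicalizeReaction <- function(rxn) {
    stopifnot(is(rxn, "EnzymaticReaction"))
    EnzymaticReaction(
        reactants = canonicalize(rxn@reactants),
        reagents = if (length(rxn@reagents)) canonicalize(rxn@reagents)
                   else character(0),
        ec = rxn@ec, products = if (length(rxn@products))
            canonicalize(rxn@products) else character(0),
        source = rxn@source)
}

#' Canonical extended reaction SMILES (deduplication key)
#'
#' Serialises a reaction in the two-part enzymatic form with canonicalised
#' molecules and lexicographically sorted reactants, so that the same
#' reaction-EC combination always yields the same string regardless of input
#' molecule order or SMILES spelling.
#'
#' @param rxn an [EnzymaticReaction-class].
#' @return a single string.
#' @export
extendedReactionSmiles <- function(rxn) {
    rxn <- canonicalizeReaction(asEnzymatic(rxn))
    formatReactionSmiles(EnzymaticReaction(
        reactants = sort(rxn@reactants, method = "radix"),
        ec = rxn@ec,
        products = rxn@products,
        source = rxn@source))
}
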