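# Token-level encoding of (enzymatic) reaction SMILES for sequence models.
#
# Molecular tokens follow the standard reaction-prediction regex: bracket
# atoms, the two-letter organic-subset atoms Cl/Br, ring-closure digits and
# %nn labels are kept whole, everything else is a single character.  EC
# annotations become one token per hierarchy level, each carrying the full
# path of fields down to that level and encapsulated in brackets with a
# level prefix (v, u, t, s for levels 1-4), e.g. EC 5.4.99 ->
# [v5] [u5.4] [t5.4.99].  Cumulative paths keep tokens unique per hierarchy
# branch, so "[u1.1]" (oxidoreductase subclass) can never alias "[u2.1]".

.SMILES_TOKEN_RE <- paste0(
    "(\\[[^][]+\\]|Br?|Cl?|N|O|S|P|F|I|b|c|n|o|s|p|\\(|\\)|\\.|=|#|-|\\+|",
    "\\\\|/|:|~|@|\\?|>|\\*|\\$|%[0-9]{2}|[0-9])")

.EC_TOKEN_RE <- "^\\[[vuts][0-9]+(\\.[0-9]+)*\\]$"

.EC_PREFIXES <- c("v", "u", "t", "s")

#' Tokenise a molecular SMILES string
#'
#' Splits SMILES (a single molecule, a dot-joined set, or a full reaction
#' without an EC field) into atom-level tokens.  Multi-character bracket
#' atoms, `Cl`/`Br`, and two-digit `%nn` ring closures stay whole.
#'
#' @param text SMILES text.
#' @return character vector of tokens whose concatenation is `text`.
#' @examples
#' tokenizeMolecular("CC(=O)O")
#' tokenizeMolecular("ClCCBr")
#' @export
tokenizeMolecular <- function(text) {
    if (!is.character(text) || length(text) != 1L || is.na(text))
        stop("'text' must be a single string")
    if (!nzchar(text))
        return(character(0))
    m <- gregexpr(.SMILES_TOKEN_RE, text, perl = TRUE)[[1]]
    tokens <- regmatches(text, list(m))[[1]]
    if (paste(tokens, collapse = "") != text)
        stop("characters outside the SMILES alphabet in '", text, "'")
    tokens
}

#' EC tokens for a token scheme
#'
#' Produces one bracketed token per EC level, prefixes `v`, `u`, `t`, `s`
#' for levels 1-4, each carrying the cumulative field path
#' (`[v5] [u5.4] [t5.4.99]` for EC 5.4.99 under scheme `"EC3"`).  The EC must
#' already be truncated to the scheme's depth; scheme `"EC0"` with a present
#' EC is an error.
#'
#' @param ec an [ECNumber-class] or EC text.
#' @param scheme one of `"EC0".."EC4"`.
#' @return character vector of EC tokens (length = scheme level).
#' @examples
#' tokenizeEC("5.4.99", "EC3")
#' @export
tokenizeEC <- function(ec, scheme) {
    ec <- ECNumber(ec)
    k <- .schemeLevel(scheme)
    lv <- ecLevels(ec)
    if (k == 0L) {
        if (length(lv))
            stop("scheme EC0 admits no EC; truncate first")
        return(character(0))
    }
    if (length(lv) != k)
        stop(sprintf("EC '%s' has %d levels; scheme %s requires exactly %d ",
                     ecText(ec), length(lv), scheme, k),
             "(truncate first)")
    vapply(seq_len(k), function(i)
        sprintf("[%s%s]", .EC_PREFIXES[i],
                paste(lv[seq_len(i)], collapse = ".")), "")
}

.isECToken <- function(tokens) grepl(.EC_TOKEN_RE, tokens)

#' Tokenise an enzymatic reaction SMILES
#'
#' Tokenises the reactant side, appends the EC tokens (between the reactant
#' tokens and the reaction arrow), then the arrow and the product side.  The
#' `>>` arrow is emitted as two `">"` tokens; seq2seq file writers split the
#' sequence at the arrow (see [writeTokenFiles()]), so the arrow itself never
#' travels inside one side.
#'
#' @param text enzymatic reaction SMILES (two-part, optional `|EC`), or a
#'   plain three-part reaction SMILES without EC.
#' @param scheme one of `"EC0".."EC4"`; the EC depth of `text` must match.
#' @return character vector of tokens.
#' @examples
#' tokenizeEnzymatic("CCO|1.1.1>>CC=O", "EC3")
#' @export
tokenizeEnzymatic <- function(text, scheme = "EC0") {
    if (!is.character(text) || length(text) != 1L || is.na(text))
        stop("'text' must be a single string")
    text <- gsub("∣", "|", text)
    parts <- strsplit(text, ">", fixed = TRUE)[[1]]
    if (endsWith(text, ">")) parts <- c(parts, "")
    if (length(parts) != 3L)
        stop("malformed reaction SMILES: '", text, "'")
    lhs <- strsplit(parts[1L], "|", fixed = TRUE)[[1]]
    ecTokens <- if (length(lhs) == 2L) tokenizeEC(ECNumber(lhs[2L]), scheme)
        else tokenizeEC(NULL, scheme)
    c(tokenizeMolecular(if (length(lhs)) lhs[1L] else ""),
      ecTokens,
      ">", tokenizeMolecular(parts[2L]),
      ">", tokenizeMolecular(parts[3L]))
}

#' Detokenise a token sequence
#'
#' Exact inverse of [tokenizeEnzymatic()] (and of [tokenizeMolecular()] for
#' sequences without EC or arrow tokens): concatenates tokens and restores
#' the `|EC` field in front of the reaction arrow from the EC tokens.  EC
#' tokens must form a consistent cumulative path (`[v5] [u5.4] ...`).
#'
#' @param tokens non-empty character vector of tokens.
#' @return the reconstructed text.
#' @examples
#' detokenize(tokenizeEnzymatic("CCO|1.1.1>>CC=O", "EC3"))
#' @export
detokenize <- function(tokens) {
    if (!is.character(tokens) || length(tokens) == 0L)
        stop("'tokens' must be a non-empty character vector")
    if (any(!nzchar(tokens)) || anyNA(tokens))
        stop("tokens must be non-empty strings")
    ec <- which(.isECToken(tokens))
    ecText <- ""
    if (length(ec)) {
        paths <- sub("^\\[[vuts]", "", sub("\\]$", "", tokens[ec]))
        prefixes <- substr(tokens[ec], 2L, 2L)
        depths <- lengths(strsplit(paths, ".", fixed = TRUE))
        ord <- order(depths)
        paths <- paths[ord]; prefixes <- prefixes[ord]; depths <- depths[ord]
        ok <- identical(depths, seq_along(depths)) &&
            identical(prefixes, .EC_PREFIXES[depths])
        if (ok && length(paths) > 1L)
            ok <- all(startsWith(paths[-1L],
                                 paste0(paths[-length(paths)], ".")))
        if (!ok)
            stop("malformed EC token path: ",
                 paste(tokens[ec], collapse = " "))
        ecText <- paths[length(paths)]
        tokens <- tokens[-ec]
    }
    if (nzchar(ecText)) {
        arrow <- which(tokens == ">")[1L]
        if (is.na(arrow))
            stop("EC tokens present but no reaction arrow")
        paste0(paste(tokens[seq_len(arrow - 1L)], collapse = ""),
               "|", ecText,
               paste(tokens[seq(arrow, length(tokens))], collapse = ""))
    } else {
        paste(tokens, collapse = "")
    }
}

#' Write seq2seq source/target token files
#'
#' Emits the standard sequence-model data layout: one space-separated token
#' sequence per line, source = reactant tokens + EC tokens, target = product
#' tokens; the reaction arrow marks the split and appears in neither file.
#'
#' @param dataset a [CuratedDataset-class].
#' @param srcPath,tgtPath output file paths.
#' @return invisibly, a list with the `src` and `tgt` lines.
#' @seealso [tokenizeEnzymatic()], [prepareMultitaskCorpus()]
#' @export
writeTokenFiles <- function(dataset, srcPath, tgtPath) {
    stopifnot(is(dataset, "CuratedDataset"))
    scheme <- tokenScheme(dataset)
    lines <- lapply(curatedRecords(dataset)$rxn_smiles, function(x) {
        tok <- tokenizeEnzymatic(x, scheme)
        arrows <- which(tok == ">")
        list(src = paste(tok[seq_len(arrows[1L] - 1L)], collapse = " "),
             tgt = paste(tok[seq(arrows[length(arrows)] + 1L, length(tok))],
                         collapse = " "))
    })
    src <- vapply(lines, `[[`, "", "src")
    tgt <- vapply(lines, `[[`, "", "tgt")
    writeLines(src, srcPath)
    writeLines(tgt, tgtPath)
    invisible(list(src = src, tgt = tgt))
}
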