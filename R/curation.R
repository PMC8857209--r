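# Dataset construction: merge multi-source raw reaction records, apply the
# four filter rules in order, truncate EC annotations to the token scheme,
# deduplicate on the canonical extended reaction SMILES, and derive
# product-disjoint splits and weighted multitask corpora.
#
# The four rules, applied to each canonicalised reaction in this order:
#   (1) drop products that also occur as reactants of the same reaction;
#   (2) in reactions with more than one product, drop products listed as
#       known co-enzymes or common byproducts;
#   (3) drop products with fewer than 4 heavy atoms;
#   (4) keep only reactions with exactly one product and at least one
#       reactant.
# Rule 2 is gated on the product count before its own removals: a reaction
# reduced to one product by rule 2 is not re-entered.

#' Default cofactor / byproduct configuration
#'
#' A list with canonicalised `coenzymes` and `byproducts` SMILES sets used by
#' the cofactor-stripping rule.  The default covers the ubiquitous redox and
#' group-transfer cofactors and small byproducts (NAD(+)/NADH, NADP(+)/NADPH,
#' ATP/ADP/AMP, coenzyme A, phosphate, diphosphate, water, CO2, O2,
#' ammonia, H+); it is fully overridable, e.g. from a file of SMILES via
#' [cofactorConfig()].
#'
#' @return a cofactor configuration list.
#' @export
defaultCofactorConfig <- function() {
    nad <- paste0("NC(=O)c1ccc[n+](c1)[C@@H]1O[C@H](COP(=O)(O)OP(=O)(O)OC",
                  "[C@H]2O[C@@H](n3cnc4c(N)ncnc34)[C@H](O)[C@@H]2O)",
                  "[C@@H](O)[C@H]1O")
    nadh <- paste0("NC(=O)C1=CN([C@@H]2O[C@H](COP(=O)(O)OP(=O)(O)OC",
                   "[C@H]3O[C@@H](n4cnc5c(N)ncnc45)[C@H](O)[C@@H]3O)",
                   "[C@@H](O)[C@H]2O)C=CC1")
    nadp <- paste0("NC(=O)c1ccc[n+](c1)[C@@H]1O[C@H](COP(=O)(O)OP(=O)(O)OC",
                   "[C@H]2O[C@@H](n3cnc4c(N)ncnc34)[C@H](OP(=O)(O)O)",
                   "[C@@H]2O)[C@@H](O)[C@H]1O")
    nadph <- paste0("NC(=O)C1=CN([C@@H]2O[C@H](COP(=O)(O)OP(=O)(O)OC",
                    "[C@H]3O[C@@H](n4cnc5c(N)ncnc45)[C@H](OP(=O)(O)O)",
                    "[C@@H]3O)[C@@H](O)[C@H]2O)C=CC1")
    atp <- paste0("Nc1ncnc2n(cnc12)[C@@H]1O[C@H](COP(=O)(O)OP(=O)(O)",
                  "OP(=O)(O)O)[C@@H](O)[C@H]1O")
    adp <- paste0("Nc1ncnc2n(cnc12)[C@@H]1O[C@H](COP(=O)(O)OP(=O)(O)O)",
                  "[C@@H](O)[C@H]1O")
    amp <- paste0("Nc1ncnc2n(cnc12)[C@@H]1O[C@H](COP(=O)(O)O)",
                  "[C@@H](O)[C@H]1O")
    coa <- paste0("CC(C)(COP(=O)(O)OP(=O)(O)OC[C@H]1O[C@@H](n2cnc3c(N)",
                  "ncnc23)[C@H](O)[C@@H]1OP(=O)(O)O)[C@@H](O)C(=O)",
                  "NCCC(=O)NCCS")
    cofactorConfig(
        coenzymes = c(nad, nadh, nadp, nadph, atp, adp, amp, coa),
        byproducts = c("OP(=O)(O)O", "OP(=O)(O)OP(=O)(O)O",
                       "O", "O=C=O", "O=O", "N", "[H+]"))
}

#' Build a cofactor configuration
#'
#' @param coenzymes,byproducts character vectors of SMILES; canonicalised on
#'   construction.
#' @return a list with canonical `coenzymes` and `byproducts` sets.
#' @export
cofactorConfig <- function(coenzymes = character(0),
                           byproducts = character(0)) {
    structure(list(coenzymes = unique(canonicalize(coenzymes)),
                   byproducts = unique(canonicalize(byproducts))),
              class = "cofactorConfig")
}

#' Read a cofactor configuration from a file
#'
#' One SMILES per line; lines starting `#` are comments.  All molecules are
#' treated as strippable (both coenzyme and byproduct roles).
#'
#' @param path file path.
#' @return a cofactor configuration list.
#' @export
readCofactorConfig <- function(path) {
    lines <- trimws(readLines(path))
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    cofactorConfig(coenzymes = lines)
}

#' The four curation filter rules
#'
#' `rule1RemoveSelfProducts()` deletes every product whose canonical SMILES
#' also occurs among the reactants.  `rule2StripCofactors()` removes
#' configured coenzymes/byproducts from the product side, but only of
#' reactions that have more than one product when the rule is applied; the
#' reactant side is never touched.  `rule3RemoveSmallProducts()` removes
#' products with fewer than 4 heavy atoms.  `rule4Keep()` returns `TRUE` iff
#' the reaction has exactly one product and at least one reactant.
#'
#' All rules expect canonicalised reactions (see [canonicalizeReaction()]).
#'
#' @param rxn a canonicalised [EnzymaticReaction-class].
#' @param cfg a cofactor configuration (see [cofactorConfig()]).
#' @return the filtered reaction, or for `rule4Keep` a logical.
#' @name curationRules
#' @export
rule1RemoveSelfProducts <- function(rxn) {
    keep <- !(rxn@products %in% rxn@reactants)
    EnzymaticReaction(reactants = rxn@reactants, reagents = rxn@reagents,
                      ec = rxn@ec, products = rxn@products[keep],
                      source = rxn@source)
}

#' @rdname curationRules
#' @export
rule2StripCofactors <- function(rxn, cfg = defaultCofactorConfig()) {
    if (length(rxn@products) <= 1L)
        return(rxn)
    listed <- rxn@products %in% c(cfg$coenzymes, cfg$byproducts)
    EnzymaticReaction(reactants = rxn@reactants, reagents = rxn@reagents,
                      ec = rxn@ec, products = rxn@products[!listed],
                      source = rxn@source)
}

#' @rdname curationRules
#' @export
rule3RemoveSmallProducts <- function(rxn) {
    keep <- if (length(rxn@products)) heavyAtomCount(rxn@products) >= 4L
            else logical(0)
    EnzymaticReaction(reactants = rxn@reactants, reagents = rxn@reagents,
                      ec = rxn@ec, products = rxn@products[keep],
                      source = rxn@source)
}

#' @rdname curationRules
#' @export
rule4Keep <- function(rxn) {
    length(rxn@products) == 1L && length(rxn@reactants) >= 1L
}

#' Curate raw reaction records into a dataset
#'
#' Runs the full pipeline: parse, canonicalise, fold reagents into reactants,
#' apply filter rules 1-4 in order, truncate the EC annotation to the token
#' scheme's depth, and deduplicate on the canonical extended reaction SMILES
#' (sorted canonical reactants + EC + canonical product).  Sources of merged
#' duplicates are concatenated with `;`.  Unparseable records are skipped
#' with a message and counted in the result's `skipped` attribute, never
#' silently dropped.
#'
#' @param records a data.frame with columns `rxn_smiles`, optional `ec`
#'   (dot-joined text; may instead be embedded as `|EC` in `rxn_smiles`) and
#'   optional `source`; or a list of [EnzymaticReaction-class] objects.
#' @param cfg cofactor configuration for rule 2.
#' @param scheme target token scheme, `"EC0".."EC4"`.
#' @return a [CuratedDataset-class]; `attr(x, "skipped")` holds the number of
#'   unparseable input records.
#' @examples
#' raw <- data.frame(rxn_smiles = c("CC(=O)O.OCC>>CC(=O)OCC.O",
#'                                  "OCC.CC(=O)O>>CC(=O)OCC"),
#'                   ec = c("3.1.1.1", "3.1.1.1"),
#'                   source = c("rhea", "brenda"))
#' curate(raw, scheme = "EC3")
#' @export
curate <- function(records, cfg = defaultCofactorConfig(), scheme = "EC3") {
    k <- .schemeLevel(scheme)
    if (is(records, "CuratedDataset"))
        records <- curatedRecords(records)
    if (is.data.frame(records)) {
        rxns <- .parseRawTable(records)
    } else if (is.list(records)) {
        stopifnot(all(vapply(records, is, TRUE, "EnzymaticReaction")))
        rxns <- records
    } else stop("'records' must be a data.frame or a list of reactions")
    skipped <- attr(rxns, "skipped") %||% 0L
    out <- new.env(parent = emptyenv())   # key -> list(ec, product, sources)
    keys <- character(0)
    for (rxn in rxns) {
        r <- tryCatch(canonicalizeReaction(asEnzymatic(rxn)),
                      error = function(e) NULL)
        if (is.null(r)) { skipped <- skipped + 1L; next }
        r <- rule3RemoveSmallProducts(rule2StripCofactors(
                 rule1RemoveSelfProducts(r), cfg))
        if (!rule4Keep(r)) next
        ec <- truncateEC(r@ec, min(k, length(ecLevels(r@ec))))
        rec <- EnzymaticReaction(reactants = r@reactants, ec = ec,
                                 products = r@products, source = r@source)
        key <- extendedReactionSmiles(rec)
        prev <- out[[key]]
        if (is.null(prev)) {
            keys <- c(keys, key)
            out[[key]] <- list(ec = ecText(ec), sources = r@source)
        } else {
            out[[key]]$sources <- c(prev$sources, r@source)
        }
    }
    if (skipped > 0L)
        message(skipped, " unparseable record(s) skipped")
    recs <- data.frame(
        rxn_smiles = keys,
        ec = vapply(keys, function(kk) out[[kk]]$ec, "", USE.NAMES = FALSE),
        sources = vapply(keys, function(kk)
            paste(sort(unique(out[[kk]]$sources[nzchar(out[[kk]]$sources)])),
                  collapse = ";"), "", USE.NAMES = FALSE),
        stringsAsFactors = FALSE)
    ds <- new("CuratedDataset", scheme = scheme, records = recs)
    attr(ds, "skipped") <- skipped
    ds
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.parseRawTable <- function(df) {
    stopifnot("rxn_smiles" %in% names(df))
    n <- nrow(df)
    ecCol <- if ("ec" %in% names(df)) as.character(df$ec) else rep("", n)
    srcCol <- if ("source" %in% names(df)) as.character(df$source)
              else rep("", n)
    skipped <- 0L
    rxns <- vector("list", n)
    for (i in seq_len(n)) {
        r <- tryCatch({
            rr <- parseReactionSmiles(df$rxn_smiles[i], source = srcCol[i])
            if (nzchar(ecCol[i]) && !is.na(ecCol[i])) {
                if (!ecIsAbsent(rr@ec) && ecText(rr@ec) != ecCol[i])
                    stop("conflicting EC annotations for record ", i)
                rr@ec <- ECNumber(ecCol[i])
            }
            rr
        }, error = function(e) { message("record ", i, ": ",
                                         conditionMessage(e)); NULL })
        if (is.null(r)) skipped <- skipped + 1L
        rxns[[i]] <- r
    }
    rxns <- rxns[!vapply(rxns, is.null, TRUE)]
    attr(rxns, "skipped") <- skipped
    rxns
}

## ---- CuratedDataset accessors --------------------------------------------

#' Access curated dataset contents
#'
#' `curatedRecords()` returns the record data.frame, `tokenScheme()` the
#' dataset's EC token scheme, `datasetProducts()` the canonical product of
#' each record.
#'
#' @param x a [CuratedDataset-class].
#' @return data.frame / character scalar / character vector.
#' @name curatedRecords
NULL

#' @rdname curatedRecords
setMethod("curatedRecords", "CuratedDataset", function(x) x@records)

#' @rdname curatedRecords
setMethod("tokenScheme", "CuratedDataset", function(x) x@scheme)

#' @rdname curatedRecords
#' @export
datasetProducts <- function(x) {
    stopifnot(is(x, "CuratedDataset"))
    vapply(x@records$rxn_smiles, function(s)
        sub("^.*>>", "", s), "", USE.NAMES = FALSE)
}

setMethod("show", "CuratedDataset", function(object) {
    cat("CuratedDataset:", nrow(object@records), "records, scheme",
        object@scheme, "\n")
    if (nrow(object@records))
        cat("  e.g.", object@records$rxn_smiles[1L], "\n")
})

#' @describeIn curatedRecords number of records
#' @export
setMethod("length", "CuratedDataset", function(x) nrow(x@records))

## ---- product-disjoint split ----------------------------------------------

#' Product-disjoint train/validation/test split
#'
#' Groups records by canonical product and assigns whole product groups to
#' splits, so that no product molecule occurs in more than one split (a
#' product in the test split never occurs as a product in training).  Groups
#' are assigned largest-first to the split with the greatest remaining
#' record deficit relative to its target fraction; ties among equally sized
#' groups are shuffled with the seed, making the split deterministic given
#' `(dataset, seed)`.
#'
#' @param dataset a [CuratedDataset-class].
#' @param fractions named numeric of train/valid/test proportions summing
#'   to 1.
#' @param seed integer seed.
#' @return named list of three [CuratedDataset-class] objects.
#' @export
productDisjointSplit <- function(dataset,
                                 fractions = c(train = 0.90, valid = 0.05,
                                               test = 0.05),
                                 seed = 42L) {
    stopifnot(is(dataset, "CuratedDataset"))
    if (length(dataset) == 0L)
        stop("dataset is empty")
    if (abs(sum(fractions) - 1) > 1e-8 || any(fractions <= 0) ||
        any(fractions >= 1))
        stop("fractions must lie in (0,1) and sum to 1")
    prods <- datasetProducts(dataset)
    groups <- split(seq_along(prods), prods)
    if (length(groups) < length(fractions))
        stop("fewer distinct products (", length(groups),
             ") than splits (", length(fractions), ")")
    sizes <- lengths(groups)
    ord <- withr_seed(seed, {
        jitter <- sample.int(length(groups))
        order(-sizes, jitter)
    })
    target <- fractions * length(dataset)
    assigned <- stats::setNames(numeric(length(fractions)), names(fractions))
    bucket <- stats::setNames(vector("list", length(fractions)),
                              names(fractions))
    for (g in ord) {
        deficit <- target - assigned
        dest <- names(fractions)[which.max(deficit)]
        bucket[[dest]] <- c(bucket[[dest]], groups[[g]])
        assigned[dest] <- assigned[dest] + sizes[g]
    }
    lapply(bucket, function(idx) {
        new("CuratedDataset", scheme = dataset@scheme,
            records = dataset@records[sort(idx), , drop = FALSE])
    })
}

# run code under a temporary RNG state
withr_seed <- function(seed, code) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
        get(".Random.seed", globalenv()) else NULL
    on.exit({
        if (is.null(old)) rm(".Random.seed", envir = globalenv())
        else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
    code
}

## ---- multitask corpus -----------------------------------------------------

#' Prepare a weighted multitask corpus
#'
#' Combines several seq2seq corpora (src/tgt token-file pairs) under positive
#' integer sampling weights — the multitask transfer-learning setup in which
#' a large general-chemistry corpus is mixed with a small enzymatic corpus at
#' 9:1.  Emits a manifest declaring the per-corpus weights for
#' weighted-corpus trainers and, optionally, a materialised interleaved
#' sample in which corpus *i* contributes lines with probability
#' proportional to its weight.
#'
#' @param corpora named list; each element a list with `src` and `tgt` file
#'   paths (equal line counts).
#' @param weights named positive integer vector, same names as `corpora`.
#' @param sampleLines if non-`NULL`, number of lines of the materialised
#'   sample.
#' @param seed integer seed for the sampling.
#' @return list with `manifest` (data.frame: corpus, weight, n_lines) and,
#'   when materialised, `sample` (list of `src`, `tgt`, `corpus` vectors).
#' @export
prepareMultitaskCorpus <- function(corpora, weights, sampleLines = NULL,
                                   seed = 42L) {
    stopifnot(is.list(corpora), length(corpora) >= 1L)
    if (is.null(names(corpora)) || any(!nzchar(names(corpora))))
        stop("corpora must be named")
    if (!all(names(corpora) %in% names(weights)))
        stop("missing weights for: ",
             paste(setdiff(names(corpora), names(weights)), collapse = ", "))
    weights <- weights[names(corpora)]
    if (any(weights <= 0) || any(weights != as.integer(weights)))
        stop("weights must be positive integers")
    data <- lapply(corpora, function(co) {
        src <- readLines(co$src); tgt <- readLines(co$tgt)
        if (length(src) != length(tgt))
            stop("mismatched src/tgt line counts: ", co$src)
        list(src = src, tgt = tgt)
    })
    manifest <- data.frame(corpus = names(corpora),
                           weight = as.integer(weights),
                           n_lines = vapply(data, function(d)
                               length(d$src), 0L),
                           stringsAsFactors = FALSE)
    out <- list(manifest = manifest)
    if (!is.null(sampleLines)) {
        stopifnot(sampleLines >= 1L)
        pick <- withr_seed(seed, {
            ci <- sample.int(length(data), sampleLines, replace = TRUE,
                             prob = weights / sum(weights))
            li <- vapply(ci, function(i)
                sample.int(length(data[[i]]$src), 1L), 0L)
            list(ci = ci, li = li)
        })
        out$sample <- list(
            src = mapply(function(i, j) data[[i]]$src[j],
                         pick$ci, pick$li, USE.NAMES = FALSE),
            tgt = mapply(function(i, j) data[[i]]$tgt[j],
                         pick$ci, pick$li, USE.NAMES = FALSE),
            corpus = names(corpora)[pick$ci])
    }
    out
}

## ---- training-config descriptor ------------------------------------------

#' Emit a training-configuration descriptor
#'
#' Writes a human-readable YAML descriptor of the published sequence-model
#' hyperparameters (transformer encoder/decoder, 6 layers, model size 512,
#' gradient accumulation 8, token batches of 4096, adam with beta1 0.9 /
#' beta2 0.998, learning rate 2.0 with noam decay, dropout 0.1, label
#' smoothing 0.1) for use with an external trainer.  This package never
#' trains a model; the descriptor documents the intended downstream setup.
#'
#' @param path output file, or `NULL` to return the descriptor only.
#' @param overrides named list of overrides merged over the defaults
#'   (nested, e.g. `list(training = list(dropout = 0.2))`).
#' @return the descriptor list, invisibly when written to a file.
#' @seealso [readTrainingConfig()]
#' @export
emitTrainingConfig <- function(path = NULL, overrides = list()) {
    cfg <- list(
        model = list(encoder = "transformer", decoder = "transformer",
                     layers = 6L, hidden_size = 512L, word_vec_size = 512L,
                     position_encoding = TRUE, param_init = 0),
        optimizer = list(name = "adam", beta1 = 0.9, beta2 = 0.998,
                         learning_rate = 2.0, decay_method = "noam",
                         accum_count = 8L, max_grad_norm = 0.0),
        training = list(batch_size = 4096L, batch_type = "tokens",
                        normalization = "tokens", dropout = 0.1,
                        label_smoothing = 0.1))
    cfg <- utils::modifyList(cfg, overrides)
    if (is.null(path)) return(cfg)
    yaml::write_yaml(cfg, path)
    invisible(cfg)
}

#' Read back a training-configuration descriptor
#'
#' @param path YAML file written by [emitTrainingConfig()].
#' @return the descriptor list.
#' @export
readTrainingConfig <- function(path) yaml::read_yaml(path)

## ---- TSV I/O --------------------------------------------------------------

#' Read and write reaction tables
#'
#' `readReactionTable()` reads a raw-record TSV (header required; columns
#' `rxn_smiles`, optional `ec`, `source`).  `writeCuratedDataset()` /
#' `readCuratedDataset()` round-trip a curated dataset as TSV with columns
#' `rxn_smiles`, `ec`, `sources`.
#'
#' @param path file path.
#' @param dataset a [CuratedDataset-class].
#' @param scheme token scheme of the file being read.
#' @return a data.frame, or a [CuratedDataset-class].
#' @name reactionIO
#' @export
readReactionTable <- function(path) {
    df <- utils::read.delim(path, stringsAsFactors = FALSE,
                            colClasses = "character")
    if (!"rxn_smiles" %in% names(df))
        stop("missing required column 'rxn_smiles' in ", path)
    df
}

#' @rdname reactionIO
#' @export
writeCuratedDataset <- function(dataset, path) {
    stopifnot(is(dataset, "CuratedDataset"))
    utils::write.table(curatedRecords(dataset), path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' @rdname reactionIO
#' @export
readCuratedDataset <- function(path, scheme = "EC3") {
    df <- utils::read.delim(path, stringsAsFactors = FALSE,
                            colClasses = "character")
    new("CuratedDataset", scheme = scheme, records = df)
}
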