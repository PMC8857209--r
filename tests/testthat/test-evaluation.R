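# fabricate an evaluation record with the truth planted at a known rank
# (rank = 0 means the truth never appears)
plantForward <- function(truthRank, ec = "1.1.1", nPred = 5L) {
    prods <- canonicalize(sprintf("OC%s", strrep("C", 1:6)))
    truth <- prods[6L]
    preds <- prods[seq_len(nPred)]
    if (truthRank >= 1L) preds[truthRank] <- truth
    list(type = "forward", truth = list(product = truth, ec = ec),
         predictions = data.frame(
             rank = seq_len(nPred), product = preds,
             confidence = round(seq(0.9, 0.1,
                                    length.out = nPred), 3),
             stringsAsFactors = FALSE))
}

plantBackward <- function(precursorsOK, ecOK, rank = 1L, trueEC = "1.1.1") {
    truthPre <- paste(sort(canonicalize(c("CC(=O)O", "OCC")),
                           method = "radix"), collapse = ".")
    predPre <- if (precursorsOK) truthPre else canonicalize("NCCCC")
    predEC <- if (ecOK) trueEC else "2.6.1"
    n <- max(rank, 2L)
    pre <- rep(canonicalize("OCCCCCC"), n); ecs <- rep("7.1.1", n)
    pre[rank] <- predPre; ecs[rank] <- predEC
    list(type = "backward",
         truth = list(precursors = truthPre, ec = trueEC,
                      product = canonicalize("CC(=O)OCC")),
         predictions = data.frame(rank = seq_len(n), precursors = pre,
                                  ec = ecs,
                                  confidence = seq(0.9, 0.1,
                                                   length.out = n),
                                  stringsAsFactors = FALSE))
}

test_that("top-k accuracy counts truths planted at known ranks", {
    # 10 records with truths at ranks 1,1,2,3,3,4,5,0,0,0
    ranks <- c(1L, 1L, 2L, 3L, 3L, 4L, 5L, 0L, 0L, 0L)
    records <- lapply(ranks, plantForward)
    expect_equal(topkAccuracy(records, 1L), 0.2)
    expect_equal(topkAccuracy(records, 2L), 0.3)
    expect_equal(topkAccuracy(records, 3L), 0.5)
    expect_equal(topkAccuracy(records, 4L), 0.6)
    expect_equal(topkAccuracy(records, 5L), 0.7)
    # monotone in k
    accs <- vapply(1:5, function(k) topkAccuracy(records, k), 0.0)
    expect_true(all(diff(accs) >= 0))
    # all-empty predictions -> 0
    empty <- lapply(records, function(r) {
        r$predictions <- r$predictions[0L, ]; r })
    expect_equal(topkAccuracy(empty, 5L), 0.0)
    expect_error(topkAccuracy(list(), 1L), "empty")
})

test_that("backward matching requires both precursor set and EC", {
    records <- list(plantBackward(TRUE, TRUE),    # full match
                    plantBackward(TRUE, FALSE),   # substrates only
                    plantBackward(FALSE, TRUE),   # EC only
                    plantBackward(FALSE, FALSE))  # neither
    expect_equal(topkAccuracy(records, 1L), 0.25)
    expect_equal(topkAccuracy(records, 1L, match = "precursors_only"), 0.5)
    expect_equal(ecOnlyAccuracy(records, 1L), 0.5)
    # EC-only accuracy dominates full backward accuracy at every k
    for (k in 1:2)
        expect_gte(ecOnlyAccuracy(records, k), topkAccuracy(records, k))
    expect_error(ecOnlyAccuracy(list(plantForward(1L)), 1L), "backward")
})

test_that("stereo-insensitive matching recovers stereo-only mismatches", {
    rec <- plantForward(0L)
    rec$truth$product <- canonicalize("C[C@@H](N)C(=O)O")
    rec$predictions$product[1L] <- canonicalize("C[C@H](N)C(=O)O")
    expect_equal(topkAccuracy(list(rec), 1L), 0.0)
    expect_equal(topkAccuracy(list(rec), 1L, ignoreStereo = TRUE), 1.0)
})

test_that("round-trip accuracy is 1 for inverse stubs and 1-f corrupted", {
    ds <- curate(makeRawRecords(fixtureSpec(seed = 31L, nReactions = 40L)),
                 scheme = "EC3")
    stubs <- inverseStubPair(ds)
    # unique targets: the corruption set is defined by product value
    prods <- unique(datasetProducts(ds))
    expect_equal(roundTripAccuracy(stubs$backward, stubs$forward, prods,
                                   k = 1L), 1.0)
    expect_equal(roundTripAccuracy(stubs$backward, stubs$forward, prods,
                                   k = 5L), 1.0)
    # corrupt the forward model on a fixed 40% of the targets
    nBad <- round(0.4 * length(prods))
    bad <- sort(prods)[seq_len(nBad)]
    corrupted <- corruptedForward(stubs$forward, bad)
    expect_equal(roundTripAccuracy(stubs$backward, corrupted, prods, k = 1L),
                 1 - nBad / length(prods))
    # a constant-wrong forward model gives zero
    wrong <- functionForwardModel(function(reactants, ec, k)
        data.frame(rank = 1L, product = "C1CCCCCCCCC1", confidence = 1.0))
    expect_equal(roundTripAccuracy(stubs$backward, wrong, prods, k = 1L),
                 0.0)
})

test_that("class breakdown partitions records and recovers group accuracy", {
    # class 1: truth always at rank 1; class 2: never found
    records <- c(lapply(1:4, function(i) plantForward(1L, ec = "1.1.1")),
                 lapply(1:4, function(i) plantForward(0L, ec = "2.6.1")))
    bd <- classBreakdown(records, level = 1L)
    expect_identical(bd$group, c("1", "2"))
    expect_identical(bd$n, c(4L, 4L))
    expect_equal(bd$top1, c(1, 0))
    expect_equal(bd$top5, c(1, 0))
    expect_identical(sum(bd$n), length(records))
    # overall accuracy is the N-weighted mean of the group accuracies
    expect_equal(topkAccuracy(records, 1L),
                 sum(bd$top1 * bd$n) / sum(bd$n))
    bd3 <- classBreakdown(records, level = 3L)
    expect_identical(bd3$group, c("1.1.1", "2.6.1"))
})

test_that("the confusion matrix tabulates rank-1 EC classes", {
    records <- list(plantBackward(TRUE, TRUE),          # 1 -> 1
                    plantBackward(FALSE, FALSE),        # 1 -> 2
                    plantBackward(TRUE, TRUE, trueEC = "5.3.1"))  # 5 -> 5
    noPred <- plantBackward(TRUE, TRUE, trueEC = "4.1.1")
    noPred$predictions <- noPred$predictions[0L, ]
    records <- c(records, list(noPred))                 # 4 -> none
    cm <- confusionMatrixLevel1(records)
    expect_identical(dim(cm), c(7L, 8L))
    expect_identical(cm["1", "1"], 1L)
    expect_identical(cm["1", "2"], 1L)
    expect_identical(cm["5", "5"], 1L)
    expect_identical(cm["4", "none"], 1L)
    expect_identical(sum(cm), 4L)
    expect_identical(unname(rowSums(cm)[c("1", "4", "5")]), c(2, 1, 1))
})

test_that("model-built eval records agree with direct model queries", {
    ds <- curate(makeRawRecords(fixtureSpec(seed = 33L, nReactions = 30L)),
                 scheme = "EC3")
    stubs <- inverseStubPair(ds)
    fw <- forwardEvalRecords(ds, stubs$forward, k = 5L)
    expect_equal(topkAccuracy(fw, 1L), 1.0)
    # a product can be reachable from several recorded disconnections, so
    # the record's own precursors are only guaranteed within the top k
    bw <- backwardEvalRecords(ds, stubs$backward, k = 10L)
    expect_equal(topkAccuracy(bw, 10L), 1.0)
    expect_equal(ecOnlyAccuracy(bw, 10L), 1.0)
    expect_gte(ecOnlyAccuracy(bw, 1L), topkAccuracy(bw, 1L))
    cm <- confusionMatrixLevel1(bw)
    expect_identical(sum(cm), length(bw))
})
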