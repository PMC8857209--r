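test_that("complexity scores sit in [1,5] and respect monotonicity", {
    expect_equal(complexityScore("C"), 1.0)
    smis <- c("C", "CCO", "CC(=O)OCC", "c1ccccc1", "C[C@H](N)C(=O)O",
              strrep("C", 60))
    sc <- complexityScore(smis)
    expect_true(all(sc >= 1 & sc <= 5))
    # adding a ring never decreases the score (same heavy-atom count)
    pairs <- list(c("CCCCCC", "C1CCCCC1"), c("CCCCCCC", "CC1CCCCC1"),
                  c("CCCCCCCC", "C1CCCCCCC1"))
    for (p in pairs)
        expect_gte(complexityScore(p[2L]), complexityScore(p[1L]))
    # more heavy atoms, more complexity
    expect_gt(complexityScore("CCCCCCCC"), complexityScore("CCC"))
    # a stereocentre adds complexity
    expect_gt(complexityScore("C[C@H](N)C(=O)O"),
              complexityScore("CC(N)C(=O)O"))
})

test_that("step score boundary identities hold exactly", {
    expect_identical(scoreStep(0.5, 1.0, c(1, 1, 1), lambda = 0.7), 1.0)
    expect_identical(scoreStep(0.5, 0.37, c(3.2, 4.8), lambda = 0), 0.37)
    expect_identical(scoreStep(0.5, 0, c(2, 3), lambda = 0.25), 0)
    # monotone: increasing forward confidence raises, complexity lowers
    expect_gt(scoreStep(0.5, 0.9, c(2, 2)), scoreStep(0.5, 0.5, c(2, 2)))
    expect_lt(scoreStep(0.5, 0.9, c(4, 4)), scoreStep(0.5, 0.9, c(2, 2)))
    expect_error(scoreStep(0.5, 1.2, 1), "forwardConf")
})

test_that("expansion applies the round-trip filter and sorts by score", {
    toy <- toyPlanningInstance()
    steps <- expandMolecule(toy$target, toy$backward, toy$forward, k = 5L)
    expect_length(steps, 3L)
    scores <- vapply(steps, `[[`, 0.0, "combined_score")
    expect_true(all(diff(scores) <= 0))
    for (s in steps) {
        fwd <- forwardPredict(toy$forward, s$precursors, ECNumber(s$ec),
                              k = 1L)
        expect_identical(fwd$product[1L], canonicalize(toy$target))
        expect_equal(s$combined_score,
                     scoreStep(s$backward_confidence, s$forward_confidence,
                               s$complexity, 0.25))
    }
    # corrupt the forward model for one disconnection: it must disappear
    dropPre <- canonicalize("NCCCCC")
    crippled <- functionForwardModel(function(reactants, ec, k) {
        if (identical(sort(canonicalize(reactants)), dropPre))
            return(data.frame(rank = 1L, product = "C",
                              confidence = 1.0))
        forwardPredict(toy$forward, reactants, ec, k = k)
    })
    steps2 <- expandMolecule(toy$target, toy$backward, crippled, k = 5L)
    expect_length(steps2, 2L)
    expect_false(any(vapply(steps2, function(s)
        identical(s$precursors, dropPre), FALSE)))
})

test_that("the planner recovers a planted route as rank 1", {
    sc <- makeRouteScenario(depth = 3L, branching = 3L, seed = 7L)
    routes <- planRoutes(sc$target, sc$backward, sc$forward, sc$stock,
                         plannerConfig(beamWidth = 10L, maxDepth = 5L))
    expect_length(routes, 1L)
    r <- routes[[1L]]
    expect_true(isSolved(r))
    expect_identical(routeDepth(r), 3L)
    expect_true(all(routeLeaves(r) %in% sc$stock))
    # the backbone follows the planted molecule chain
    node <- r@tree
    for (i in seq_len(length(sc$plantedRoute) - 1L)) {
        expect_identical(node$smiles, sc$plantedRoute[i])
        kids <- vapply(node$children, `[[`, "", "smiles")
        expect_true(sc$plantedRoute[i + 1L] %in% kids)
        node <- node$children[[match(sc$plantedRoute[i + 1L], kids)]]
    }
    expect_identical(node$smiles, sc$plantedRoute[length(sc$plantedRoute)])
    # single-step scenario
    sc1 <- makeRouteScenario(depth = 1L, branching = 2L, seed = 3L)
    r1 <- planRoutes(sc1$target, sc1$backward, sc1$forward, sc1$stock,
                     plannerConfig(beamWidth = 5L, maxDepth = 3L))
    expect_length(r1, 1L)
    expect_identical(routeDepth(r1[[1L]]), 1L)
    # decoy leaves are disjoint from stock
    expect_length(intersect(sc$decoys, sc$stock), 0L)
})

test_that("a target already in stock yields the trivial route", {
    toy <- toyPlanningInstance()
    expect_message(
        routes <- planRoutes("CCCC", toy$backward, toy$forward, toy$stock),
        "already in stock")
    expect_length(routes, 1L)
    expect_identical(routeDepth(routes[[1L]]), 0L)
    expect_true(isSolved(routes[[1L]]))
})

test_that("wide beam search equals exhaustive enumeration", {
    toy <- toyPlanningInstance()
    cfg <- plannerConfig(beamWidth = 1000L, maxDepth = 4L, k = 5L)
    routes <- planRoutes(toy$target, toy$backward, toy$forward, toy$stock,
                         cfg)
    oracle <- bruteForceRoutes(toy$target, toy$backward, toy$forward,
                               toy$stock, maxDepth = 4L, k = 5L)
    expect_identical(sort(vapply(routes, function(r) routeTreeKey(r@tree),
                                 "")),
                     sort(vapply(oracle, routeTreeKey, "")))
    expect_equal(sort(vapply(routes, routeScore, 0.0)),
                 sort(vapply(oracle, `[[`, 0.0, "score")))
    # scores come back in non-increasing order
    expect_true(all(diff(vapply(routes, routeScore, 0.0)) <= 0))
    # the same holds on a planted scenario
    sc <- makeRouteScenario(depth = 3L, branching = 3L, seed = 19L)
    got <- planRoutes(sc$target, sc$backward, sc$forward, sc$stock,
                      plannerConfig(beamWidth = 1000L, maxDepth = 4L,
                                    k = 5L))
    want <- bruteForceRoutes(sc$target, sc$backward, sc$forward, sc$stock,
                             maxDepth = 4L, k = 5L)
    expect_identical(sort(vapply(got, function(r) routeTreeKey(r@tree), "")),
                     sort(vapply(want, routeTreeKey, "")))
})

test_that("growing the beam never loses a previously found route", {
    toy <- toyPlanningInstance()
    keysAt <- function(w) sort(vapply(
        planRoutes(toy$target, toy$backward, toy$forward, toy$stock,
                   plannerConfig(beamWidth = w, maxDepth = 4L, k = 5L)),
        function(r) routeTreeKey(r@tree), ""))
    k1 <- keysAt(1L); k2 <- keysAt(2L); k8 <- keysAt(8L)
    expect_true(all(k1 %in% k2))
    expect_true(all(k2 %in% k8))
})

test_that("returned routes pass an independent forward re-check", {
    toy <- toyPlanningInstance()
    routes <- planRoutes(toy$target, toy$backward, toy$forward, toy$stock,
                         plannerConfig(beamWidth = 10L, maxDepth = 4L))
    checkNode <- function(node) {
        if (!length(node$children)) return(invisible(TRUE))
        pre <- vapply(node$children, `[[`, "", "smiles")
        fwd <- forwardPredict(toy$forward, pre, ECNumber(node$step$ec),
                              k = 1L)
        expect_identical(fwd$product[1L], node$smiles)
        for (ch in node$children) checkNode(ch)
    }
    for (r in routes) {
        checkNode(r@tree)
        expect_true(all(routeLeaves(r) %in% canonicalize(toy$stock)))
    }
})

test_that("routes serialise to JSON and back unchanged", {
    sc <- makeRouteScenario(depth = 2L, branching = 2L, seed = 5L)
    routes <- planRoutes(sc$target, sc$backward, sc$forward, sc$stock,
                         plannerConfig(beamWidth = 5L, maxDepth = 3L))
    r <- routes[[1L]]
    json <- serializeRoute(r)
    back <- parseRoute(json)
    expect_identical(back@target, r@target)
    expect_equal(back@tree, r@tree)
    expect_equal(routeScore(back), routeScore(r))
    expect_identical(routeDepth(back), routeDepth(r))
    # trivial zero-step route
    triv <- new("Route", target = "C", tree = list(smiles = "C",
                in_stock = TRUE, step = NULL, children = list()),
                score = 1, depth = 0L, solved = TRUE)
    expect_equal(parseRoute(serializeRoute(triv))@tree, triv@tree)
})
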