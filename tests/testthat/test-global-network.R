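test_that("network construction enforces a simple typed graph", {
  expect_error(interactionNetwork(
    data.frame(node_id = c("a", "a"), node_type = "gene")), "duplicate")
  expect_error(interactionNetwork(
    data.frame(node_id = "a", node_type = "gene"),
    data.frame(u = "a", v = "a", confidence = 0.5)), "self-loops")
  expect_error(interactionNetwork(
    data.frame(node_id = c("a", "b"), node_type = "gene"),
    data.frame(u = c("a", "b"), v = c("b", "a"), confidence = 0.5)),
    "duplicate edge")
})

test_that("merging takes node/edge unions with max confidence", {
  mk <- function(ids, type, edges = NULL)
    interactionNetwork(data.frame(node_id = ids, node_type = type), edges)
  a <- mk(sprintf("a%02d", 1:6), "gene",
          data.frame(u = c("a01", "a01", "a02"),
                     v = c("a02", "a03", "a04"),
                     confidence = c(0.9, 0.8, 0.7)))
  b <- mk(c("m1", "m2"), "metabolite",
          data.frame(u = "m1", v = "m2", confidence = 0.6))
  merged <- mergeNetworks(a, b)
  expect_identical(nrow(nodeTable(merged)), 8L)
  expect_identical(nrow(edgeTable(merged)), 4L)

  dup <- mk(c("a01", "a02"), "gene",
            data.frame(u = "a01", v = "a02", confidence = 0.3))
  dup2 <- mk(c("a01", "a02"), "gene",
             data.frame(u = "a02", v = "a01", confidence = 0.9))
  m2 <- mergeNetworks(dup, dup2)
  expect_equal(edgeTable(m2)$confidence, 0.9)

  conflict <- mk("a01", "metabolite")
  expect_error(mergeNetworks(a, conflict), "a01")

  # commutative and idempotent
  ab <- mergeNetworks(a, b); ba <- mergeNetworks(b, a)
  key <- function(n) list(nodeTable(n)[order(nodeTable(n)$node_id),
                                       c("node_id", "node_type")],
                          {e <- edgeTable(n)
                           e <- data.frame(u = pmin(e$u, e$v),
                                           v = pmax(e$u, e$v),
                                           confidence = e$confidence)
                           e[order(e$u, e$v), ]})
  expect_equal(key(ab), key(ba), ignore_attr = TRUE)
  expect_equal(key(mergeNetworks(a, a)), key(a), ignore_attr = TRUE)
})

test_that("prizes are the max absolute fold change over layers", {
  net <- interactionNetwork(
    data.frame(node_id = c("citric_acid", "G1", "G2"),
               node_type = c("metabolite", "gene", "gene")),
    data.frame(u = c("G1", "G1"), v = c("G2", "citric_acid"),
               confidence = 0.8))
  stats <- data.frame(
    feature_id = c("citric_acid", "G1", "G1", "ghost"),
    layer = c("metabolite", "transcript", "protein", "transcript"),
    log2fc = c(-2.6, 2.0, -3.0, 9),
    significant = TRUE)
  expect_warning(prized <- assignPrizes(net, stats), "absent")
  nt <- nodeTable(prized)
  p <- setNames(nt$prize, nt$node_id)
  expect_equal(unname(p["citric_acid"]), 2.6)
  expect_equal(unname(p["G1"]), 3.0)
  expect_equal(unname(p["G2"]), 0)
  expect_false(nt$measured[nt$node_id == "G2"])
  # sum of prizes over unmeasured nodes is zero
  expect_equal(sum(nt$prize[!nt$measured]), 0)
  # restriction to significant features
  stats$significant <- c(TRUE, FALSE, FALSE, FALSE)
  onlySig <- assignPrizes(net, stats[1:3, ], onlySignificant = TRUE)
  expect_equal(setNames(nodeTable(onlySig)$prize,
                        nodeTable(onlySig)$node_id)[["G1"]], 0)
})

test_that("hub penalty shrinks prizes by degree and clamps at zero", {
  net <- interactionNetwork(
    data.frame(node_id = c("h", "x1", "x2", "x3", "x4"),
               node_type = "gene", prize = c(3, 1, 0, 0, 0)),
    data.frame(u = "h", v = c("x1", "x2", "x3", "x4"),
               confidence = 0.9))
  p0 <- nodeTable(applyHubPenalty(net, 0))
  expect_equal(p0$prize, c(3, 1, 0, 0, 0))
  p <- nodeTable(applyHubPenalty(net, 0.5))
  expect_equal(p$prize[p$node_id == "h"], 3 - 0.5 * 4)
  # clamped: x1 has degree 1 -> 1 - 0.5 = 0.5; with mu = 2 it clamps
  p2 <- nodeTable(applyHubPenalty(net, 2))
  expect_equal(p2$prize[p2$node_id == "x1"], 0)
  expect_true(all(p$prize <= p$prize_original))
  expect_error(applyHubPenalty(net, -1), "non-negative")
})

test_that("edge costs are one minus confidence", {
  net <- interactionNetwork(
    data.frame(node_id = c("a", "b", "c"), node_type = "gene"),
    data.frame(u = c("a", "b"), v = c("b", "c"),
               confidence = c(1.0, 0.8)))
  ec <- edgeTable(edgeCostsFromConfidence(net))
  expect_equal(sort(ec$cost), c(0, 0.2), tolerance = 1e-12)
  # monotone: higher confidence, lower cost
  set.seed(8)
  conf <- runif(20, 0.01, 1)
  ids <- sprintf("n%02d", 1:21)
  chain <- interactionNetwork(
    data.frame(node_id = ids, node_type = "gene"),
    data.frame(u = ids[1:20], v = ids[2:21], confidence = conf))
  cost <- edgeTable(edgeCostsFromConfidence(chain))$cost
  expect_equal(order(cost), order(-edgeTable(chain)$confidence))
})

test_that("edge lists load from TSV with dedup and validation", {
  ep <- withr::local_tempfile(fileext = ".tsv")
  np <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("node_u\tnode_v\tconfidence",
               "g1\tg2\t0.3", "g2\tg1\t0.9", "g2\tm1\t0.7"), ep)
  writeLines(c("node_id\tnode_type", "g1\tgene", "g2\tgene",
               "m1\tmetabolite", "iso\tgene"), np)
  net <- readEdgeList(ep, np)
  expect_identical(nrow(nodeTable(net)), 4L)   # isolated node retained
  et <- edgeTable(net)
  expect_identical(nrow(et), 2L)               # duplicate pair collapsed
  expect_equal(et$confidence[et$u == "g1" | et$v == "g1"], 0.9)

  writeLines(c("node_u\tnode_v\tconfidence", "g1\tg9\t0.5"), ep)
  expect_error(readEdgeList(ep, np), "g9")
  writeLines(c("node_u\tnode_v\tconfidence", "g1\tg2\t1.5"), ep)
  expect_error(readEdgeList(ep, np), "confidence")
})

test_that("GraphML export writes node and edge annotations", {
  net <- assignPrizes(
    interactionNetwork(
      data.frame(node_id = c("a", "b", "c"), node_type = "gene"),
      data.frame(u = c("a", "b"), v = c("b", "c"), confidence = 0.8)),
    data.frame(feature_id = c("a", "c"), layer = "transcript",
               log2fc = c(2, -1), significant = TRUE))
  net <- edgeCostsFromConfidence(net)
  path <- withr::local_tempfile(fileext = ".graphml")
  writeNetworkGraphML(net, path)
  g <- igraph::read_graph(path, format = "graphml")
  expect_setequal(igraph::V(g)$name, c("a", "b", "c"))
  expect_equal(sort(igraph::V(g)$prize), c(0, 1, 2))

  sol <- solvePCSF(net, pcsfConfig(beta = 5, omega = 0.5))
  writeNetworkGraphML(net, path, solution = sol)
  gs <- igraph::read_graph(path, format = "graphml")
  expect_setequal(igraph::V(gs)$name, selectedNodes(sol))
  expect_identical(sum(igraph::V(gs)$is_steiner),
                   length(steinerNodes(sol)))
})
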