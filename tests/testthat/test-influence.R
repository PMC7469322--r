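# SIP probabilities, node/set influence, greedy IM-SIP, colored queries,
# suite relevance.

test_that("sip follows the product-of-weights rule on paths", {
  g <- edge_graph("a", "b", 0.75)
  expect_equal(sip(g, "a", "b"), 0.75)
  expect_equal(sip(g, "a", "a"), 1)

  chain <- edge_graph(c("a", "b"), c("b", "c"), c(0.75, 0.5))
  expect_equal(sip(chain, "a", "c"), 0.375)

  # two-hop 0.75 * 0.5 beats the direct 0.25 edge
  tri <- edge_graph(c("a", "a", "b"), c("c", "b", "c"), c(0.25, 0.75, 0.5))
  expect_equal(sip(tri, "a", "c"), 0.375)
  expect_equal(sip(tri, "a", "c"), bruteForceSip(tri, "a", "c"))
  # symmetric on undirected graphs
  expect_equal(sip(tri, "c", "a"), sip(tri, "a", "c"))

  expect_error(sip(tri, "a", "zz"), "unknown node")
})

test_that("sipFrom equals per-pair sip and handles unreachable nodes", {
  star <- star_graph(3, 0.5)
  sf <- sipFrom(star, "c0")
  expect_equal(unname(sf[paste0("l", 1:3)]), rep(0.5, 3))
  expect_equal(unname(sf["c0"]), 1)

  # edgeless graph: all zero except the source itself
  iso <- generateGraph(4, 0, seed = 5)
  sf <- sipFrom(iso, nodeNames(iso)[1])
  expect_equal(unname(sf[nodeNames(iso)[1]]), 1)
  expect_equal(unname(sf[nodeNames(iso)[-1]]), rep(0, 3))

  g <- generateGraph(8, 10, seed = 42)
  sf <- sipFrom(g, "n001")
  for (v in nodeNames(g))
    expect_equal(unname(sf[v]), sip(g, "n001", v))
})

test_that("node influence sums SIP over eligible targets", {
  star <- star_graph(3, 0.5)
  expect_equal(nodeInfluence(star, "c0"), 1.5)          # 3 x 0.5
  expect_equal(nodeInfluence(star, "l1"), 1.0)          # 0.5 + 0.25 + 0.25
  expect_equal(nodeInfluence(generateGraph(1, 0, seed = 1), "n001"), 0)
})

test_that("set influence combines per-seed SIP with noisy-OR or max", {
  # two seeds each reaching the single remaining target at 0.5
  g <- edge_graph(c("a", "b"), c("v", "v"), c(0.5, 0.5))
  expect_equal(setInfluence(g, c("a", "b")), 1 - (1 - 0.5) * (1 - 0.5))
  expect_equal(setInfluence(g, c("a", "b"), aggregator = "max"), 0.5)

  star <- star_graph(3, 0.5)
  expect_equal(setInfluence(star, "c0"), nodeInfluence(star, "c0"))
  expect_error(setInfluence(star, character()), "non-empty")
})

test_that("greedy selection starts at the influence argmax and is deterministic", {
  star <- star_graph(3, 0.5)
  res <- selectSeedsGreedy(star, 1)
  expect_equal(seeds(res), "c0")
  expect_equal(finalInfluence(res), 1.5)

  # exhaustive check over single seeds
  bf <- bruteForceSeeds(star, 1)
  expect_equal(bf$seeds, seeds(res))
  expect_equal(bf$influence, finalInfluence(res))

  # two disconnected triangles: one seed lands in each component
  g <- edge_graph(c("a", "a", "b", "x", "x", "y"),
                  c("b", "c", "c", "y", "z", "z"),
                  c(0.75, 0.75, 0.75, 0.5, 0.5, 0.5))
  res2 <- selectSeedsGreedy(g, 2)
  comp1 <- c("a", "b", "c"); comp2 <- c("x", "y", "z")
  expect_equal(sum(seeds(res2) %in% comp1), 1L)
  expect_equal(sum(seeds(res2) %in% comp2), 1L)
  bf2 <- bruteForceSeeds(g, 2)
  expect_equal(sort(seeds(res2)), bf2$seeds)

  # repeated runs identical
  expect_identical(seeds(selectSeedsGreedy(g, 3)), seeds(selectSeedsGreedy(g, 3)))

  # degenerate: every node a seed, no targets left
  res3 <- selectSeedsGreedy(star_graph(2, 1), 3)
  expect_equal(finalInfluence(res3), 0)

  expect_error(selectSeedsGreedy(star, 10), "exceeds")
})

test_that("greedy trace is nondecreasing while targets remain plentiful", {
  g <- generateGraph(30, 60, seed = 9)
  res <- selectSeedsGreedy(g, 5)
  expect_true(all(diff(influenceTrace(res)) >= -1e-12))
  # first trace value is the argmax single-node influence
  infl <- vapply(nodeNames(g), function(u) nodeInfluence(g, u), numeric(1))
  expect_equal(influenceTrace(res)[1], max(infl))
  expect_equal(seeds(res)[1], names(which.max(infl)))
})

test_that("colored queries rank sources by influence on the fixed targets", {
  g <- edge_graph(c("g1", "g2"), c("d1", "d1"), c(1, 0.25),
                  colors = c(g1 = "gene", g2 = "gene", d1 = "disease"))
  res <- queryInfluencers(g, targets = "d1", k = 1, sourceColor = "gene")
  expect_equal(seeds(res), "g1")
  expect_equal(finalInfluence(res), 1)

  # unreachable targets: all-zero influence, lexicographic tie-break
  iso <- generateGraph(5, 0, seed = 3, colorFractions = c(gene = 0.8, disease = 0.2))
  genes <- names(which(nodeColors(iso) == "gene"))
  dis <- names(which(nodeColors(iso) == "disease"))
  res0 <- queryInfluencers(iso, targets = dis[1], k = 2, sourceColor = "gene")
  expect_equal(seeds(res0), sort(genes)[1:2])
  expect_equal(finalInfluence(res0), 0)

  expect_error(queryInfluencers(g, targets = "nope", k = 1), "unknown target")
})

test_that("query results match the exhaustive 2-subset optimum", {
  for (sd in c(21, 22, 23)) {
    g <- generateGraph(8, 12, seed = sd,
                       colorFractions = c(gene = 0.75, disease = 0.25))
    cols <- nodeColors(g)
    dis <- names(cols)[cols == "disease"]
    genes <- sort(names(cols)[cols == "gene"])
    if (length(dis) < 1 || length(genes) < 3) next
    res <- queryInfluencers(g, targets = dis, k = 2, sourceColor = "gene")
    M <- sipMatrix(g)
    scoreS <- function(S) sum(1 - apply(1 - M[S, dis, drop = FALSE], 2, prod))
    best <- max(vapply(utils::combn(genes, 2, simplify = FALSE), scoreS,
                       numeric(1)))
    expect_equal(finalInfluence(res), best, tolerance = 1e-12)
  }
})

test_that("suite relevance sums combined SIP over the disease suite", {
  g <- edge_graph(c("g1", "g2"), c("d1", "d1"), c(0.75, 0.5),
                  colors = c(g1 = "gene", g2 = "gene", d1 = "disease"))
  expect_equal(relevance(suiteRelevance(g, "g1", "d1")), 0.75)
  # two genes, noisy-OR: 1 - (1-0.75)(1-0.5) = 0.875
  expect_equal(relevance(suiteRelevance(g, c("g1", "g2"), "d1")), 0.875)
  expect_equal(relevance(suiteRelevance(g, c("g1", "g2"), "d1",
                                        aggregator = "max")), 0.75)
  expect_equal(relevance(suiteRelevance(g, "g1", character())), 0)
  expect_error(suiteRelevance(g, c("g1", "d1"), "d1"), "disjoint")
})

test_that("brute-force oracles refuse oversized graphs and agree on 2 nodes", {
  g2 <- edge_graph("a", "b", 0.5)
  expect_equal(bruteForceSip(g2, "a", "b"), sip(g2, "a", "b"))
  big <- generateGraph(11, 10, seed = 1)
  expect_error(bruteForceSip(big, "n001", "n002"), "refusing")
  expect_error(bruteForceSeeds(big, 2), "refusing")
})

test_that("adding an edge never decreases any sip (monotonicity)", {
  set.seed(31)
  for (rep in 1:20) {
    n <- 6
    m <- sample(3:8, 1)
    g <- generateGraph(n, m, seed = 100 + rep)
    et <- edgeTable(g)
    # add one absent edge
    all_pairs <- t(utils::combn(nodeNames(g), 2))
    present <- paste(pmin(et$source, et$target), pmax(et$source, et$target))
    absent <- all_pairs[!(paste(all_pairs[, 1], all_pairs[, 2]) %in% present), ,
                        drop = FALSE]
    if (!nrow(absent)) next
    pick <- absent[sample.int(nrow(absent), 1), ]
    aug <- rbind(et[c("source", "target", "weight")],
                 data.frame(source = pick[1], target = pick[2], weight = 0.75))
    g2 <- edge_graph(aug$source, aug$target, aug$weight)
    common <- nodeNames(g2)  # g may have isolated nodes g2 lacks
    M1 <- sipMatrix(g)[common, common]
    M2 <- sipMatrix(g2)[common, common]
    expect_true(all(M2 >= M1 - 1e-12))
  }
})
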