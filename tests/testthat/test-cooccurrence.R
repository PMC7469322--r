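# Evidence typing, aggregation, filtering, graph construction, and the
# soft-threshold expression adjacency.

classify <- function(abstract, terms = defaultInteractionTerms()) {
  d <- toy_doc(abstract)
  ents <- tagEntities(d, toy_lexicon())
  classifyPairInDocument(d, ents, c("GENEA", "GENEB"), terms)
}

test_that("the four evidence types map to their fixed confidence scores", {
  expect_equal(evidenceScore(1:4), c(1, 0.75, 0.5, 0.25))
  expect_error(evidenceScore(5), "1..4")

  ev <- classify("GENEA activates GENEB.")
  expect_equal(ev$etype, 1L); expect_equal(ev$score, 1)

  # term present in the sentence but not between the names
  ev <- classify("Striking activation preceded shifts in GENEA and GENEB.")
  expect_equal(ev$etype, 2L); expect_equal(ev$score, 0.75)

  ev <- classify("GENEA and GENEB were measured.")
  expect_equal(ev$etype, 3L); expect_equal(ev$score, 0.5)

  ev <- classify("GENEA was examined. Separately GENEB was recorded.")
  expect_equal(ev$etype, 4L); expect_equal(ev$score, 0.25)

  expect_null(classify("GENEA alone was measured."))
})

test_that("'between' means strictly between the entity names", {
  # term after both entities: sentence-level only
  ev <- classify("GENEA and GENEB show activation.")
  expect_equal(ev$etype, 2L)
  # order of the entities does not matter for betweenness
  ev <- classify("GENEB inhibits GENEA.")
  expect_equal(ev$etype, 1L)
})

test_that("a document yields one evidence row per pair, the strongest type", {
  d <- toy_doc("GENEA and GENEB were measured. GENEA activates GENEB.")
  ents <- tagEntities(d, toy_lexicon())
  ev <- classifyPairInDocument(d, ents, c("GENEA", "GENEB"))
  expect_equal(ev$etype, 1L)

  ev_all <- extractEvidence(list(d), toy_lexicon())
  expect_equal(nrow(ev_all), 1L)
})

test_that("aggregation tallies counts and takes the maximum confidence", {
  ev <- data.frame(doc_id = c("d1", "d2", "d3"), a = "A", b = "B",
                   etype = c(3L, 3L, 1L), score = c(0.5, 0.5, 1),
                   stringsAsFactors = FALSE)
  rec <- aggregateEvidence(ev)
  expect_equal(rec$count_total, 3L)
  expect_equal(rec$count_type3, 2L)
  expect_equal(rec$count_type1, 1L)
  expect_equal(rec$confidence, 1)

  one <- aggregateEvidence(data.frame(doc_id = "d1", a = "A", b = "B",
                                      etype = 4L, score = 0.25))
  expect_equal(one$count_total, 1L)
  expect_equal(one$confidence, 0.25)

  expect_equal(nrow(aggregateEvidence(ev[0, ])), 0L)

  dup <- rbind(ev, ev[1, ])
  expect_error(aggregateEvidence(dup), "duplicate evidence")
})

test_that("edge filtering drops low-support pairs and applies the confidence cutoff", {
  rec <- data.frame(a = c("A", "C"), b = c("B", "D"),
                    count_total = c(5L, 6L),
                    count_type1 = c(0L, 0L), count_type2 = c(0L, 0L),
                    count_type3 = c(5L, 6L), count_type4 = c(0L, 0L),
                    confidence = c(0.5, 0.5), stringsAsFactors = FALSE)
  kept <- filterEdges(rec, minCount = 5)
  expect_equal(kept$a, "C")  # count <= 5 removed, count 6 survives

  rec$confidence <- c(1, 0.75)
  kept <- filterEdges(rec, minCount = 0, minConfidence = 0.90)
  expect_equal(kept$confidence, 1)  # only type-1-backed edges reach 0.90

  expect_equal(filterEdges(rec, minCount = 0), rec)  # identity
})

test_that("raising minCount only removes edges (monotonicity)", {
  set.seed(7)
  rec <- data.frame(a = paste0("A", 1:20), b = paste0("B", 1:20),
                    count_total = sample.int(10, 20, replace = TRUE),
                    count_type1 = 0L, count_type2 = 0L, count_type3 = 0L,
                    count_type4 = 0L, confidence = 0.5,
                    stringsAsFactors = FALSE)
  prev <- filterEdges(rec, minCount = 0)
  for (mc in 1:10) {
    cur <- filterEdges(rec, minCount = mc)
    expect_true(all(paste(cur$a, cur$b) %in% paste(prev$a, prev$b)))
    prev <- cur
  }
})

test_that("graph construction colors nodes and carries confidences as weights", {
  lex <- Lexicon(c("A", "B", "C"), NULL, c("gene", "gene", "disease"))
  rec <- aggregateEvidence(data.frame(doc_id = "d1", a = "A", b = "B",
                                      etype = 2L, score = 0.75))
  g <- buildGraph(rec, lex)
  expect_equal(sort(nodeNames(g)), c("A", "B"))
  expect_equal(edgeTable(g)$weight, 0.75)

  tri <- data.frame(doc_id = c("d1", "d2", "d3"),
                    a = c("A", "A", "B"), b = c("B", "C", "C"),
                    etype = 3L, score = 0.5)
  g3 <- buildGraph(aggregateEvidence(tri), lex)
  expect_equal(length(nodeNames(g3)), 3L)
  expect_equal(nrow(edgeTable(g3)), 3L)
  expect_equal(unname(nodeColors(g3)["C"]), "disease")

  expect_error(buildGraph(aggregateEvidence(
    data.frame(doc_id = "d", a = "A", b = "ZZZ", etype = 1L, score = 1)), lex),
    "missing from lexicon")
})

test_that("edge lists survive a write/read round trip", {
  g <- edge_graph(c("A", "A", "B"), c("B", "C", "C"), c(1, 0.5, 0.25),
                  colors = c(A = "gene", B = "gene", C = "disease"))
  path <- withr::local_tempfile(fileext = ".tsv")
  writeEdgeList(g, path)
  back <- readEdgeList(path)
  expect_equal(sort(nodeNames(back)), sort(nodeNames(g)))
  expect_equal(nodeColors(back)[sort(nodeNames(back))],
               nodeColors(g)[sort(nodeNames(g))])
  et <- function(x) {
    d <- edgeTable(x); d <- d[order(d$source, d$target), ]
    rownames(d) <- NULL; d
  }
  expect_equal(et(back), et(g))
})

test_that("soft-threshold adjacency follows |cor|^beta with diagonal excluded", {
  X <- rbind(g1 = c(1, 2, 3, 4, 5),
             g2 = c(2, 4, 6, 8, 10),        # identical profile to g1 (r = 1)
             g3 = c(5, 4, 3, 1, 0),         # strongly anti-correlated
             g4 = c(1.2, 0.7, 2.9, 1.1, 2.4))
  adj <- softThresholdAdjacency(X, beta = 2)
  s <- adj@correlations
  a <- adj@adjacency
  expect_equal(a["g1", "g2"], 1)                       # perfect correlation
  expect_equal(a["g1", "g3"], abs(s["g1", "g3"])^2)    # |s|^beta convention
  expect_true(s["g1", "g3"] < 0)                       # negative source corr
  expect_true(all(is.na(diag(a))))
  expect_equal(a, t(a))
  expect_true(all(a[!is.na(a)] >= 0 & a[!is.na(a)] <= 1))
})

test_that("adjacency is monotone nonincreasing in beta when |s| < 1", {
  set.seed(11)
  X <- matrix(rnorm(40), nrow = 5)
  rownames(X) <- paste0("g", 1:5)
  a1 <- softThresholdAdjacency(X, beta = 1)@adjacency
  a3 <- softThresholdAdjacency(X, beta = 3)@adjacency
  off <- upper.tri(a1)
  expect_true(all(a3[off] <= a1[off] + 1e-12))
})

test_that("zero-variance genes are excluded with a warning", {
  X <- rbind(g1 = c(1, 2, 3), g2 = c(3, 1, 2), flat = c(2, 2, 2))
  expect_warning(adj <- softThresholdAdjacency(X, beta = 1), "flat")
  expect_equal(adj@dropped, "flat")
  expect_equal(rownames(adj@adjacency), c("g1", "g2"))
})
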