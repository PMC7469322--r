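# Strongest-Influence-Path (SIP) probabilities and greedy IM-SIP seed
# selection on the weighted colored co-occurrence graph.
#
# Edge weights are influence probabilities in (0, 1]; the influence of a
# path is the product of its edge weights, and the pairwise influence
# sip(u, v) is the maximum over all paths. Because all weights are <= 1 the
# maximum-product path is exactly the least-cost path under edge costs
# -log(weight) >= 0, so sip is computed with a nonnegative least-cost search
# rather than path enumeration.
#
# "Combined influence" of a seed set on a target combines the per-seed SIP
# probabilities with noisy-OR, 1 - prod(1 - sigma), treating the strongest
# paths from different seeds as independent influence channels (the "max"
# alternative takes the single strongest seed). Noisy-OR makes the
# seed-selection objective monotone and submodular, which underwrites the
# (1 - 1/e) guarantee of the greedy heuristic.

.check_nodes <- function(graph, nodes, what = "node") {
  miss <- setdiff(nodes, nodeNames(graph))
  if (length(miss))
    stop("unknown ", what, "(s): ", paste(miss, collapse = ", "))
}

.eligible <- function(graph, color) {
  nm <- nodeNames(graph)
  if (identical(color, "all")) return(nm)
  nm[nodeColors(graph)[nm] == color]
}

#' Pairwise strongest-influence-path matrix
#'
#' All-pairs SIP probabilities: entry (u, v) is the maximum over all u-v
#' paths of the product of edge weights, 1 on the diagonal, 0 for
#' unreachable pairs. Computed via least-cost search on edge costs
#' `-log(weight)`.
#'
#' @param graph a [CoocGraph-class].
#' @return symmetric numeric matrix with node names as dimnames.
#' @export
sipMatrix <- function(graph) {
  g <- graph@graph
  if (igraph::ecount(g) == 0) {
    n <- igraph::vcount(g)
    m <- diag(1, n)
    dimnames(m) <- list(nodeNames(graph), nodeNames(graph))
    return(m)
  }
  d <- igraph::distances(g, weights = -log(igraph::E(g)$weight),
                         algorithm = "dijkstra")
  exp(-d)
}

#' Strongest-influence-path probability between two nodes
#'
#' @param graph a [CoocGraph-class].
#' @param source,dest node names present in the graph.
#' @return probability in \[0, 1\]; `sip(u, u) = 1`; 0 when unreachable.
#' @seealso [sipFrom()] for the single-source batch, [bruteForceSip()] for
#'   the exhaustive oracle.
#' @export
sip <- function(graph, source, dest) {
  .check_nodes(graph, c(source, dest))
  unname(sipFrom(graph, source)[dest])
}

#' Single-source SIP probabilities
#'
#' One least-cost search giving `sip(source, v)` for every node `v`.
#'
#' @param graph a [CoocGraph-class].
#' @param source a node name.
#' @return named numeric vector over all nodes.
#' @export
sipFrom <- function(graph, source) {
  .check_nodes(graph, source)
  g <- graph@graph
  w <- if (igraph::ecount(g)) -log(igraph::E(g)$weight) else numeric()
  d <- igraph::distances(g, v = source, weights = w, algorithm = "dijkstra")
  stats::setNames(exp(-d[1, ]), colnames(d))
}

# combined influence of the seed rows of sip matrix M on each target column
.combine_cols <- function(M, S, targets, aggregator) {
  sub <- M[S, targets, drop = FALSE]
  if (aggregator == "noisy_or") 1 - apply(1 - sub, 2L, prod)
  else apply(sub, 2L, max)
}

#' Influence of a single node on the graph
#'
#' Sum of SIP probabilities from `u` to every eligible target: nodes other
#' than `u` that match `targetColor` and are not listed in `exclude`
#' (e.g. already-selected seeds).
#'
#' @param graph a [CoocGraph-class].
#' @param u node name.
#' @param targetColor a node color, or `"all"`.
#' @param exclude nodes to leave out of the target set.
#' @return non-negative influence value.
#' @export
nodeInfluence <- function(graph, u, targetColor = "all", exclude = character()) {
  .check_nodes(graph, u)
  targets <- setdiff(.eligible(graph, targetColor), c(u, exclude))
  if (!length(targets)) return(0)
  sum(sipFrom(graph, u)[targets])
}

#' Combined influence of a seed set
#'
#' Sum over eligible targets (matching `targetColor`, not in `S`) of the
#' combined per-seed SIP probabilities: noisy-OR `1 - prod(1 - sigma)` by
#' default, or the maximum.
#'
#' @param graph a [CoocGraph-class].
#' @param S non-empty character vector of seed nodes.
#' @param aggregator `"noisy_or"` or `"max"`.
#' @param targetColor a node color, or `"all"`.
#' @param sipmat optional precomputed [sipMatrix()].
#' @return non-negative influence value.
#' @export
setInfluence <- function(graph, S, aggregator = c("noisy_or", "max"),
                         targetColor = "all", sipmat = NULL) {
  aggregator <- match.arg(aggregator)
  if (!length(S)) stop("seed set must be non-empty")
  .check_nodes(graph, S)
  targets <- setdiff(.eligible(graph, targetColor), S)
  if (!length(targets)) return(0)
  M <- if (is.null(sipmat)) sipMatrix(graph) else sipmat
  sum(.combine_cols(M, S, targets, aggregator))
}

# Shared greedy engine. `targets_of(S_and_u)` returns the target set given
# the would-be seed set; candidates are scanned in lexicographic order and
# strict improvement keeps the first (lexicographically smallest) argmax.
.greedy <- function(M, candidates, numSeeds, targets_of, aggregator) {
  candidates <- sort(candidates)
  S <- character()
  trace <- numeric()
  state <- stats::setNames(rep(if (aggregator == "noisy_or") 1 else 0,
                               ncol(M)), colnames(M))
  for (it in seq_len(numSeeds)) {
    best <- -Inf; bestu <- NA_character_
    for (u in setdiff(candidates, S)) {
      tg <- targets_of(c(S, u))
      if (length(tg)) {
        val <- if (aggregator == "noisy_or")
          sum(1 - state[tg] * (1 - M[u, tg]))
        else
          sum(pmax(state[tg], M[u, tg]))
      } else val <- 0
      if (val > best) { best <- val; bestu <- u }
    }
    S <- c(S, bestu)
    state <- if (aggregator == "noisy_or") state * (1 - M[bestu, ])
             else pmax(state, M[bestu, ])
    tg <- targets_of(S)
    trace <- c(trace, if (length(tg)) {
      if (aggregator == "noisy_or") sum(1 - state[tg]) else sum(state[tg])
    } else 0)
  }
  list(seeds = S, trace = trace)
}

#' Greedy IM-SIP seed selection
#'
#' The greedy influence-maximization heuristic: the first seed is the node
#' with the highest single-node influence; every later iteration adds the
#' eligible node whose inclusion maximizes the combined influence of the
#' enlarged seed set on the remaining eligible targets (marginal-gain
#' greedy). Ties are broken lexicographically by node name, so the result is
#' deterministic.
#'
#' @param graph a [CoocGraph-class].
#' @param numSeeds number of seeds `s >= 1`; must not exceed the number of
#'   eligible source nodes.
#' @param aggregator `"noisy_or"` (default) or `"max"` combination rule.
#' @param sourceColor restrict seed candidates to this color (`"all"`: none).
#' @param targetColor restrict influence targets to this color.
#' @return a [SeedResult-class]: seeds in selection order plus the combined
#'   influence after each addition.
#' @export
selectSeedsGreedy <- function(graph, numSeeds,
                              aggregator = c("noisy_or", "max"),
                              sourceColor = "all", targetColor = "all") {
  aggregator <- match.arg(aggregator)
  stopifnot(numSeeds >= 1)
  cand <- .eligible(graph, sourceColor)
  if (numSeeds > length(cand))
    stop("numSeeds (", numSeeds, ") exceeds the ", length(cand),
         " eligible source node(s)")
  M <- sipMatrix(graph)
  elig_t <- .eligible(graph, targetColor)
  res <- .greedy(M, cand, numSeeds,
                 targets_of = function(S) setdiff(elig_t, S),
                 aggregator = aggregator)
  new("SeedResult", seeds = res$seeds, trace = res$trace,
      config = list(mode = "select", num_seeds = numSeeds,
                    aggregator = aggregator, source_color = sourceColor,
                    target_color = targetColor))
}

#' Colored influence query against a fixed target set
#'
#' Greedy selection of the `k` nodes (restricted to `sourceColor`) most
#' influential on a fixed set of target nodes -- e.g. "find 5 genes most
#' closely related to a given disease set", or the reverse query with colors
#' swapped. Influence is summed over the fixed targets only; targets are
#' never candidates.
#'
#' @param graph a [CoocGraph-class].
#' @param targets fixed target node set (must exist in the graph).
#' @param k number of influencers to select.
#' @param sourceColor candidate color restriction (`"all"`: none).
#' @param aggregator `"noisy_or"` or `"max"`.
#' @return a [SeedResult-class].
#' @export
queryInfluencers <- function(graph, targets, k, sourceColor = "all",
                             aggregator = c("noisy_or", "max")) {
  aggregator <- match.arg(aggregator)
  stopifnot(k >= 1, length(targets) >= 1)
  .check_nodes(graph, targets, "target node")
  cand <- setdiff(.eligible(graph, sourceColor), targets)
  if (k > length(cand))
    stop("k (", k, ") exceeds the ", length(cand),
         " eligible source node(s) outside the target set")
  M <- sipMatrix(graph)
  res <- .greedy(M, cand, k,
                 targets_of = function(S) targets,
                 aggregator = aggregator)
  new("SeedResult", seeds = res$seeds, trace = res$trace,
      config = list(mode = "query", k = k, targets = targets,
                    aggregator = aggregator, source_color = sourceColor))
}

#' Relevance of a gene suite to a disease suite
#'
#' A reconstruction of the suite-to-suite relevance score: the sum over
#' diseases `d` of the combined (noisy-OR by default) SIP probability from
#' the gene suite, `sum_d combine({sip(g, d) : g in geneSuite})`. The exact
#' formula behind published relevance values is not pinned down, so the
#' combination rule is configurable and any significance cutoff is left to
#' the caller.
#'
#' @param graph a [CoocGraph-class].
#' @param geneSuite,diseaseSuite disjoint node sets present in the graph.
#' @param aggregator `"noisy_or"` or `"max"`.
#' @return a [SuiteRelevance-class].
#' @export
suiteRelevance <- function(graph, geneSuite, diseaseSuite,
                           aggregator = c("noisy_or", "max")) {
  aggregator <- match.arg(aggregator)
  .check_nodes(graph, c(geneSuite, diseaseSuite), "suite member")
  if (length(intersect(geneSuite, diseaseSuite)))
    stop("gene and disease suites must be disjoint")
  rel <- 0
  if (length(diseaseSuite) && length(geneSuite)) {
    M <- sipMatrix(graph)
    rel <- sum(.combine_cols(M, geneSuite, diseaseSuite, aggregator))
  }
  new("SuiteRelevance", geneSuite = as.character(geneSuite),
      diseaseSuite = as.character(diseaseSuite), relevance = rel)
}

#' Rank table for a seed-selection result
#'
#' @param result a [SeedResult-class].
#' @param graph the [CoocGraph-class] it was computed on.
#' @return data.frame `rank`, `node`, `color`, `marginal_gain`,
#'   `cumulative_influence`.
#' @export
rankTable <- function(result, graph) {
  tr <- influenceTrace(result)
  data.frame(rank = seq_along(seeds(result)),
             node = seeds(result),
             color = unname(nodeColors(graph)[seeds(result)]),
             marginal_gain = tr - c(0, utils::head(tr, -1)),
             cumulative_influence = tr,
             stringsAsFactors = FALSE)
}
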