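# Exhaustive oracles for small graphs. Both are deliberately independent of
# the least-cost-search implementation in influence.R: SIP by recursive
# enumeration of all simple paths, seed selection by exhaustive subset
# search over the brute-force SIP matrix. Exact, but exponential -- they
# refuse graphs above a node cap.

.check_cap <- function(graph, cap) {
  n <- igraph::vcount(graph@graph)
  if (n > cap)
    stop("refusing brute force on ", n, " nodes (cap ", cap,
         "); raise `cap` explicitly if you mean it")
}

# integer adjacency list: adj[[i]] = list(to = int vector, w = numeric)
.adj_list <- function(graph) {
  et <- edgeTable(graph)
  nm <- nodeNames(graph)
  adj <- lapply(seq_along(nm), function(i) list(to = integer(), w = numeric()))
  ai <- match(et$source, nm); bi <- match(et$target, nm)
  for (i in seq_len(nrow(et))) {
    adj[[ai[i]]]$to <- c(adj[[ai[i]]]$to, bi[i])
    adj[[ai[i]]]$w <- c(adj[[ai[i]]]$w, et$weight[i])
    adj[[bi[i]]]$to <- c(adj[[bi[i]]]$to, ai[i])
    adj[[bi[i]]]$w <- c(adj[[bi[i]]]$w, et$weight[i])
  }
  names(adj) <- nm
  adj
}

#' Brute-force strongest-influence-path probability
#'
#' Exhaustively enumerates every simple path from `source` to `dest` and
#' returns the maximum product of edge weights. Exact; used as the test
#' oracle for [sip()]. Refuses graphs above `cap` nodes.
#'
#' @param graph a [CoocGraph-class].
#' @param source,dest node names.
#' @param cap maximum allowed node count (default 10).
#' @return probability in \[0, 1\].
#' @export
bruteForceSip <- function(graph, source, dest, cap = 10) {
  .check_cap(graph, cap)
  .check_nodes(graph, c(source, dest))
  if (source == dest) return(1)
  adj <- .adj_list(graph)
  si <- match(source, names(adj)); di <- match(dest, names(adj))
  best <- 0
  visited <- logical(length(adj))
  walk <- function(u, prob) {
    if (u == di) { best <<- max(best, prob); return(invisible()) }
    visited[u] <<- TRUE
    nb <- adj[[u]]
    for (i in seq_along(nb$to)) {
      v <- nb$to[i]
      if (!visited[v]) walk(v, prob * nb$w[i])
    }
    visited[u] <<- FALSE
  }
  walk(si, 1)
  best
}

# full brute-force sip matrix (symmetric on undirected graphs)
.brute_sip_matrix <- function(graph, cap = 10) {
  nm <- sort(nodeNames(graph))
  M <- diag(1, length(nm))
  dimnames(M) <- list(nm, nm)
  for (i in seq_along(nm)) for (j in seq_along(nm)) if (i < j) {
    p <- bruteForceSip(graph, nm[i], nm[j], cap = cap)
    M[i, j] <- M[j, i] <- p
  }
  M
}

#' Brute-force optimal seed set
#'
#' Exhaustive search over all size-`numSeeds` subsets of the eligible source
#' nodes, scoring each by its combined influence (computed from the
#' brute-force SIP matrix) on the eligible targets outside the set. Exact
#' optimum; the oracle for [selectSeedsGreedy()]'s approximation guarantee.
#' Ties keep the lexicographically first subset.
#'
#' @param graph a [CoocGraph-class].
#' @param numSeeds seed-set size.
#' @param aggregator `"noisy_or"` or `"max"`.
#' @param sourceColor,targetColor color restrictions (`"all"`: none).
#' @param cap maximum allowed node count (default 10).
#' @return list with `seeds` (sorted character vector) and `influence`.
#' @export
bruteForceSeeds <- function(graph, numSeeds,
                            aggregator = c("noisy_or", "max"),
                            sourceColor = "all", targetColor = "all",
                            cap = 10) {
  aggregator <- match.arg(aggregator)
  .check_cap(graph, cap)
  cand <- sort(.eligible(graph, sourceColor))
  if (numSeeds > length(cand))
    stop("numSeeds exceeds the number of eligible source nodes")
  M <- .brute_sip_matrix(graph, cap = cap)
  elig_t <- .eligible(graph, targetColor)
  best <- -Inf; bestS <- NULL
  sets <- utils::combn(cand, numSeeds, simplify = FALSE)
  for (S in sets) {
    tg <- setdiff(elig_t, S)
    val <- if (length(tg)) sum(.combine_cols(M, S, tg, aggregator)) else 0
    if (val > best) { best <- val; bestS <- S }
  }
  list(seeds = bestS, influence = best)
}
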