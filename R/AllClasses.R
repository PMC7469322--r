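#' @import methods
#' @importFrom igraph vcount ecount
NULL

setOldClass("igraph")

#' Document: an abstract with sentence segmentation
#'
#' A single literature record: an identifier, a title, the abstract text, and
#' the sentence table produced by [splitSentences()]. Sentence offsets are
#' 0-based, half-open, counted in characters, and always satisfy
#' `substr(abstract, start + 1, end) == text`.
#'
#' @slot docId single character identifier, unique within a corpus.
#' @slot title title text (not scanned for entities).
#' @slot abstract abstract text, case preserved.
#' @slot sentences data.frame with columns `start`, `end` (0-based half-open
#'   character offsets into `abstract`) and `text`.
#' @export
setClass("Document",
  slots = c(
    docId = "character",
    title = "character",
    abstract = "character",
    sentences = "data.frame"
  )
)

setValidity("Document", function(object) {
  msgs <- character()
  if (length(object@docId) != 1L || !nzchar(object@docId))
    msgs <- c(msgs, "docId must be a single non-empty string")
  s <- object@sentences
  if (nrow(s)) {
    if (!all(c("start", "end", "text") %in% names(s)))
      return("sentences must have columns start, end, text")
    if (any(s$start < 0) || any(s$end > nchar(object@abstract)) ||
        any(s$start >= s$end))
      msgs <- c(msgs, "sentence spans must satisfy 0 <= start < end <= nchar(abstract)")
    if (is.unsorted(s$start) || any(utils::head(s$end, -1) > utils::tail(s$start, -1)))
      msgs <- c(msgs, "sentence spans must be sorted and non-overlapping")
    ok <- vapply(seq_len(nrow(s)), function(i) {
      substr(object@abstract, s$start[i] + 1L, s$end[i]) == s$text[i]
    }, logical(1))
    if (!all(ok))
      msgs <- c(msgs, "sentence text must equal the abstract substring at its span")
  }
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "Document", function(object) {
  cat("Document", object@docId, "|", nrow(object@sentences), "sentence(s),",
      nchar(object@abstract), "chars\n")
})

#' Lexicon: species-specific dictionary of entity symbols
#'
#' Canonical symbols with their synonyms, an entity class label ("color",
#' e.g. `"gene"` or `"disease"`) and a species tag. Canonical symbols are
#' unique, and no surface form (canonical or synonym, case-insensitively)
#' may map to more than one canonical: ambiguous dictionaries are rejected
#' rather than resolved by guessing.
#'
#' @slot entries data.frame with columns `canonical` (character), `synonyms`
#'   (list of character vectors), `color` (character), `species` (character).
#' @export
setClass("Lexicon", slots = c(entries = "data.frame"))

setValidity("Lexicon", function(object) {
  e <- object@entries
  need <- c("canonical", "synonyms", "color", "species")
  if (!all(need %in% names(e)))
    return("entries must have columns canonical, synonyms, color, species")
  if (anyDuplicated(e$canonical))
    return("duplicate canonical symbols in lexicon")
  syn <- unlist(e$synonyms, use.names = FALSE)
  if (length(syn) && any(!nzchar(syn)))
    return("empty synonym in lexicon")
  surfaces <- tolower(c(e$canonical, syn))
  if (anyDuplicated(surfaces))
    return(paste0("ambiguous lexicon: surface form(s) map to multiple entries: ",
                  paste(unique(surfaces[duplicated(surfaces)]), collapse = ", ")))
  TRUE
})

setMethod("show", "Lexicon", function(object) {
  e <- object@entries
  cat("Lexicon:", nrow(e), "entries (",
      paste(sprintf("%s=%d", names(table(e$color)), table(e$color)),
            collapse = ", "), ")\n")
})

#' CoocGraph: weighted colored co-occurrence graph
#'
#' Undirected graph over canonical symbols. Every node carries a color (entity
#' class) and every edge a weight in (0, 1] equal to the confidence of its
#' supporting evidence record -- one of 1, 0.75, 0.5, 0.25 for evidence types
#' 1-4. Edge weights are interpreted as influence probabilities by the
#' influence-maximization functions.
#'
#' @slot graph an undirected \pkg{igraph} object with vertex attribute
#'   `color` and edge attributes `weight`, `count_total`, `count_type1` ..
#'   `count_type4`.
#' @slot records the aggregated evidence table the graph was built from (one
#'   row per edge; see [aggregateEvidence()]).
#' @export
setClass("CoocGraph", slots = c(graph = "igraph", records = "data.frame"))

setValidity("CoocGraph", function(object) {
  g <- object@graph
  msgs <- character()
  if (igraph::is_directed(g))
    msgs <- c(msgs, "graph must be undirected")
  if (any(igraph::which_loop(g)))
    msgs <- c(msgs, "self-loops are not allowed")
  if (is.null(igraph::vertex_attr(g, "color")))
    msgs <- c(msgs, "every node must carry a color")
  w <- igraph::edge_attr(g, "weight")
  if (ecount(g) > 0 && (is.null(w) || any(w <= 0) || any(w > 1)))
    msgs <- c(msgs, "edge weights must lie in (0, 1]")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "CoocGraph", function(object) {
  g <- object@graph
  cols <- table(igraph::vertex_attr(g, "color"))
  cat("CoocGraph:", vcount(g), "nodes,", ecount(g), "edges\n")
  cat("  colors:", paste(sprintf("%s=%d", names(cols), cols), collapse = ", "), "\n")
  if (ecount(g))
    cat("  weights:", paste(sprintf("%g", sort(unique(igraph::edge_attr(g, "weight")))),
        collapse = " "), "\n")
})

#' SeedResult: outcome of greedy seed selection
#'
#' @slot seeds seed nodes in selection order.
#' @slot trace combined influence of the seed set after each addition
#'   (same length as `seeds`).
#' @slot config list echoing the selection configuration (aggregator, colors,
#'   number of seeds, fixed targets if any).
#' @export
setClass("SeedResult",
  slots = c(seeds = "character", trace = "numeric", config = "list")
)

setValidity("SeedResult", function(object) {
  if (length(object@seeds) != length(object@trace))
    return("trace must have one entry per selected seed")
  if (anyDuplicated(object@seeds))
    return("seeds must be distinct")
  TRUE
})

setMethod("show", "SeedResult", function(object) {
  cat("SeedResult:", length(object@seeds), "seed(s)\n")
  for (i in seq_along(object@seeds))
    cat(sprintf("  %d. %-12s influence %.6g\n", i, object@seeds[i], object@trace[i]))
})

#' SuiteRelevance: relevance of a gene suite to a disease suite
#'
#' The relevance score is a reconstruction: the sum over diseases of the
#' combined (noisy-OR by default) strongest-influence-path probability from
#' the gene suite. See [suiteRelevance()].
#'
#' @slot geneSuite,diseaseSuite disjoint node sets.
#' @slot relevance non-negative relevance score.
#' @export
setClass("SuiteRelevance",
  slots = c(geneSuite = "character", diseaseSuite = "character",
            relevance = "numeric")
)

setValidity("SuiteRelevance", function(object) {
  if (length(intersect(object@geneSuite, object@diseaseSuite)))
    return("gene and disease suites must be disjoint")
  if (object@relevance < 0) return("relevance must be >= 0")
  TRUE
})

setMethod("show", "SuiteRelevance", function(object) {
  cat(sprintf("SuiteRelevance: genes {%s} -> diseases {%s} = %.6g\n",
      paste(object@geneSuite, collapse = ","),
      paste(object@diseaseSuite, collapse = ","), object@relevance))
})

#' ExpressionAdjacency: soft-threshold expression adjacency
#'
#' Connection strengths `a_ij = |cor(x_i, x_j)|^beta` between gene expression
#' profiles (unsigned soft-threshold convention). The diagonal is excluded
#' (set to `NA`).
#'
#' @slot correlations pairwise Pearson correlation matrix `s`.
#' @slot adjacency the adjacency `a = |s|^beta`, diagonal `NA`.
#' @slot beta the soft-threshold exponent.
#' @slot dropped genes excluded for zero variance.
#' @export
setClass("ExpressionAdjacency",
  slots = c(correlations = "matrix", adjacency = "matrix",
            beta = "numeric", dropped = "character")
)

setMethod("show", "ExpressionAdjacency", function(object) {
  cat("ExpressionAdjacency:", nrow(object@adjacency), "genes, beta =",
      object@beta, "\n")
  if (length(object@dropped))
    cat("  dropped (zero variance):", paste(object@dropped, collapse = ", "), "\n")
})

# ---- accessors -------------------------------------------------------------

#' Accessors for litInfluence classes
#'
#' Small accessor generics: `docId`, `sentences`, `entries`, `nodeNames`,
#' `nodeColors`, `edgeTable`, `asIgraph`, `seeds`, `influenceTrace`,
#' `finalInfluence`, `relevance`.
#'
#' @param x an object of the documented classes.
#' @return The corresponding slot content; `edgeTable` returns one row per
#'   edge with endpoints, weight and evidence counts.
#' @name accessors
#' @aliases docId sentences entries nodeNames nodeColors edgeTable asIgraph
#'   seeds influenceTrace finalInfluence relevance
NULL

#' @rdname accessors
#' @export
setGeneric("docId", function(x) standardGeneric("docId"))
#' @rdname accessors
#' @export
setMethod("docId", "Document", function(x) x@docId)

#' @rdname accessors
#' @export
setGeneric("sentences", function(x) standardGeneric("sentences"))
#' @rdname accessors
#' @export
setMethod("sentences", "Document", function(x) x@sentences)

#' @rdname accessors
#' @export
setGeneric("entries", function(x) standardGeneric("entries"))
#' @rdname accessors
#' @export
setMethod("entries", "Lexicon", function(x) x@entries)

#' @rdname accessors
#' @export
setGeneric("nodeNames", function(x) standardGeneric("nodeNames"))
#' @rdname accessors
#' @export
setMethod("nodeNames", "CoocGraph", function(x) igraph::V(x@graph)$name)

#' @rdname accessors
#' @export
setGeneric("nodeColors", function(x) standardGeneric("nodeColors"))
#' @rdname accessors
#' @export
setMethod("nodeColors", "CoocGraph", function(x) {
  stats::setNames(igraph::V(x@graph)$color, igraph::V(x@graph)$name)
})

#' @rdname accessors
#' @export
setGeneric("edgeTable", function(x) standardGeneric("edgeTable"))
#' @rdname accessors
#' @export
setMethod("edgeTable", "CoocGraph", function(x) {
  g <- x@graph
  el <- igraph::as_edgelist(g, names = TRUE)
  df <- data.frame(source = el[, 1], target = el[, 2],
                   stringsAsFactors = FALSE)
  for (a in c("weight", "count_total", paste0("count_type", 1:4)))
    if (!is.null(igraph::edge_attr(g, a))) df[[a]] <- igraph::edge_attr(g, a)
  df
})

#' @rdname accessors
#' @export
setGeneric("asIgraph", function(x) standardGeneric("asIgraph"))
#' @rdname accessors
#' @export
setMethod("asIgraph", "CoocGraph", function(x) x@graph)

#' @rdname accessors
#' @export
setGeneric("seeds", function(x) standardGeneric("seeds"))
#' @rdname accessors
#' @export
setMethod("seeds", "SeedResult", function(x) x@seeds)

#' @rdname accessors
#' @export
setGeneric("influenceTrace", function(x) standardGeneric("influenceTrace"))
#' @rdname accessors
#' @export
setMethod("influenceTrace", "SeedResult", function(x) x@trace)

#' @rdname accessors
#' @export
setGeneric("finalInfluence", function(x) standardGeneric("finalInfluence"))
#' @rdname accessors
#' @export
setMethod("finalInfluence", "SeedResult", function(x) {
  if (length(x@trace)) x@trace[length(x@trace)] else 0
})

#' @rdname accessors
#' @export
setGeneric("relevance", function(x) standardGeneric("relevance"))
#' @rdname accessors
#' @export
setMethod("relevance", "SuiteRelevance", function(x) x@relevance)
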