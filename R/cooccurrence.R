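# Four-type co-occurrence evidence classification, corpus-level aggregation,
# edge filtering and construction of the weighted colored graph.
#
# The evidence hierarchy, strongest first:
#   type 1: both entities in one sentence with an interaction term strictly
#           between the entity names
#   type 2: both entities in one sentence with an interaction term anywhere
#           in that sentence
#   type 3: both entities share a sentence (no term)
#   type 4: both entities occur anywhere in the same abstract
# Confidence scores are fixed at 1, 0.75, 0.5 and 0.25 for types 1-4.
# Negations are not handled; evidence is per-document only (no cross-document
# co-occurrence).

#' Confidence score for an evidence type
#'
#' The fixed mapping from co-occurrence evidence types to confidence scores:
#' types 1, 2, 3, 4 score 1, 0.75, 0.5, 0.25 respectively. These scores are
#' also the influence-probability edge weights of the co-occurrence graph.
#'
#' @param etype integer vector with values in 1:4.
#' @return numeric scores.
#' @examples
#' evidenceScore(1:4)  # 1.00 0.75 0.50 0.25
#' @export
evidenceScore <- function(etype) {
  if (!all(etype %in% 1:4)) stop("evidence type must be in 1..4")
  c(1, 0.75, 0.5, 0.25)[etype]
}

# whole-word, case-insensitive interaction-term occurrences in a sentence;
# 0-based half-open spans
.find_terms <- function(text, terms) {
  out <- lapply(terms, function(t) .find_surface(text, t))
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out))
    return(data.frame(start = integer(), end = integer()))
  do.call(rbind, out)
}

#' Classify one entity pair within one document
#'
#' Returns the strongest (numerically smallest) applicable evidence type for
#' the pair in this document, with its confidence score, or `NULL` when the
#' pair does not co-occur in the document. "Strictly between" for type 1
#' means some interaction-term occurrence lies entirely after the end of the
#' earlier entity mention and before the start of the later one, within one
#' sentence.
#'
#' @param doc a [Document-class].
#' @param entities [tagEntities()] output for `doc`.
#' @param pair character vector of two canonical symbols.
#' @param terms interaction-term vector (see [defaultInteractionTerms()]).
#' @return one-row data.frame `doc_id`, `a`, `b`, `etype`, `score`, or `NULL`.
#' @export
classifyPairInDocument <- function(doc, entities, pair,
                                   terms = defaultInteractionTerms()) {
  stopifnot(is(doc, "Document"), length(pair) == 2L)
  if (nrow(entities) && !all(entities$doc_id == doc@docId))
    stop("entities do not belong to document ", doc@docId)
  a <- min(pair); b <- max(pair)
  ea <- entities[entities$canonical == a, , drop = FALSE]
  eb <- entities[entities$canonical == b, , drop = FALSE]
  if (!nrow(ea) || !nrow(eb) || a == b) return(NULL)

  shared <- intersect(ea$sentence_index, eb$sentence_index)
  etype <- 4L
  if (length(shared)) {
    etype <- 3L
    sents <- sentences(doc)
    for (si in shared) {
      tocc <- .find_terms(sents$text[si + 1L], terms)
      if (!nrow(tocc)) next
      etype <- min(etype, 2L)
      ma <- ea[ea$sentence_index == si, , drop = FALSE]
      mb <- eb[eb$sentence_index == si, , drop = FALSE]
      for (i in seq_len(nrow(ma))) for (j in seq_len(nrow(mb))) {
        lo <- min(ma$end[i], mb$end[j])      # end of the earlier entity
        hi <- max(ma$start[i], mb$start[j])  # start of the later entity
        if (any(tocc$start >= lo & tocc$end <= hi)) etype <- 1L
      }
      if (etype == 1L) break
    }
  }
  data.frame(doc_id = doc@docId, a = a, b = b, etype = etype,
             score = evidenceScore(etype), stringsAsFactors = FALSE)
}

#' Extract co-occurrence evidence from a corpus
#'
#' Tags every document, forms distinct pairs per document, and classifies
#' each pair, emitting at most one evidence row per (document, pair): the
#' strongest applicable type.
#'
#' @param docs list of [Document-class] objects.
#' @param lexicon a [Lexicon-class].
#' @param terms interaction-term vector.
#' @return data.frame `doc_id`, `a`, `b`, `etype`, `score`.
#' @export
extractEvidence <- function(docs, lexicon, terms = defaultInteractionTerms()) {
  out <- list()
  for (doc in docs) {
    ents <- tagEntities(doc, lexicon)
    prs <- distinctPairs(ents)
    for (k in seq_len(nrow(prs))) {
      ev <- classifyPairInDocument(doc, ents, c(prs$a[k], prs$b[k]), terms)
      if (!is.null(ev)) out[[length(out) + 1L]] <- ev
    }
  }
  if (!length(out))
    return(data.frame(doc_id = character(), a = character(), b = character(),
                      etype = integer(), score = numeric(),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Aggregate evidence into per-pair edge records
#'
#' Tallies, per unordered pair, the number of supporting documents overall
#' and by evidence type. The edge confidence is the maximum score observed
#' across documents, so it always lands on the four-level grid
#' \{1, 0.75, 0.5, 0.25\}.
#'
#' @param evidence [extractEvidence()] output; at most one row per
#'   (document, pair) -- duplicates are a validation error.
#' @return data.frame `a`, `b`, `count_total`, `count_type1` ..
#'   `count_type4`, `confidence`, sorted by pair.
#' @export
aggregateEvidence <- function(evidence) {
  empty <- data.frame(a = character(), b = character(), count_total = integer(),
                      count_type1 = integer(), count_type2 = integer(),
                      count_type3 = integer(), count_type4 = integer(),
                      confidence = numeric(), stringsAsFactors = FALSE)
  if (!nrow(evidence)) return(empty)
  key <- paste(evidence$doc_id, evidence$a, evidence$b, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate evidence for the same (document, pair): ",
         paste(utils::head(unique(gsub("\r", " / ", key[duplicated(key)])), 3),
               collapse = "; "))
  pk <- paste(evidence$a, evidence$b, sep = "\r")
  out <- lapply(split(evidence, pk), function(g) {
    cnt <- tabulate(g$etype, nbins = 4L)
    data.frame(a = g$a[1], b = g$b[1], count_total = nrow(g),
               count_type1 = cnt[1], count_type2 = cnt[2],
               count_type3 = cnt[3], count_type4 = cnt[4],
               confidence = max(g$score), stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  res <- res[order(res$a, res$b), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Filter edge records by support and confidence
#'
#' Keeps records whose document count is strictly greater than `minCount`
#' (so the default 5 removes pairs with a relevance rate less than or equal
#' to 5) and, if `minConfidence` is set, whose confidence is at least that
#' value. The confidence filter is off by default.
#'
#' @param records [aggregateEvidence()] output.
#' @param minCount non-negative integer; records with
#'   `count_total <= minCount` are dropped.
#' @param minConfidence numeric in (0, 1] or `NULL` (off).
#' @return the surviving records.
#' @export
filterEdges <- function(records, minCount = 5, minConfidence = NULL) {
  stopifnot(minCount >= 0)
  keep <- records$count_total > minCount
  if (!is.null(minConfidence)) keep <- keep & records$confidence >= minConfidence
  res <- records[keep, , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Build the weighted colored co-occurrence graph
#'
#' Nodes are the union of pair endpoints, colored via the lexicon; each edge
#' carries the record's confidence as its weight (an influence probability in
#' (0, 1]) together with the evidence counts. Undirected, no self-loops.
#'
#' @param records (filtered) [aggregateEvidence()] output.
#' @param lexicon a [Lexicon-class] resolving every endpoint to a color.
#' @return a [CoocGraph-class].
#' @export
buildGraph <- function(records, lexicon) {
  e <- entries(lexicon)
  syms <- sort(unique(c(records$a, records$b)))
  miss <- setdiff(syms, e$canonical)
  if (length(miss))
    stop("edge endpoint(s) missing from lexicon: ", paste(miss, collapse = ", "))
  if (any(records$a == records$b)) stop("self-loop in edge records")
  vdf <- data.frame(name = syms,
                    color = e$color[match(syms, e$canonical)],
                    stringsAsFactors = FALSE)
  edf <- data.frame(from = records$a, to = records$b,
                    weight = records$confidence,
                    count_total = records$count_total,
                    count_type1 = records$count_type1,
                    count_type2 = records$count_type2,
                    count_type3 = records$count_type3,
                    count_type4 = records$count_type4,
                    stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(edf, directed = FALSE, vertices = vdf)
  new("CoocGraph", graph = g, records = records)
}

# ---- serialization ---------------------------------------------------------

#' Evidence table I/O
#'
#' TSV with columns `doc_id`, `geneA`, `geneB`, `etype`, `score`.
#'
#' @param evidence [extractEvidence()] output.
#' @param path file path.
#' @export
writeEvidence <- function(evidence, path) {
  df <- data.frame(doc_id = evidence$doc_id, geneA = evidence$a,
                   geneB = evidence$b, etype = evidence$etype,
                   score = evidence$score, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname writeEvidence
#' @export
readEvidence <- function(path) {
  df <- utils::read.delim(path, sep = "\t", quote = "", header = TRUE,
                          check.names = FALSE, fileEncoding = "UTF-8")
  need <- c("doc_id", "geneA", "geneB", "etype", "score")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("evidence TSV is missing column(s): ", paste(miss, collapse = ", "))
  data.frame(doc_id = as.character(df$doc_id), a = as.character(df$geneA),
             b = as.character(df$geneB), etype = as.integer(df$etype),
             score = as.numeric(df$score), stringsAsFactors = FALSE)
}

#' Edge-list graph exchange format
#'
#' TSV with columns `source`, `target`, `weight`, `count_total`,
#' `count_type1` .. `count_type4`, `color_source`, `color_target`.
#' `readEdgeList` reconstructs the [CoocGraph-class] (colors come from the
#' color columns, no lexicon needed).
#'
#' @param graph a [CoocGraph-class].
#' @param path file path.
#' @export
writeEdgeList <- function(graph, path) {
  df <- edgeTable(graph)
  cols <- nodeColors(graph)
  df$color_source <- unname(cols[df$source])
  df$color_target <- unname(cols[df$target])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname writeEdgeList
#' @export
readEdgeList <- function(path) {
  if (!file.exists(path)) stop("edge-list file not found: ", path)
  df <- utils::read.delim(path, sep = "\t", quote = "", header = TRUE,
                          check.names = FALSE, fileEncoding = "UTF-8")
  need <- c("source", "target", "weight", "color_source", "color_target")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("edge-list TSV is missing column(s): ", paste(miss, collapse = ", "))
  for (cc in c("count_total", paste0("count_type", 1:4)))
    if (is.null(df[[cc]])) df[[cc]] <- NA_integer_
  a <- pmin(df$source, df$target); b <- pmax(df$source, df$target)
  records <- data.frame(a = a, b = b, count_total = df$count_total,
                        count_type1 = df$count_type1, count_type2 = df$count_type2,
                        count_type3 = df$count_type3, count_type4 = df$count_type4,
                        confidence = df$weight, stringsAsFactors = FALSE)
  col <- c(stats::setNames(df$color_source, df$source),
           stats::setNames(df$color_target, df$target))
  col <- col[!duplicated(names(col))]
  syms <- sort(names(col))
  vdf <- data.frame(name = syms, color = unname(col[syms]),
                    stringsAsFactors = FALSE)
  edf <- cbind(data.frame(from = records$a, to = records$b,
                          weight = records$confidence,
                          stringsAsFactors = FALSE),
               records[c("count_total", paste0("count_type", 1:4))])
  g <- igraph::graph_from_data_frame(edf, directed = FALSE, vertices = vdf)
  new("CoocGraph", graph = g, records = records)
}
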