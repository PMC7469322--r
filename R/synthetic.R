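# Synthetic corpora with planted typed co-occurrences, and random colored
# weighted graphs, with ground truth known by construction. Planted
# sentences are templated (not free text) so that each planted (pair, type)
# realizes exactly its evidence type under the classification rules; each
# document supports exactly one planted pair so no incidental cross-pair
# co-occurrence can arise. Seeds are mandatory, never defaulted.

.with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, !is.na(seed))
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else on.exit(rm(".Random.seed", envir = globalenv()))
  set.seed(as.integer(seed))
  expr
}

# one planted block per type; block sentences go at the start of the abstract
.planted_templates <- list(
  `1` = function(a, b) sprintf("%s activates %s.", a, b),
  `2` = function(a, b)
    sprintf("Striking activation preceded shifts in %s and %s together.", a, b),
  `3` = function(a, b) sprintf("%s and %s were measured together.", a, b),
  `4` = function(a, b)
    sprintf("%s was examined first. Separately %s was then recorded.", a, b)
)

.distractor_pool <- c(
  "The overall cohort was reviewed in detail.",
  "Baseline characteristics appeared broadly comparable.",
  "Sampling followed the archived protocol closely.",
  "Several covariates were summarized beforehand.",
  "Routine checks continued throughout the study.",
  "Follow-up visits occurred at fixed intervals.",
  "Data entry was verified by two curators."
)

.reserved_words <- function(terms) {
  txt <- c(unlist(lapply(.planted_templates, function(f) f("x", "y"))),
           .distractor_pool)
  words <- unlist(strsplit(tolower(txt), "[^a-z0-9]+"))
  unique(c(words[nzchar(words)], tolower(terms)))
}

#' Generate a synthetic corpus with planted typed co-occurrences
#'
#' Builds documents from fixed sentence templates so that each planted
#' (pair, evidence type) is realized exactly: type 1 puts an interaction
#' term between the two names, type 2 puts the term elsewhere in the shared
#' sentence, type 3 shares a sentence without a term, and type 4 puts the
#' entities in different sentences of the same abstract. Every document
#' supports exactly one planted pair, plus term-free, symbol-free distractor
#' sentences, so the returned ground-truth table is exactly what a correct
#' extract-and-aggregate pipeline must produce.
#'
#' @param plantedPairs data.frame with columns `a`, `b` (symbols), `etype`
#'   (1-4) and `ndocs` (number of supporting documents). The same pair may
#'   appear with several types.
#' @param geneSymbols,diseaseSymbols symbol vectors (unique across colors;
#'   must not collide with template vocabulary or interaction terms).
#' @param numDocs total documents, `>= sum(ndocs)`; the excess are
#'   distractor-only documents. Default: exactly the planted documents.
#' @param distractorsPerDoc distractor sentences appended to every document.
#' @param seed mandatory RNG seed.
#' @return list with `documents`, `lexicon`, `terms`, and `groundTruth`
#'   (the planted edge-record table in [aggregateEvidence()] layout).
#' @export
generateCorpus <- function(plantedPairs, geneSymbols,
                           diseaseSymbols = character(),
                           numDocs = NULL, distractorsPerDoc = 1,
                           seed) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(is.data.frame(plantedPairs) || is.null(plantedPairs))
  if (is.null(plantedPairs))
    plantedPairs <- data.frame(a = character(), b = character(),
                               etype = integer(), ndocs = integer())
  syms <- c(geneSymbols, diseaseSymbols)
  if (anyDuplicated(tolower(syms)))
    stop("symbol collision across colors: ",
         paste(unique(syms[duplicated(tolower(syms))]), collapse = ", "))
  terms <- defaultInteractionTerms()
  clash <- intersect(tolower(syms), .reserved_words(terms))
  if (length(clash))
    stop("symbol(s) collide with template vocabulary: ",
         paste(clash, collapse = ", "))
  if (nrow(plantedPairs)) {
    stopifnot(all(c("a", "b", "etype", "ndocs") %in% names(plantedPairs)),
              all(plantedPairs$etype %in% 1:4),
              all(plantedPairs$ndocs >= 1))
    bad <- setdiff(c(plantedPairs$a, plantedPairs$b), syms)
    if (length(bad))
      stop("planted pair member(s) not among the symbols: ",
           paste(bad, collapse = ", "))
    if (any(plantedPairs$a == plantedPairs$b))
      stop("planted self-pair")
  }

  nPlanted <- if (nrow(plantedPairs)) sum(plantedPairs$ndocs) else 0L
  if (is.null(numDocs)) numDocs <- nPlanted
  if (numDocs < nPlanted)
    stop("numDocs (", numDocs, ") smaller than the ", nPlanted,
         " planted documents")

  docs <- .with_seed(seed, {
    out <- vector("list", numDocs)
    di <- 0L
    mk_doc <- function(block) {
      di <<- di + 1L
      extra <- if (distractorsPerDoc > 0)
        sample(.distractor_pool, distractorsPerDoc, replace = TRUE)
      else character()
      Document(sprintf("doc%05d", di),
               title = sprintf("Synthetic abstract %d", di),
               abstract = paste(c(block, extra), collapse = " "))
    }
    for (k in seq_len(nrow(plantedPairs))) {
      f <- .planted_templates[[as.character(plantedPairs$etype[k])]]
      for (r in seq_len(plantedPairs$ndocs[k])) {
        d <- mk_doc(f(plantedPairs$a[k], plantedPairs$b[k]))
        out[[di]] <- d
      }
    }
    while (di < numDocs) { d <- mk_doc(character()); out[[di]] <- d }
    out
  })

  lexicon <- Lexicon(canonical = syms,
                     color = c(rep("gene", length(geneSymbols)),
                               rep("disease", length(diseaseSymbols))))

  gt <- if (nrow(plantedPairs)) {
    pp <- plantedPairs
    swap <- pp$a > pp$b
    tmp <- pp$a[swap]; pp$a[swap] <- pp$b[swap]; pp$b[swap] <- tmp
    ev <- data.frame(
      doc_id = sprintf("gtdoc%06d", seq_len(sum(pp$ndocs))),
      a = rep(pp$a, pp$ndocs), b = rep(pp$b, pp$ndocs),
      etype = rep(pp$etype, pp$ndocs),
      score = evidenceScore(rep(pp$etype, pp$ndocs)),
      stringsAsFactors = FALSE)
    aggregateEvidence(ev)
  } else aggregateEvidence(data.frame(doc_id = character(), a = character(),
                                      b = character(), etype = integer(),
                                      score = numeric()))

  list(documents = docs, lexicon = lexicon, terms = terms, groundTruth = gt)
}

#' Generate a random colored weighted graph
#'
#' Simple undirected graph with `numEdges` edges drawn uniformly at random
#' without replacement from all node pairs; edge weights drawn uniformly
#' from `weightLevels` (the four-level confidence grid by default) and node
#' colors assigned by `colorFractions`. Deterministic given `seed`.
#'
#' @param numNodes,numEdges graph size; `numEdges <= numNodes*(numNodes-1)/2`.
#' @param weightLevels non-empty subset of `c(0.25, 0.5, 0.75, 1)`.
#' @param colorFractions named numeric vector of color proportions summing
#'   to 1, e.g. `c(gene = 0.9, disease = 0.1)`.
#' @param seed mandatory RNG seed.
#' @return a [CoocGraph-class].
#' @export
generateGraph <- function(numNodes, numEdges,
                          weightLevels = c(0.25, 0.5, 0.75, 1),
                          colorFractions = c(gene = 1), seed) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(numNodes >= 1, numEdges >= 0,
            all(weightLevels %in% c(0.25, 0.5, 0.75, 1)),
            length(weightLevels) >= 1,
            !is.null(names(colorFractions)),
            abs(sum(colorFractions) - 1) < 1e-8)
  maxE <- numNodes * (numNodes - 1) / 2
  if (numEdges > maxE)
    stop("numEdges (", numEdges, ") exceeds the ", maxE, " possible pairs")

  width <- max(3L, nchar(as.character(numNodes)))
  nm <- sprintf(paste0("n%0", width, "d"), seq_len(numNodes))

  .with_seed(seed, {
    counts <- floor(colorFractions * numNodes)
    rem <- numNodes - sum(counts)
    if (rem > 0) counts[seq_len(rem)] <- counts[seq_len(rem)] + 1L
    colors <- sample(rep(names(counts), counts))

    if (numEdges > 0) {
      idx <- sort(sample.int(maxE, numEdges))
      ut <- which(upper.tri(matrix(nrow = numNodes, ncol = numNodes)))
      ij <- arrayInd(ut[idx], c(numNodes, numNodes))
      w <- sample(weightLevels, numEdges, replace = TRUE)
      etype <- match(w, c(1, 0.75, 0.5, 0.25))
      records <- data.frame(
        a = nm[ij[, 1]], b = nm[ij[, 2]],
        count_total = 1L,
        count_type1 = as.integer(etype == 1L),
        count_type2 = as.integer(etype == 2L),
        count_type3 = as.integer(etype == 3L),
        count_type4 = as.integer(etype == 4L),
        confidence = w, stringsAsFactors = FALSE)
      records <- records[order(records$a, records$b), , drop = FALSE]
      rownames(records) <- NULL
      edf <- cbind(data.frame(from = records$a, to = records$b,
                              weight = records$confidence,
                              stringsAsFactors = FALSE),
                   records[c("count_total", paste0("count_type", 1:4))])
    } else {
      records <- data.frame(a = character(), b = character(),
                            count_total = integer(), count_type1 = integer(),
                            count_type2 = integer(), count_type3 = integer(),
                            count_type4 = integer(), confidence = numeric())
      edf <- data.frame(from = character(), to = character(),
                        weight = numeric())
    }
    vdf <- data.frame(name = nm, color = colors, stringsAsFactors = FALSE)
    g <- igraph::graph_from_data_frame(edf, directed = FALSE, vertices = vdf)
    new("CoocGraph", graph = g, records = records)
  })
}
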