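# Dictionary-based entity recognition. Matching is case-insensitive and
# word-boundary anchored (a boundary is a non-alphanumeric neighbour or the
# string edge); overlapping candidates are resolved longest-match-first,
# then leftmost. Each match is normalized to its canonical symbol.

.rx_escape <- function(x) gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", x)

# all whole-word matches of `surface` in `text`; 0-based half-open offsets
.find_surface <- function(text, surface) {
  pat <- paste0("(?<![A-Za-z0-9])", .rx_escape(surface), "(?![A-Za-z0-9])")
  m <- gregexpr(pat, text, perl = TRUE, ignore.case = TRUE)[[1]]
  if (m[1] == -1) return(NULL)
  data.frame(start = as.integer(m) - 1L,
             end = as.integer(m) + attr(m, "match.length") - 1L)
}

#' Tag entity mentions in a document
#'
#' Scans every sentence of `doc` for canonical symbols and synonyms from
#' `lexicon`. Matching is case-insensitive and anchored at word boundaries
#' (alphanumeric runs), so `TP53` is not found inside `TP533`. When candidate
#' matches overlap, the longer match wins (preferring specific multiword
#' names), ties broken leftmost; the surviving mentions within a sentence
#' never overlap. Every mention is normalized to its canonical symbol.
#'
#' @param doc a [Document-class] with sentences populated.
#' @param lexicon a [Lexicon-class].
#' @return data.frame with columns `doc_id`, `sentence_index` (0-based),
#'   `start`, `end` (0-based half-open offsets within the sentence),
#'   `mention`, `canonical`, `color`; zero rows if nothing matches.
#' @export
tagEntities <- function(doc, lexicon) {
  stopifnot(is(doc, "Document"), is(lexicon, "Lexicon"))
  e <- entries(lexicon)
  if (!nrow(e)) stop("lexicon is empty")
  surf <- data.frame(
    surface = c(e$canonical, unlist(e$synonyms, use.names = FALSE)),
    canonical = c(e$canonical,
                  rep(e$canonical, lengths(e$synonyms))),
    stringsAsFactors = FALSE)
  surf$color <- e$color[match(surf$canonical, e$canonical)]

  sents <- sentences(doc)
  out <- list()
  for (si in seq_len(nrow(sents))) {
    txt <- sents$text[si]
    cand <- list()
    for (k in seq_len(nrow(surf))) {
      hits <- .find_surface(txt, surf$surface[k])
      if (is.null(hits)) next
      hits$canonical <- surf$canonical[k]
      hits$color <- surf$color[k]
      cand[[length(cand) + 1L]] <- hits
    }
    if (!length(cand)) next
    cand <- do.call(rbind, cand)
    cand <- cand[order(-(cand$end - cand$start), cand$start), , drop = FALSE]
    taken <- logical(nrow(cand))
    occ <- rep(FALSE, nchar(txt))
    for (k in seq_len(nrow(cand))) {
      span <- (cand$start[k] + 1L):cand$end[k]
      if (!any(occ[span])) { occ[span] <- TRUE; taken[k] <- TRUE }
    }
    kept <- cand[taken, , drop = FALSE]
    kept <- kept[order(kept$start), , drop = FALSE]
    out[[length(out) + 1L]] <- data.frame(
      doc_id = doc@docId, sentence_index = si - 1L,
      start = kept$start, end = kept$end,
      mention = substring(txt, kept$start + 1L, kept$end),
      canonical = kept$canonical, color = kept$color,
      stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(doc_id = character(), sentence_index = integer(),
                      start = integer(), end = integer(), mention = character(),
                      canonical = character(), color = character(),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Tag every document of a corpus
#'
#' @param docs list of [Document-class] objects.
#' @param lexicon a [Lexicon-class].
#' @return row-bound [tagEntities()] output for all documents.
#' @export
tagCorpus <- function(docs, lexicon) {
  res <- lapply(docs, tagEntities, lexicon = lexicon)
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Distinct unordered entity pairs per document
#'
#' Collapses tagged mentions to the distinct unordered pairs of canonical
#' symbols co-occurring within each document. Self-pairs are excluded and
#' duplicates collapsed. Pair members are returned in sorted order
#' (`a < b`).
#'
#' @param entities [tagEntities()]/[tagCorpus()] output.
#' @return data.frame with columns `doc_id`, `a`, `b`.
#' @export
distinctPairs <- function(entities) {
  empty <- data.frame(doc_id = character(), a = character(), b = character(),
                      stringsAsFactors = FALSE)
  if (!nrow(entities)) return(empty)
  out <- lapply(split(entities$canonical, entities$doc_id), function(cs) {
    cs <- sort(unique(cs))
    if (length(cs) < 2L) return(NULL)
    cmb <- utils::combn(cs, 2L)
    data.frame(a = cmb[1, ], b = cmb[2, ], stringsAsFactors = FALSE)
  })
  keep <- !vapply(out, is.null, logical(1))
  if (!any(keep)) return(empty)
  res <- do.call(rbind, Map(function(id, df) cbind(doc_id = id, df),
                            names(out)[keep], out[keep]))
  rownames(res) <- NULL
  res
}
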