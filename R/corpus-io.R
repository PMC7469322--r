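# Reading/writing corpora, lexicons and interaction-term lists, and the
# rule-based sentence splitter. Offsets throughout are 0-based, half-open,
# counted in characters; text is stored case-preserved.

# Tokens (including their final period) that never end a sentence.
.abbrev_stop <- c("et al.", "al.", "Fig.", "Figs.", "vs.", "e.g.", "i.e.",
                  "cf.", "etc.", "ca.", "Dr.", "No.", "St.")

.ends_with_abbrev <- function(prefix) {
  for (ab in .abbrev_stop) {
    nab <- nchar(ab)
    n <- nchar(prefix)
    if (n < nab) next
    if (substr(prefix, n - nab + 1L, n) != ab) next
    # require a token boundary before the abbreviation
    if (n == nab) return(TRUE)
    before <- substr(prefix, n - nab, n - nab)
    if (!grepl("[A-Za-z0-9]", before)) return(TRUE)
  }
  FALSE
}

#' Split text into sentences with character offsets
#'
#' Deterministic rule-based splitter: a sentence ends at a run of `.`, `?` or
#' `!` that is followed by whitespace and an upper-case letter, unless the
#' token ending there is on a fixed abbreviation stop-list ("et al.", "Fig.",
#' "vs.", "e.g.", ...). Spans are 0-based half-open character offsets into
#' `text`; leading/trailing whitespace is excluded from each span, so spans
#' are non-overlapping and in order, and `substr(text, start+1, end)`
#' reconstructs each sentence exactly.
#'
#' @param text a single character string (an abstract).
#' @return data.frame with columns `start`, `end`, `text`; zero rows for
#'   empty input.
#' @examples
#' splitSentences("A binds B. C inhibits D.")
#' @export
splitSentences <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  empty <- data.frame(start = integer(), end = integer(),
                      text = character(), stringsAsFactors = FALSE)
  if (is.na(text) || !nzchar(trimws(text))) return(empty)

  m <- gregexpr("[.?!]+(?=\\s+[A-Z])", text, perl = TRUE)[[1]]
  ends1 <- integer()                       # 1-based index of last punct char
  if (m[1] != -1) {
    for (i in seq_along(m)) {
      e <- m[i] + attr(m, "match.length")[i] - 1L
      if (!.ends_with_abbrev(substr(text, 1L, e))) ends1 <- c(ends1, e)
    }
  }

  bounds <- c(ends1, nchar(text))
  out <- empty
  cur <- 1L
  for (b in bounds) {
    seg <- substr(text, cur, b)
    # trim whitespace but keep offsets consistent
    lead <- attr(regexpr("^\\s*", seg), "match.length")
    trail <- attr(regexpr("\\s*$", seg), "match.length")
    s1 <- cur + lead                       # 1-based start
    e1 <- b - trail                        # 1-based inclusive end
    if (s1 <= e1) {
      out <- rbind(out, data.frame(
        start = s1 - 1L, end = e1,
        text = substr(text, s1, e1), stringsAsFactors = FALSE))
    }
    cur <- b + 1L
  }
  rownames(out) <- NULL
  out
}

#' Construct a Document
#'
#' @param docId,title,abstract character scalars; `abstract` is segmented
#'   with [splitSentences()].
#' @return a [Document-class] object.
#' @export
Document <- function(docId, title = "", abstract = "") {
  new("Document", docId = as.character(docId), title = as.character(title),
      abstract = as.character(abstract),
      sentences = splitSentences(as.character(abstract)))
}

#' Read a corpus of abstracts
#'
#' Two dialects: `"tsv"` with header columns `doc_id`, `title`, `abstract`,
#' and a minimal MEDLINE text dialect restricted to the `PMID- `, `TI  - `
#' and `AB  - ` field tags (6-character prefix; continuation lines indented
#' with spaces are joined with a single space).
#'
#' @param path input file.
#' @param format `"tsv"` or `"medline"`.
#' @return list of [Document-class] objects, sentences populated.
#' @export
readCorpus <- function(path, format = c("tsv", "medline")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("corpus file not found: ", path)
  recs <- if (format == "tsv") .read_corpus_tsv(path) else .read_corpus_medline(path)
  if (anyDuplicated(recs$doc_id))
    stop("duplicate doc_id in corpus: ",
         paste(unique(recs$doc_id[duplicated(recs$doc_id)]), collapse = ", "))
  lapply(seq_len(nrow(recs)), function(i)
    Document(recs$doc_id[i], recs$title[i], recs$abstract[i]))
}

.read_corpus_tsv <- function(path) {
  df <- utils::read.delim(path, sep = "\t", quote = "", header = TRUE,
                          colClasses = "character", fill = FALSE,
                          check.names = FALSE, fileEncoding = "UTF-8")
  need <- c("doc_id", "title", "abstract")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("corpus TSV ", path, " is missing column(s): ",
         paste(miss, collapse = ", "))
  df[need]
}

.read_corpus_medline <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  recs <- list()
  cur <- NULL
  field <- NULL
  flush <- function(cur) {
    if (is.null(cur)) return(NULL)
    if (is.null(cur$PMID))
      stop("MEDLINE record without PMID in ", path)
    data.frame(doc_id = cur$PMID,
               title = if (is.null(cur$TI)) "" else cur$TI,
               abstract = if (is.null(cur$AB)) "" else cur$AB,
               stringsAsFactors = FALSE)
  }
  for (ln in lines) {
    if (!nzchar(trimws(ln))) { r <- flush(cur); if (!is.null(r)) recs <- c(recs, list(r)); cur <- NULL; field <- NULL; next }
    tag <- substr(ln, 1, 4)
    if (grepl("^[A-Z]{2,4}\\s*$", tag) && substr(ln, 5, 6) == "- ") {
      tag <- trimws(tag)
      val <- substr(ln, 7, nchar(ln))
      if (tag == "PMID" && !is.null(cur$PMID)) {  # new record without blank line
        r <- flush(cur); if (!is.null(r)) recs <- c(recs, list(r)); cur <- NULL
      }
      if (is.null(cur)) cur <- list()
      field <- tag
      cur[[tag]] <- if (is.null(cur[[tag]])) val else paste(cur[[tag]], val)
    } else if (grepl("^\\s{6}", ln) && !is.null(field)) {
      cur[[field]] <- paste(cur[[field]], trimws(ln))
    } else {
      stop("unparseable MEDLINE line in ", path, ": ", ln)
    }
  }
  r <- flush(cur); if (!is.null(r)) recs <- c(recs, list(r))
  if (!length(recs)) stop("no records in MEDLINE file ", path)
  do.call(rbind, recs)
}

#' Write a corpus as TSV
#'
#' Inverse of `readCorpus(format = "tsv")`: columns `doc_id`, `title`,
#' `abstract`, tab-separated, UTF-8, header row.
#'
#' @param docs list of [Document-class] objects.
#' @param path output file.
#' @export
writeCorpus <- function(docs, path) {
  df <- data.frame(
    doc_id = vapply(docs, function(d) d@docId, character(1)),
    title = vapply(docs, function(d) d@title, character(1)),
    abstract = vapply(docs, function(d) d@abstract, character(1)),
    stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Construct a Lexicon
#'
#' @param canonical character vector of unique canonical symbols.
#' @param synonyms list of character vectors (one per canonical), or `NULL`.
#' @param color entity class per entry, e.g. `"gene"` or `"disease"`.
#' @param species species tag per entry (default `"Homo sapiens"`).
#' @return a [Lexicon-class].
#' @export
Lexicon <- function(canonical, synonyms = NULL, color, species = "Homo sapiens") {
  n <- length(canonical)
  if (is.null(synonyms)) synonyms <- rep(list(character()), n)
  e <- data.frame(canonical = as.character(canonical),
                  color = rep_len(as.character(color), n),
                  species = rep_len(as.character(species), n),
                  stringsAsFactors = FALSE)
  e$synonyms <- synonyms
  new("Lexicon", entries = e[, c("canonical", "synonyms", "color", "species")])
}

#' Read an entity lexicon
#'
#' TSV with header columns `canonical`, `synonyms` (pipe-separated, may be
#' empty), `color`, `species`. When `species` is given, entries of other
#' species are dropped (target-species filtering, e.g. `"Homo sapiens"`).
#'
#' @param path lexicon TSV.
#' @param species target species, or `NULL` to keep all entries.
#' @return a [Lexicon-class].
#' @export
readLexicon <- function(path, species = NULL) {
  if (!file.exists(path)) stop("lexicon file not found: ", path)
  df <- utils::read.delim(path, sep = "\t", quote = "", header = TRUE,
                          colClasses = "character", check.names = FALSE,
                          fileEncoding = "UTF-8")
  need <- c("canonical", "synonyms", "color", "species")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("lexicon TSV is missing column(s): ", paste(miss, collapse = ", "))
  if (!nrow(df)) stop("empty lexicon: ", path)
  if (anyDuplicated(df$canonical))
    stop("duplicate canonical symbol(s) in lexicon: ",
         paste(unique(df$canonical[duplicated(df$canonical)]), collapse = ", "))
  if (!is.null(species)) {
    df <- df[df$species == species, , drop = FALSE]
    if (!nrow(df)) stop("no lexicon entries left after filtering to species ", species)
  }
  syn <- lapply(strsplit(df$synonyms, "|", fixed = TRUE),
                function(s) s[nzchar(s)])
  Lexicon(df$canonical, syn, df$color, df$species)
}

#' Write a Lexicon as TSV
#' @param lexicon a [Lexicon-class].
#' @param path output file.
#' @export
writeLexicon <- function(lexicon, path) {
  e <- entries(lexicon)
  df <- data.frame(canonical = e$canonical,
                   synonyms = vapply(e$synonyms, paste, character(1), collapse = "|"),
                   color = e$color, species = e$species,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Interaction-term lists
#'
#' `readInteractionTerms` reads one term per line (`#` comments and blank
#' lines skipped), lower-cases and de-duplicates. `defaultInteractionTerms`
#' returns the built-in list of gene interaction terms (e.g. "activates",
#' "induces", "inhibits"); it is a package default and fully overrideable.
#'
#' @param path terms file.
#' @return lower-case character vector without duplicates.
#' @export
readInteractionTerms <- function(path) {
  if (!file.exists(path)) stop("interaction-term file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- sub("#.*$", "", lines)
  terms <- unique(tolower(trimws(lines)))
  terms <- terms[nzchar(terms)]
  if (!length(terms)) stop("interaction-term file contains no terms: ", path)
  terms
}

#' @rdname readInteractionTerms
#' @export
defaultInteractionTerms <- function() {
  c("activates", "activation", "inhibits", "inhibition", "induces",
    "binds", "regulates", "suppresses", "phosphorylates", "interacts")
}
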