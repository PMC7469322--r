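# Shared fixtures, built in code.

# CoocGraph from a bare edge table (a, b, weight); all nodes one color
# unless a named `colors` vector says otherwise.
edge_graph <- function(a, b, weight, colors = NULL) {
  nodes <- sort(unique(c(a, b)))
  if (is.null(colors)) colors <- setNames(rep("gene", length(nodes)), nodes)
  etype <- match(weight, c(1, 0.75, 0.5, 0.25))
  records <- data.frame(
    a = pmin(a, b), b = pmax(a, b), count_total = 1L,
    count_type1 = as.integer(etype == 1L),
    count_type2 = as.integer(etype == 2L),
    count_type3 = as.integer(etype == 3L),
    count_type4 = as.integer(etype == 4L),
    confidence = weight, stringsAsFactors = FALSE)
  buildGraph(records, Lexicon(nodes, NULL, unname(colors[nodes])))
}

# star: center "c" with `k` leaves "l1".."lk", all edges `w`
star_graph <- function(k = 3, w = 0.5) {
  edge_graph(rep("c0", k), paste0("l", seq_len(k)), rep(w, k))
}

# small two-gene lexicon used by the worked examples
toy_lexicon <- function() {
  Lexicon(c("GENEA", "GENEB"), NULL, c("gene", "gene"))
}

toy_doc <- function(abstract, id = "d1") Document(id, "t", abstract)
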