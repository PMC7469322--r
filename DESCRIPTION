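Package: litInfluence
Title: Literature Co-Occurrence Networks and Influence Maximization for
    Gene-Disease Association Mining
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Builds weighted, colored gene-disease association networks from
    dictionary-tagged abstract corpora. Co-occurring entity pairs are
    classified into a four-level evidence hierarchy (interaction term between
    the names, term elsewhere in the sentence, shared sentence, shared
    abstract) and mapped onto fixed confidence weights interpreted as
    influence probabilities. On the resulting graph, pairwise influence is
    the strongest-influence-path (SIP) probability, the maximum over paths of
    the product of edge weights, and influential gene suites are selected by
    a greedy influence-maximization heuristic with a noisy-OR combination
    rule. Includes a soft-threshold expression adjacency, colored
    (class-restricted) influence queries, exhaustive small-graph oracles, a
    synthetic corpus/graph generator with planted ground truth, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    igraph,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'corpus-io.R'
    'tagging.R'
    'cooccurrence.R'
    'expression.R'
    'influence.R'
    'oracles.R'
    'synthetic.R'
    'cli.R'
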