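---
title: "Methods: co-occurrence evidence typing and IM-SIP influence maximization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: co-occurrence evidence typing and IM-SIP influence maximization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(litInfluence)
```

This vignette is the package's account of its model and of the design
choices made where the method left room. It states no empirical result
that the test suite and `scripts/acceptance.R` do not themselves compute.

## The model

### From text to typed evidence

Gene and disease mentions are found by exact dictionary matching: every
canonical symbol and synonym in the `Lexicon` is matched case-insensitively
with word boundaries defined as non-alphanumeric neighbours, so `TP53` is
found in `(TP53)` but not inside `TP533`. Overlapping candidates are
resolved longest-match-first (so *liver cancer* beats its substring
*cancer*), then leftmost; each match is normalized to its canonical symbol.
Dictionary matching replaces learned sequence taggers deliberately: it is
fully reproducible without training corpora or model weights, and the
downstream contribution — evidence typing and influence maximization — is
agnostic to how mentions were found. The price is recall on surface forms
absent from the lexicon: no abbreviation/full-form expansion is attempted,
and lexicons in which one surface form maps to several canonicals are
rejected rather than disambiguated.

For each document, each co-occurring pair of canonicals receives **one**
evidence row, the strongest applicable type in a four-level hierarchy:

| type | condition | score |
|------|-----------|-------|
| 1 | interaction term strictly between the two names, same sentence | 1.00 |
| 2 | interaction term anywhere in the shared sentence | 0.75 |
| 3 | shared sentence, no term | 0.50 |
| 4 | shared abstract only | 0.25 |

"Strictly between" means the term's span lies entirely after the end of the
earlier mention and before the start of the later one; if either entity is
mentioned several times in a sentence, every mention pairing is tried.
Negations are not handled (a deliberate simplification: *A does not bind B*
still counts as type 1), and co-occurrence is never counted across
documents. The interaction-term list is a plain lower-case word list; the
shipped default (`defaultInteractionTerms()`) contains ten common verbs and
nominalizations and is fully overrideable, since no canonical list exists.

### Aggregation and the graph

Evidence is aggregated per unordered pair: a document count (the pair's
*relevance rate*), counts by type, and a confidence equal to the **maximum**
score observed. The maximum — rather than a mean or sum — keeps every edge
on the four-level grid, which is what lets edge weights double as the fixed
influence probabilities downstream. `filterEdges()` removes pairs whose
document count is ≤ `minCount` (default 5, i.e. strictly more than five
supporting documents survive). An optional confidence cutoff exists but
defaults to off: applied at 0.90 it would keep only type-1-backed edges,
which would contradict running influence maximization over the four-level
weights; both filters are therefore explicit, visible parameters. Whether
the relevance rate should count documents or sentence-level mentions is
ambiguous; documents are counted, matching one-evidence-per-document
aggregation.

The result is an undirected colored graph: nodes are canonical symbols with
their entity class, edge weights *w(a,b) ∈ (0,1]* are the confidences. A
weight of exactly 1 is allowed (type-1 edges have it by construction), so
the open interval often quoted for influence probabilities is treated as
half-open at the top.

### SIP and influence

The influence of a path is the product of its edge probabilities; the
pairwise influence σ(u,v) is the maximum over paths (the strongest
influence path). Since all weights are ≤ 1, maximizing a product is
minimizing the sum of −log weights, all ≥ 0, so σ is computed exactly with
Dijkstra's algorithm (`igraph::distances` on −log weights) rather than path
enumeration; σ(u,u) = 1 and unreachable pairs have σ = 0.

Two scalars had to be pinned down that the method's prose leaves open:

* **Node influence** is the sum of σ(u,v) over eligible targets — the
  simplest scalar consistent with sorting nodes by "influence on the entire
  graph", interpretable as the expected number of nodes influenced.
* **Combined influence** of a seed set S on a target v is noisy-OR,
  `1 − prod(1 − σ(s,v))`, treating the strongest paths from different seeds
  as independent channels; `max` is available as an alternative aggregator.
  Noisy-OR makes the objective monotone and submodular, which is exactly
  the condition under which the greedy heuristic carries the classical
  (1 − 1/e) approximation guarantee — the test suite asserts that bound
  empirically against an exhaustive oracle on small graphs.

The greedy selection itself follows the stepwise heuristic: pick the
single most influential node first, then repeatedly add the candidate
whose inclusion maximizes the combined influence of the enlarged set on
the remaining eligible targets (a marginal-gain reading of the iteration,
the only one under which the loop acquires new nodes). All argmax ties
break lexicographically by node name, making results fully deterministic.
Colored queries (`queryInfluencers()`) are the same greedy loop with the
target set held fixed, enabling "genes most related to a disease set" and
its reverse.

**Suite relevance** (`suiteRelevance()`) is an explicit reconstruction: the
sum over diseases of the combined SIP from the gene suite. The exact
formula behind published suite-relevance figures is not documented anywhere
we could pin down, so the aggregator is configurable and no significance
cutoff is defaulted; treat its absolute values as comparable within one
graph only.

A note on the influence trace: it is nondecreasing while seeds are few
relative to eligible targets (the regime of every realistic run), but it is
*not* guaranteed monotone in the degenerate limit — when a strongly
influenced target is itself converted into a seed, its contribution leaves
the objective (seeding every node yields influence 0). The trace is
therefore reported, and asserted nondecreasing in tests only on
non-degenerate instances.

### Expression adjacency

`softThresholdAdjacency()` implements the soft-threshold connection
strength a<sub>ij</sub> = |s<sub>ij</sub>|<sup>β</sup> with s the pairwise
Pearson correlation of expression profiles. The absolute value follows the
unsigned convention — fractional powers of negative correlations are
undefined — and β defaults to 1 since no calibrated value is prescribed;
zero-variance genes are excluded with a warning. It is a standalone
operation: nothing in the pipeline fuses it with the literature graph, as
no fusion rule is defined.

## Tunable parameters

| parameter | where | default | meaning |
|-----------|-------|---------|---------|
| `minCount` | `filterEdges` | 5 | drop pairs with ≤ 5 supporting documents |
| `minConfidence` | `filterEdges` | off | optional confidence floor (0.90 keeps only type-1 edges) |
| `terms` | `extractEvidence` | 10-word list | interaction vocabulary, fully overrideable |
| `species` | `readLexicon` | off | target-species filter, e.g. `"Homo sapiens"` |
| `aggregator` | influence functions | `"noisy_or"` | seed combination rule (`"max"` alternative) |
| `numSeeds` / `k` | selection/query | — | seed-set size; 2–5 is the exercised range at full scale |
| `sourceColor`, `targetColor` | influence functions | `"all"` | colored-graph restrictions |
| `beta` | `softThresholdAdjacency` | 1 | soft-threshold exponent, > 0 |
| `cap` | oracles | 10 | node-count ceiling for exhaustive search |

## Numerical choices

* SIP via −log/Dijkstra is exact for this objective; the oracle-equivalence
  test demands agreement with exhaustive simple-path enumeration to 1e−12.
* Ties at every argmax (seed selection, brute-force subset search) break
  lexicographically; repeated runs are bit-identical.
* `sip = 0` encodes unreachability, consistent with absent edges meaning
  no influence.
* Sentence segmentation is rule-based (`[.?!]` + whitespace + capital, with
  an abbreviation stop-list); no splitter is prescribed by the method, so
  determinism was preferred over linguistic coverage. Offsets are 0-based,
  half-open, in characters.
* Degenerate inputs: empty abstracts yield zero sentences; empty evidence
  tables aggregate to empty records; an edgeless graph gives σ = 0
  everywhere off the diagonal; `numSeeds` above the candidate count is a
  validation error, not a truncation.

## The synthetic generator

`generateCorpus()` emits templated — not free-text — documents so that each
planted (pair, type) realizes exactly its evidence type under the
classification rules, each document supports exactly one planted pair, and
distractor sentences contain neither symbols nor interaction terms. The
returned ground-truth table is thus what a correct extractor must produce,
by construction; the planted-recovery tests demand exact equality, and on
such noise-free text pairwise precision and recall are both 100% by design.
What passing these tests shows is that the extraction machinery implements
its stated rules exactly; what they deliberately do not show is robustness
to real prose — paraphrase, anaphora, novel surface forms, tagging errors —
which templated text cannot emulate (and simulating NER noise is out of
scope). `generateGraph()` draws simple graphs uniformly at random with
weights on the four-level grid and colors by fraction; seeds are mandatory
everywhere, never defaulted.

Problem sizes used by the shipped tests: oracle comparisons run on 200
random graphs of 4–8 nodes; the greedy bound is checked for seed sizes 2–3
on 30 graphs of 6–8 nodes against exhaustive subset search; the full-scale
smoke run selects 2–5 seeds on one 487-node / 1626-edge random graph —
sizes chosen so the exhaustive oracles stay exact and the whole suite runs
in well under a minute per property.

## Known limitations

* Dictionary tagging bounds recall by lexicon coverage; no disambiguation
  of shared symbols across species or classes.
* One evidence row per (document, pair) discards within-document mention
  multiplicity.
* The suite-relevance scalar and the combined-influence rule are
  reconstructions (documented above), not canonical formulas.
* Influence is undirected; directed influence, independent-cascade and
  linear-threshold simulation are out of scope.
* The expression adjacency is computed but never fused with the literature
  graph.
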