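---
title: "Ontology-based document similarity: models, measures and the parallel decomposition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ontology-based document similarity: models, measures and the parallel decomposition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(meshsim)
```

## The problem

Biomedical documents in MEDLINE are indexed with Medical Subject Headings
(MeSH): curated concepts placed at one or more positions in a hierarchical
vocabulary. Each position is encoded by a *tree number* such as
`G02.111.222` — a dot-separated path from a category root, so the component
count is the node's depth and every prefix names an ancestor. Treating a
document as the *set* of its headings, the semantic similarity of two
documents can be computed entirely from the ontology structure, without any
text. `meshsim` implements that computation: node- and heading-level
similarity measures, their aggregation to document level, a parallelisable
decomposition of the all-pairs similarity matrix, and clustering with NMI
evaluation on top.

## Data model

Three layers, each a set over the layer below:

* **Node** `v`: one tree-number position. Depth `H(v)` = component count.
  All category trees are joined at a synthetic **virtual root** of depth 0,
  so the least common ancestor (LCA) and path length are total functions:
  nodes in different category trees meet at the root, path lengths stay
  finite, and cross-category similarities are 0. Nodes implied by a prefix
  but absent from the input (e.g. `A.1` when only `A.1.1` was listed) are
  materialised as unnamed nodes — tree numbers guarantee they exist in the
  real vocabulary — and they count toward the ontology size.
* **Heading** `m`: a named concept mapped to one or more nodes.
* **Document** `d`: a set of headings (duplicates are collapsed before any
  denominator is taken).

## Information content

IC is computed from structure alone (no corpus frequencies):

$$IC(v) = H(v)\left(1 - \frac{\log(|C(v)|+1)}{\log T_{total}}\right)$$

with `C(v)` the node's **direct** children and `T_total` the total node
count. Deeper nodes with fewer children are more specific; leaves get
`IC = H(v)` exactly since `log(0+1) = 0`. The ratio of logarithms makes the
value log-base invariant; natural logs are used internally. An alternative
`ic_children = "descendants"` mode counts the whole subtree instead of
direct children; the default follows the direct-children definition. A
single-node ontology has `log T_total = 0` and IC is refused as undefined.

## The six measures

Node-level (lifted to headings by aggregation):

* **WP** (Wu–Palmer): `2·H(lca) / (H(v)+H(v'))`, in [0,1].
* **Res** (Resnik): `IC(lca)`, unbounded above (≤ max IC of the ontology).
* **Lin**: `2·IC(lca) / (IC(v)+IC(v'))`, in [0,1]; defined as 0 when both
  ICs are 0 (the ratio is otherwise 0/0).
* **Sch** (Schlicker): Lin damped by `(1 − e^{−IC(lca)})`, which penalises
  pairs whose shared ancestor is generic; strictly below 1 even on the
  diagonal.

Heading-level (computed from path statistics over the two node sets, with
`L_min`/`L_max` the shortest/longest pairwise path lengths):

* **SP**: `(L_max − L_min)/L_max`, implemented exactly in that printed
  ratio form. When `L_max = 0` (identical single-node headings) the ratio
  is 0/0 and we define the similarity as 1 — identical headings must be
  maximally similar. Note the formula's asymmetric flavour: two
  single-node headings always score 0 because `L_min = L_max`; the measure
  only discriminates among multi-position headings.
* **LC** (Leacock–Chodorow): `1 − log(1+L_min)/log(1+2D)` with `D` the
  maximum depth over all loaded nodes (a global maximum, not per
  category), so `L_min = 0` gives 1 and the worst case `L_min = 2D` gives 0.

Why the split between node-level and heading-level measures? The path
statistics `L_min`/`L_max` are already set-level summaries, so SP and LC
consume heading pairs directly; the other four compare single nodes and
need the aggregation below. Path statistics enumerate **all** node pairs,
including pairs routed through the virtual root.

## Average maximum match (AMM)

Two applications of the same idea — match each element with its best
counterpart in the opposite set, then average over both directions:

$$Sim(m,m') = \frac{\sum_{v\in m}\max_{v'\in m'}Sim(v,v') +
  \sum_{v'\in m'}\max_{v\in m}Sim(v',v)}{|m|+|m'|}$$

$$Sim(d,d') = \frac{\sum_{m\in d}\underbrace{\max_{m'\in d'}Sim(m,m')}_{Sim(m,d')} +
  \sum_{m'\in d'}Sim(m',d)}{|d|+|d'|}$$

Under measures with unit self-similarity, `Sim(d,d) = 1`. For Resnik the
raw self-value is IC-scaled; the matrix diagonal is nonetheless fixed to 1
for every measure so clustering sees a consistent self-affinity
(`raw_diagonal = TRUE` on the brute-force path exposes the raw values).
Whether a Resnik matrix should additionally be rescaled to [0,1] before
clustering is left to the user (`res_normalization` in the pipeline
config); the default clusters it raw.

## The map/shuffle/reduce decomposition

Computing `Sim(d,d')` pair by pair costs `O(m²n²)` best-match evaluations
(`n` documents, `m` headings per document). The engine restructures the
work around the heading-to-document contribution `Sim(m,d')`:

1. **Transform** (`transform_corpus`): invert `docID#h1,h2,...` lines into
   `<heading, list(docID)>` — documents sharing a feature sit under one key.
2. **Precompute** (`precompute_heading_table`): all `k(k+1)/2` heading-pair
   similarities, since they are reused constantly downstream.
3. **Map** (`docsim_map`): for each inverted-index entry `m`, evaluate
   `Sim(m,d')` once per document `d'` — `k·n` evaluations per full map
   stage — and emit the value to every canonical pair `(d,d')` with
   `m ∈ d`. The canonical key orders the two doc ids lexicographically so
   both directions of the AMM numerator aggregate under one reduce key.
   Self-pairs are never emitted; the diagonal is set to 1 directly.
4. **Combine** (optional, `combiner`): per-partition partial sums per key,
   shrinking shuffle volume without changing any per-key total.
5. **Shuffle + Reduce** (`docsim_reduce`): group by key, sum the
   `|d|+|d'|` contributions, divide by `|d|+|d'|` (heading counts are
   recovered from the corpus at reduce time rather than carried through
   the shuffle, keeping the intermediate data compact).

The distributed runtime is replaced by pure in-process stages over
*logical* workers (round-robin partitions of the map input); the
decomposition, key design and combiner semantics are what matter, and the
output contract is equality with the brute-force pairwise matrix to within
1e-9 for any worker count and either combiner setting.

**Floating-point determinism.** Without the combiner, shuffled
contributions are sorted into a canonical per-key order (heading, then
target document) before summation, so the matrix is bitwise identical for
every worker count. With the combiner, partial sums regroup additions and
runs may differ across worker counts in the last bits — always within the
1e-9 contract. `count_operations()` exposes the instrumented counters
(`map_ops = k·n`, `reduce_keys ≤ n(n−1)/2`) that reflect the stage
complexities `O(kmn)` and `O(n²)`.

## Clustering and evaluation

Three standard algorithms run over the similarity matrix:

* **spectral**: the matrix is a precomputed graph affinity; we embed with
  the top-`k` eigenvectors of the symmetric normalised Laplacian
  (row-normalised) and run k-means on the embedding.
* **agglomerative**: average linkage on `1 − sim` (after rescaling by the
  max when similarities exceed 1). Average linkage is a robust default for
  similarity-derived distances; the linkage is otherwise a free choice.
* **kmeans**: each document embedded as its row of the similarity matrix —
  the simplest faithful reading of clustering "performed over the document
  similarity".

`k` is supplied by the user (in benchmark settings it is the known topic
count). All stochastic steps accept an explicit seed (default 0) and
restore the caller's RNG state.

Evaluation uses normalized mutual information,

$$NMI = \frac{\sum_{h,l} n_{h,l}\log\frac{n\,n_{h,l}}{n_h n_l}}
 {\sqrt{\left(\sum_h n_h\log\frac{n_h}{n}\right)\left(\sum_l n_l\log\frac{n_l}{n}\right)}}$$

Both factors under the radical are negative, so the product is positive
and the index lies in [0,1]; zero cells contribute 0; the value is
log-base invariant and permutation invariant. With a single class on
either side the denominator vanishes and `NA` is returned with a warning.
The test suite cross-checks this form against the algebraically equivalent
entropy identity `(H(T)+H(P)−H(T,P))/√(H(T)H(P))` computed through an
independent code path.

## The synthetic generator

Real labelled corpora of this kind are licensed and cannot ship with the
package, so `fixture_spec()` / `make_ontology()` / `make_corpus()` generate
everything: a random forest of tree-numbered nodes, a heading vocabulary
spread evenly over the category trees (even allocation keeps every planted
topic's subtree populated), and a planted-topic corpus in which each
document draws each heading from its topic's category subtree with
probability `within_topic_prob`, otherwise uniformly elsewhere. Headings
are sampled without replacement within a document (documents are sets);
most headings map to one node, a minority to two or three, mirroring
multi-position headings in real vocabularies.

Defaults — 3 topics × 30 documents, 60 headings over 3 category trees of
depth ≤ 4, 3–8 headings per document, `within_topic_prob = 0.9` — describe
a small, well-separated labelled benchmark. At `within_topic_prob = 0.9`
spectral clustering on the WP matrix recovers the planted topics with NMI
≥ 0.9 in the large majority of seeds; at the chance rate (`1/n_topics`)
NMI collapses to near 0. What the generator does **not** emulate: real
MeSH depth (11+ levels) and fan-out, the heavy-tailed heading frequency
distribution of MEDLINE (check tags like *Humans* attach to almost every
document), and topics that overlap in the hierarchy. Passing tests
therefore demonstrate correctness of the machinery and recoverability of
clean planted structure, not clustering quality on real literature.

## Problem sizes and numerical choices

The test and acceptance workloads use corpora up to 60 documents and 40
headings over ontologies of up to ~300 nodes, with the planted-recovery
runs at 90 documents and the null-model runs at ~200; these sizes exercise
every code path while keeping the whole suite fast. Tolerances: engine vs
oracle 1e-9 (floating-point regrouping only); hand-derived fixture values
1e-4 absolute (the frozen constants are 4-decimal roundings); NMI vs
reference 1e-9. Ties in k-means are resolved by `stats::kmeans` under the
supplied seed with 20 restarts; eigenvector sign ambiguity in the spectral
embedding is harmless to k-means since it is an isometry of the embedding.

## Known limitations

* Heading-level SP cannot distinguish single-node heading pairs (always 0
  unless identical); this is a property of the printed ratio form, kept
  deliberately.
* The engine materialises all map emissions in memory; at `n` documents
  and average `m` headings per document that is `O(m·n²)` values. Fine for
  tens of thousands of pairs; a true out-of-core shuffle is out of scope.
* The virtual root makes cross-category IC-based similarities exactly 0;
  if two category trees are semantically related, that relation is
  invisible to structure-only IC.

## A worked toy example

```{r toy}
ont <- build_ontology(list(
  hA = "A", h1 = "A.1", h2 = "A.2", h11 = "A.1.1", h12 = "A.1.2",
  m1 = "A.1.1", m2 = c("A.1.2", "A.2")
))
c(T_total = ont$T_total, D = ont$D)
information_content(ont, "A.1")     # 2 * (1 - log 3 / log 5)
sim_wp(ont, "A.1.1", "A.1.2")       # 2*2 / (3+3)
heading_sim(ont, "WP", "m1", "m2")  # (2/3 + 2/3 + 2/5) / 3
corpus <- new_corpus(list(d1 = "m1", d2 = "m2"))
run_docsim(ont, "WP", corpus)
```
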