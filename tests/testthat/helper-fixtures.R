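# TOY ontology: one category tree A with two branches, two multi-node
# headings m1 = {A.1.1}, m2 = {A.1.2, A.2}, plus one heading per node.
toy_ontology <- function() {
  build_ontology(list(
    hA = "A", h1 = "A.1", h2 = "A.2", h11 = "A.1.1", h12 = "A.1.2",
    m1 = "A.1.1", m2 = c("A.1.2", "A.2")
  ))
}

toy_corpus <- function() {
  new_corpus(list(d1 = "m1", d2 = "m2"))
}

# Two-category ontology for cross-tree cases.
twotree_ontology <- function() {
  build_ontology(list(
    a1 = "A.1", a11 = "A.1.1", b1 = "B.1", b2 = "B.2", b21 = "B.2.1"
  ))
}

# Random fixture helpers used by property tests: small planted corpora.
random_fixture <- function(seed, n_topics = 2L, docs_per_topic = 10L,
                           n_headings = 20L, within = 0.8) {
  # a sampled ontology can leave a topic subtree too sparse; step the seed
  # deterministically until the planted construction is feasible
  for (s in seed + 1000L * (0:19)) {
    spec <- fixture_spec(seed = s, n_categories = 3L, branching = c(2L, 3L),
                         max_depth = 4L, n_headings = n_headings,
                         n_topics = n_topics, docs_per_topic = docs_per_topic,
                         headings_per_doc = c(2L, 5L), within_topic_prob = within)
    synth <- make_ontology(spec)
    corp <- tryCatch(make_corpus(spec, synth), error = function(e) NULL)
    if (!is.null(corp)) {
      return(list(spec = spec, ont = synth$ontology, synth = synth,
                  corpus = corp$corpus, labels = corp$labels,
                  lines = corp$lines))
    }
  }
  stop("no feasible fixture near seed ", seed)
}

expect_symmetric <- function(m, tol = 1e-12) {
  expect_lt(max(abs(m - t(m))), tol)
}
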