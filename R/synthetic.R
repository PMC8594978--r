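#' Specification for a synthetic ontology/corpus fixture
#'
#' Bundles the knobs of the planted-topic generator. The defaults emulate a
#' small labelled benchmark: a few disjoint category trees, a vocabulary of
#' named headings spread over them, and documents whose headings concentrate
#' (with probability `within_topic_prob`) in the subtree anchoring their
#' topic — giving known ground-truth clusters with a tunable separation.
#'
#' @param seed Integer seed; fixed seed gives byte-identical fixtures.
#' @param n_categories Number of disjoint category trees.
#' @param branching Integer range `c(min, max)`: children drawn per
#'   internal node.
#' @param max_depth Maximum node depth (`>= 2`).
#' @param n_headings Number of named headings.
#' @param n_topics Number of planted topics (each anchored to its own
#'   category tree, so `n_topics <= n_categories`).
#' @param docs_per_topic Documents generated per topic.
#' @param headings_per_doc Integer range `c(min, max)` of headings per
#'   document (sampled without replacement: documents are heading sets).
#' @param within_topic_prob Probability that a document's heading is drawn
#'   from its topic's subtree rather than uniformly elsewhere.
#' @return List of class `fixture_spec`.
#' @export
fixture_spec <- function(seed = 0L, n_categories = 3L, branching = c(2L, 4L),
                         max_depth = 4L, n_headings = 60L, n_topics = 3L,
                         docs_per_topic = 30L, headings_per_doc = c(3L, 8L),
                         within_topic_prob = 0.9) {
  stopifnot(max_depth >= 2L, n_headings >= 1L, n_topics >= 1L,
            docs_per_topic >= 1L, headings_per_doc[1L] >= 1L,
            within_topic_prob >= 0, within_topic_prob <= 1,
            branching[1L] >= 1L, branching[2L] >= branching[1L],
            headings_per_doc[2L] >= headings_per_doc[1L])
  structure(
    list(seed = as.integer(seed), n_categories = as.integer(n_categories),
         branching = as.integer(branching), max_depth = as.integer(max_depth),
         n_headings = as.integer(n_headings), n_topics = as.integer(n_topics),
         docs_per_topic = as.integer(docs_per_topic),
         headings_per_doc = as.integer(headings_per_doc),
         within_topic_prob = within_topic_prob),
    class = "fixture_spec"
  )
}

#' Generate a random ontology forest with named headings
#'
#' Grows `n_categories` random trees of tree-numbered nodes (ids like
#' `"C3.7.2"`), then names a random subset of nodes as headings; each
#' heading maps to a primary node and, occasionally, one or two additional
#' nodes elsewhere — mirroring how real headings can sit at several tree
#' positions.
#'
#' @param spec A [fixture_spec()].
#' @return List of class `synthetic_ontology`: `ontology` (a
#'   `mesh_ontology` with the headings registered), `records` (the named
#'   heading -> tree-number list), and `primary` (named character vector:
#'   each heading's primary node, used for topic anchoring).
#' @export
make_ontology <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  with_seed(spec$seed, {
    nodes <- character(0)
    for (cat in seq_len(spec$n_categories)) {
      root <- paste0("C", cat)
      frontier <- root
      nodes <- c(nodes, root)
      depth <- 1L
      while (depth < spec$max_depth && length(frontier) > 0L) {
        nxt <- character(0)
        for (p in frontier) {
          nc <- sample(spec$branching[1L]:spec$branching[2L], 1L)
          kids <- paste0(p, ".", seq_len(nc))
          nxt <- c(nxt, kids)
        }
        nodes <- c(nodes, nxt)
        frontier <- nxt
        depth <- depth + 1L
      }
    }
    if (spec$n_headings > length(nodes)) {
      stop(sprintf("infeasible fixture: %d headings requested over %d nodes",
                   spec$n_headings, length(nodes)), call. = FALSE)
    }
    # spread the vocabulary evenly over the category trees so each planted
    # topic's subtree carries a comparable share of headings
    node_cat <- sub("\\..*$", "", nodes)
    cats <- paste0("C", seq_len(spec$n_categories))
    quota <- rep(spec$n_headings %/% spec$n_categories, spec$n_categories)
    extra <- spec$n_headings %% spec$n_categories
    if (extra > 0L) quota[seq_len(extra)] <- quota[seq_len(extra)] + 1L
    primary <- character(0)
    deficit <- 0L
    for (ci in seq_along(cats)) {
      pool <- nodes[node_cat == cats[ci]]
      take <- min(quota[ci], length(pool))
      deficit <- deficit + quota[ci] - take
      primary <- c(primary, sample(pool, take))
    }
    if (deficit > 0L) {
      pool <- setdiff(nodes, primary)
      primary <- c(primary, sample(pool, deficit))
    }
    records <- vector("list", spec$n_headings)
    names(records) <- sprintf("H%03d", seq_len(spec$n_headings))
    for (i in seq_len(spec$n_headings)) {
      extra <- integer(0)
      n_extra <- sample(0:2, 1L, prob = c(0.7, 0.2, 0.1))
      if (n_extra > 0L) {
        pool <- setdiff(nodes, primary[i])
        extra <- sample(pool, min(n_extra, length(pool)))
      }
      records[[i]] <- c(primary[i], extra)
    }
    names(primary) <- names(records)
    ont <- build_ontology(records)
    structure(list(ontology = ont, records = records, primary = primary),
              class = "synthetic_ontology")
  })
}

#' Generate a planted-topic corpus over a synthetic ontology
#'
#' Each topic is anchored to one category tree; a document of topic `t`
#' draws each of its headings from the topic's subtree with probability
#' `within_topic_prob`, otherwise uniformly from the remaining headings.
#' Headings are sampled without replacement within a document.
#'
#' @param spec A [fixture_spec()].
#' @param synth A `synthetic_ontology` from [make_ontology()].
#' @return List of class `synthetic_corpus`: `corpus` (a `mesh_corpus`),
#'   `labels` (named integer vector of true topic labels), and `lines`
#'   (the corpus serialised as `docID#h1,h2,...` lines).
#' @export
make_corpus <- function(spec, synth) {
  stopifnot(inherits(spec, "fixture_spec"), inherits(synth, "synthetic_ontology"))
  if (spec$n_topics > spec$n_categories) {
    stop("n_topics must not exceed n_categories (topics anchor to disjoint trees)",
         call. = FALSE)
  }
  heads <- names(synth$primary)
  cat_of <- sub("\\..*$", "", synth$primary)
  topic_pool <- lapply(seq_len(spec$n_topics), function(t) {
    heads[cat_of == paste0("C", t)]
  })
  need <- spec$headings_per_doc[2L]
  short <- which(lengths(topic_pool) < need)
  if (length(short) > 0L) {
    stop(sprintf("topic %d subtree has only %d headings (< %d per document)",
                 short[1L], length(topic_pool[[short[1L]]]), need), call. = FALSE)
  }
  with_seed(spec$seed + 1L, {
    n_docs <- spec$n_topics * spec$docs_per_topic
    docs <- vector("list", n_docs)
    labels <- integer(n_docs)
    ids <- sprintf("D%04d", seq_len(n_docs))
    i <- 0L
    for (t in seq_len(spec$n_topics)) {
      pool_in <- topic_pool[[t]]
      pool_out <- setdiff(heads, pool_in)
      for (d in seq_len(spec$docs_per_topic)) {
        i <- i + 1L
        size <- sample(spec$headings_per_doc[1L]:spec$headings_per_doc[2L], 1L)
        n_in <- sum(stats::runif(size) < spec$within_topic_prob)
        n_in <- min(n_in, length(pool_in))
        n_out <- min(size - n_in, length(pool_out))
        docs[[i]] <- c(sample(pool_in, n_in), sample(pool_out, n_out))
        labels[i] <- t
      }
    }
    names(docs) <- ids
    names(labels) <- ids
    corpus <- new_corpus(docs)
    lines <- vapply(seq_along(ids), function(j) {
      paste0(ids[j], "#", paste(corpus$headings[[j]], collapse = ","))
    }, character(1))
    structure(list(corpus = corpus, labels = labels, lines = lines),
              class = "synthetic_corpus")
  })
}
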