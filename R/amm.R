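#' Construct a document corpus
#'
#' A document is a set of ontology headings (its semantic features); a
#' corpus is an ordered collection of documents with unique ids. Duplicate
#' headings within a document are collapsed: documents are heading sets, and
#' the average-maximum-match denominator counts distinct headings.
#'
#' @param docs Named list: names are document ids (e.g. PMIDs), each element
#'   a non-empty character vector of heading names.
#' @return An object of class `mesh_corpus` with `doc_ids` and `headings`
#'   (named list of deduplicated heading sets).
#' @export
new_corpus <- function(docs) {
  if (length(docs) == 0L) stop("empty corpus", call. = FALSE)
  ids <- names(docs)
  if (is.null(ids) || any(!nzchar(ids))) {
    stop("documents must be named by doc id", call. = FALSE)
  }
  if (anyDuplicated(ids)) {
    stop(sprintf("duplicate doc id '%s'", ids[duplicated(ids)][1L]), call. = FALSE)
  }
  headings <- lapply(docs, function(h) {
    h <- unique(as.character(h))
    if (length(h) == 0L) stop("document with no headings", call. = FALSE)
    h
  })
  structure(list(doc_ids = ids, headings = headings), class = "mesh_corpus")
}

#' @export
print.mesh_corpus <- function(x, ...) {
  cat("<mesh_corpus> ", length(x$doc_ids), " documents, ",
      length(unique(unlist(x$headings, use.names = FALSE))),
      " distinct headings\n", sep = "")
  invisible(x)
}

corpus_vocabulary <- function(corpus) {
  sort(unique(unlist(corpus$headings, use.names = FALSE)))
}

#' Heading-to-heading similarity (average maximum match)
#'
#' For heading-level measures (`SP`, `LC`) this is the direct path-based
#' formula. For node-level measures the two headings' node sets are combined
#' by average maximum match: each node is matched with its best counterpart
#' in the opposite set, and the matched scores are averaged over both
#' directions,
#' \deqn{Sim(m, m') = \frac{\sum_{v \in m} \max_{v' \in m'} Sim(v, v')
#'   + \sum_{v' \in m'} \max_{v \in m} Sim(v', v)}{|m| + |m'|}.}
#'
#' @param ont A `mesh_ontology`.
#' @param measure Measure name (see [MEASURES]).
#' @param m,m2 Heading names registered in the ontology.
#' @return Non-negative real; symmetric in `m`, `m2`.
#' @export
heading_sim <- function(ont, measure, m, m2) {
  measure <- match.arg(measure, MEASURES)
  if (measure_level(measure) == "heading") {
    return(switch(measure, SP = sim_sp(ont, m, m2), LC = sim_lc(ont, m, m2)))
  }
  va <- heading_nodes(ont, m)
  vb <- heading_nodes(ont, m2)
  s <- outer(va, vb, Vectorize(function(a, b) node_sim(ont, measure, a, b)))
  (sum(apply(s, 1, max)) + sum(apply(s, 2, max))) / (length(va) + length(vb))
}

table_lookup <- function(table, m, m2) {
  i <- match(m, table$headings)
  j <- match(m2, table$headings)
  if (is.na(i) || is.na(j)) {
    stop(sprintf("heading pair (%s, %s) missing from similarity table",
                 m, m2), call. = FALSE)
  }
  table$mat[i, j]
}

#' Heading-to-document similarity
#'
#' The similarity contribution of heading `m` to document `d` is the best
#' match of `m` against any heading of `d`:
#' `Sim(m, d) = max over m' in d of Sim(m, m')`, looked up in a precomputed
#' heading similarity table (see [precompute_heading_table()]).
#'
#' @param table A `heading_sim_table`.
#' @param m Heading name.
#' @param d Character vector: the headings of the document.
#' @export
heading_to_doc_sim <- function(table, m, d) {
  i <- match(m, table$headings)
  j <- match(unique(d), table$headings)
  if (is.na(i) || anyNA(j)) {
    stop("similarity table incomplete for requested headings", call. = FALSE)
  }
  max(table$mat[i, j])
}

#' Document-to-document similarity (average maximum match)
#'
#' \deqn{Sim(d, d') = \frac{\sum_{m \in d} Sim(m, d')
#'   + \sum_{m' \in d'} Sim(m', d)}{|d| + |d'|}}
#' where each `Sim(m, d)` is a best-match lookup ([heading_to_doc_sim()]).
#' Under measures with self-similarity 1 (`WP`, `Lin`, `SP`, `LC`) the
#' similarity of a document with itself is 1.
#'
#' @param table A `heading_sim_table`.
#' @param d,d2 Character vectors of document headings (duplicates collapsed).
#' @export
doc_sim <- function(table, d, d2) {
  d <- unique(d); d2 <- unique(d2)
  if (length(d) == 0L || length(d2) == 0L) stop("empty document", call. = FALSE)
  fwd <- vapply(d, function(m) heading_to_doc_sim(table, m, d2), numeric(1))
  bwd <- vapply(d2, function(m) heading_to_doc_sim(table, m, d), numeric(1))
  (sum(fwd) + sum(bwd)) / (length(d) + length(d2))
}

#' Brute-force pairwise document similarity matrix
#'
#' Computes the full symmetric document similarity matrix pair by pair —
#' the traditional quadratic baseline. It serves as the correctness oracle
#' for the map/shuffle/reduce engine ([run_docsim()]), which must reproduce
#' it elementwise.
#'
#' @param ont A `mesh_ontology`.
#' @param measure Measure name.
#' @param corpus A `mesh_corpus`.
#' @param table Optional precomputed `heading_sim_table`; computed if `NULL`.
#' @param raw_diagonal If `FALSE` (default) the diagonal is fixed to 1 for
#'   every measure, giving clustering a consistent self-affinity; if `TRUE`
#'   the raw average-maximum-match self-similarity is kept (for `Res` that
#'   is IC-scaled, not 1).
#' @return `n x n` symmetric matrix with doc ids as dimnames.
#' @export
doc_sim_matrix_bruteforce <- function(ont, measure, corpus, table = NULL,
                                      raw_diagonal = FALSE) {
  measure <- match.arg(measure, MEASURES)
  if (is.null(table)) {
    table <- precompute_heading_table(ont, measure, corpus_vocabulary(corpus))
  }
  n <- length(corpus$doc_ids)
  out <- matrix(0, n, n, dimnames = list(corpus$doc_ids, corpus$doc_ids))
  for (i in seq_len(n)) {
    for (j in i:n) {
      if (i == j && !raw_diagonal) { out[i, i] <- 1; next }
      s <- doc_sim(table, corpus$headings[[i]], corpus$headings[[j]])
      out[i, j] <- out[j, i] <- s
    }
  }
  out
}
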