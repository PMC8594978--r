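#' Invert a corpus into a heading -> documents index
#'
#' The preprocessing transformation: corpus lines `docID#h1,h2,...` are
#' mapped to `<heading, docID>` pairs, shuffled (grouped) by heading, and
#' reduced to sorted document lists — an inverted index in which all
#' documents sharing a semantic feature sit under one key.
#'
#' @param x A `mesh_corpus`, or a character vector of corpus lines (parsed
#'   with [read_corpus_lines()]; pass `ont` to resolve headings whose names
#'   contain commas).
#' @param ont Optional `mesh_ontology` used to validate/resolve heading
#'   names when `x` is raw lines.
#' @return An object of class `inverted_index`: named list mapping each
#'   heading to the sorted character vector of doc ids containing it.
#' @export
transform_corpus <- function(x, ont = NULL) {
  corpus <- if (inherits(x, "mesh_corpus")) x else read_corpus_lines(x, ont)
  # map: emit <heading, doc> per heading per document
  heads <- unlist(corpus$headings, use.names = FALSE)
  docs <- rep(corpus$doc_ids, lengths(corpus$headings))
  # shuffle: group by heading; reduce: sorted doc list per heading
  idx <- split(docs, heads)
  idx <- lapply(idx, sort)
  idx <- idx[sort(names(idx))]
  structure(idx, class = "inverted_index")
}

#' @export
print.inverted_index <- function(x, ...) {
  cat("<inverted_index> ", length(x), " headings over ",
      length(unique(unlist(x, use.names = FALSE))), " documents\n", sep = "")
  invisible(x)
}

#' Precompute the heading-pair similarity table
#'
#' Heading similarity is looked up many times while aggregating document
#' similarity, so all `k(k+1)/2` unordered pairs over the corpus vocabulary
#' are computed once up front. The pair set is partitioned round-robin
#' across logical workers; the result is independent of the partitioning.
#'
#' @param ont A `mesh_ontology`.
#' @param measure Measure name (see [MEASURES]).
#' @param headings Character vector: the headings occurring in the corpus.
#' @param workers Number of logical map partitions (`>= 1`).
#' @return An object of class `heading_sim_table`: list with `headings`,
#'   symmetric `mat` (with heading dimnames) and `measure`.
#' @export
precompute_heading_table <- function(ont, measure, headings, workers = 1L) {
  measure <- match.arg(measure, MEASURES)
  stopifnot(workers >= 1L)
  headings <- unique(headings)
  k <- length(headings)
  node_sets <- lapply(headings, function(h) heading_nodes(ont, h))
  cache <- node_stats_cache(ont, unlist(node_sets, use.names = FALSE))
  nidx <- lapply(node_sets, function(v) match(v, cache$ids))

  level <- measure_level(measure)
  base <- if (level == "node") node_sim_matrix(cache, measure) else cache$path_len

  pair_value <- function(i, j) {
    sub <- base[nidx[[i]], nidx[[j]], drop = FALSE]
    if (level == "node") {
      # average maximum match over the two node sets
      (sum(apply(sub, 1, max)) + sum(apply(sub, 2, max))) /
        (nrow(sub) + ncol(sub))
    } else {
      lmin <- min(sub); lmax <- max(sub)
      if (measure == "SP") {
        if (lmax == 0) 1 else (lmax - lmin) / lmax
      } else { # LC
        1 - log(1 + lmin) / log(1 + 2 * ont$D)
      }
    }
  }

  pairs_i <- rep(seq_len(k), times = k - seq_len(k) + 1L)
  pairs_j <- unlist(lapply(seq_len(k), function(i) i:k), use.names = FALSE)
  part <- (seq_along(pairs_i) - 1L) %% workers + 1L

  mat <- matrix(0, k, k, dimnames = list(headings, headings))
  for (w in seq_len(workers)) {
    sel <- which(part == w)
    for (p in sel) {
      i <- pairs_i[p]; j <- pairs_j[p]
      v <- pair_value(i, j)
      mat[i, j] <- mat[j, i] <- v
    }
  }
  structure(list(headings = headings, mat = mat, measure = measure),
            class = "heading_sim_table")
}

#' @export
print.heading_sim_table <- function(x, ...) {
  cat("<heading_sim_table> ", length(x$headings), " headings, measure ",
      x$measure, "\n", sep = "")
  invisible(x)
}

# canonical pair key in doc-rank space: rank = position in sorted doc ids
pair_key <- function(rlo, rhi, n) (rlo - 1) * n + rhi
pair_key_lo <- function(key, n) (key - 1) %/% n + 1
pair_key_hi <- function(key, n) (key - 1) %% n + 1

#' Map stage of the document-similarity decomposition
#'
#' For one inverted-index entry (heading `m` with its document list), the
#' map task computes `Sim(m, d')` once per document `d'` in the corpus and
#' emits it to every canonical pair `(d, d')` with `d` containing `m`,
#' `d != d'`. This is what removes the redundancy of the pairwise baseline:
#' the inner best-match over `d'` is evaluated `k * n` times per full map
#' stage instead of once per document pair.
#'
#' @param table A `heading_sim_table`.
#' @param corpus A `mesh_corpus`.
#' @param m Heading name (must occur in the corpus).
#' @param docs_with_m Character vector of doc ids containing `m` (the
#'   inverted-index entry); defaults to scanning the corpus.
#' @param s Optional precomputed vector `Sim(m, d')` in corpus document
#'   order (used by [run_docsim()] to share the map-stage evaluations).
#' @return Data frame of emitted pairs with columns `doc_lo`, `doc_hi`
#'   (canonical: `doc_lo < doc_hi` lexicographically), `value`, `heading`,
#'   `target` (the document `d'` whose contribution the value is).
#' @export
docsim_map <- function(table, corpus, m, docs_with_m = NULL, s = NULL) {
  n <- length(corpus$doc_ids)
  if (is.null(docs_with_m)) {
    docs_with_m <- corpus$doc_ids[vapply(corpus$headings, function(h) m %in% h,
                                         logical(1))]
  }
  if (length(docs_with_m) == 0L) {
    stop(sprintf("heading '%s' absent from the inverted index", m), call. = FALSE)
  }
  src <- match(docs_with_m, corpus$doc_ids)
  if (anyNA(src)) stop("unknown doc id in inverted-index entry", call. = FALSE)
  if (is.null(s)) {
    s <- vapply(corpus$headings, function(d) heading_to_doc_sim(table, m, d),
                numeric(1))
  }
  rank <- match(corpus$doc_ids, sort(corpus$doc_ids))
  si <- rep(src, each = n)
  ti <- rep(seq_len(n), times = length(src))
  keep <- si != ti
  si <- si[keep]; ti <- ti[keep]
  rlo <- pmin(rank[si], rank[ti])
  rhi <- pmax(rank[si], rank[ti])
  sorted_ids <- sort(corpus$doc_ids)
  data.frame(
    doc_lo = sorted_ids[rlo],
    doc_hi = sorted_ids[rhi],
    value = as.numeric(s[ti]),
    heading = rep.int(m, length(ti)),
    target = corpus$doc_ids[ti],
    stringsAsFactors = FALSE
  )
}

#' Pre-shuffle combiner
#'
#' Aggregates emitted `(pair, value)` records within one map partition by
#' summing values per canonical pair, shrinking the data moved through the
#' shuffle without changing the reduced result (per-key sums are conserved).
#'
#' @param pairs Data frame with columns `doc_lo`, `doc_hi`, `value` (as
#'   produced by [docsim_map()]).
#' @return Data frame with one row per pair and the summed `value`.
#' @export
combiner <- function(pairs) {
  if (nrow(pairs) == 0L) {
    return(data.frame(doc_lo = character(0), doc_hi = character(0),
                      value = numeric(0), stringsAsFactors = FALSE))
  }
  key <- paste(pairs$doc_lo, pairs$doc_hi, sep = "\r")
  agg <- rowsum(pairs$value, key, reorder = TRUE)
  parts <- strsplit(rownames(agg), "\r", fixed = TRUE)
  data.frame(
    doc_lo = vapply(parts, `[`, character(1), 1L),
    doc_hi = vapply(parts, `[`, character(1), 2L),
    value = as.numeric(agg[, 1L]),
    stringsAsFactors = FALSE
  )
}

#' Reduce stage: one document pair
#'
#' All shuffled contributions for a canonical pair — one `Sim(m, d')` per
#' heading `m` of `d` toward `d'` and vice versa — are summed and divided
#' by the total heading count of the two documents, completing the
#' average-maximum-match formula.
#'
#' @param d,d2 The two doc ids of the pair.
#' @param values Numeric vector of contributions for this pair.
#' @param corpus A `mesh_corpus` (supplies the heading counts).
#' @return The document similarity, a real number.
#' @export
docsim_reduce <- function(d, d2, values, corpus) {
  i <- match(d, corpus$doc_ids)
  j <- match(d2, corpus$doc_ids)
  if (is.na(i) || is.na(j)) stop("unknown doc id in reduce key", call. = FALSE)
  sum(values) / (length(corpus$headings[[i]]) + length(corpus$headings[[j]]))
}

#' Parallel document-similarity matrix (map/shuffle/reduce)
#'
#' Runs the full decomposition: invert the corpus, precompute the heading
#' similarity table, map each inverted-index entry to per-pair
#' contributions ([docsim_map()]), optionally combine within partitions,
#' shuffle (group by canonical pair key) and reduce ([docsim_reduce()]).
#' The output equals the brute-force pairwise matrix
#' ([doc_sim_matrix_bruteforce()]) elementwise to within floating-point
#' regrouping (`<= 1e-9`) for any worker count, with or without combiner.
#'
#' Without the combiner, shuffled contributions are summed per key in a
#' fixed canonical order (heading, then target document), so the matrix is
#' bitwise identical for every worker count. With the combiner, per-
#' partition partial sums regroup the floating-point additions and results
#' may differ across worker counts in the last bits only.
#'
#' @param ont A `mesh_ontology`.
#' @param measure Measure name (see [MEASURES]).
#' @param corpus A `mesh_corpus`.
#' @param workers Number of logical map partitions (`>= 1`).
#' @param use_combiner Apply the pre-shuffle combiner per partition.
#' @param table Optional precomputed `heading_sim_table`.
#' @return `n x n` symmetric similarity matrix, unit diagonal, doc-id
#'   dimnames. Attribute `counters` records `map_ops` (heading-to-document
#'   evaluations, `k * n`) and `reduce_keys` (distinct pair keys,
#'   `<= n(n-1)/2`).
#' @export
run_docsim <- function(ont, measure, corpus, workers = 1L,
                       use_combiner = FALSE, table = NULL) {
  measure <- match.arg(measure, MEASURES)
  stopifnot(workers >= 1L)
  n <- length(corpus$doc_ids)
  vocab <- corpus_vocabulary(corpus)
  k <- length(vocab)
  if (is.null(table)) {
    table <- precompute_heading_table(ont, measure, vocab, workers = workers)
  }

  index <- transform_corpus(corpus)

  # shared map-stage evaluations: S[m, j] = Sim(m, doc_j), computed once each
  vsel <- match(vocab, table$headings)
  if (anyNA(vsel)) stop("similarity table incomplete", call. = FALSE)
  tmat <- table$mat[vsel, vsel, drop = FALSE]
  hidx <- lapply(corpus$headings, function(h) match(h, vocab))
  S <- matrix(0, k, n, dimnames = list(vocab, corpus$doc_ids))
  for (j in seq_len(n)) {
    sub <- tmat[, hidx[[j]], drop = FALSE]
    S[, j] <- do.call(pmax, asplit(sub, 2))
  }
  map_ops <- k * n

  if (n == 1L) {
    out <- matrix(1, 1, 1, dimnames = list(corpus$doc_ids, corpus$doc_ids))
    attr(out, "counters") <- list(map_ops = map_ops, reduce_keys = 0L)
    return(out)
  }

  rank <- match(corpus$doc_ids, sort(corpus$doc_ids))
  sorted_ids <- sort(corpus$doc_ids)
  sizes <- lengths(corpus$headings)

  # map: one task per inverted-index entry, partitioned round-robin
  heads <- names(index)
  part <- (seq_along(heads) - 1L) %% workers + 1L
  chunk_out <- vector("list", workers)
  for (w in seq_len(workers)) {
    sel <- which(part == w)
    ems <- vector("list", length(sel))
    for (a in seq_along(sel)) {
      h <- heads[sel[a]]
      m_idx <- match(h, vocab)
      src <- match(index[[h]], corpus$doc_ids)
      si <- rep(src, each = n)
      ti <- rep(seq_len(n), times = length(src))
      keep <- si != ti
      si <- si[keep]; ti <- ti[keep]
      ems[[a]] <- list(
        key = pair_key(pmin(rank[si], rank[ti]), pmax(rank[si], rank[ti]), n),
        value = S[m_idx, ti],
        m = rep.int(m_idx, length(ti)),
        tgt = rank[ti]
      )
    }
    key <- unlist(lapply(ems, `[[`, "key"), use.names = FALSE)
    value <- unlist(lapply(ems, `[[`, "value"), use.names = FALSE)
    mm <- unlist(lapply(ems, `[[`, "m"), use.names = FALSE)
    tg <- unlist(lapply(ems, `[[`, "tgt"), use.names = FALSE)
    if (use_combiner) {
      agg <- rowsum(value, key, reorder = TRUE)
      chunk_out[[w]] <- list(key = as.numeric(rownames(agg)),
                             value = agg[, 1L], m = NULL, tgt = NULL)
    } else {
      chunk_out[[w]] <- list(key = key, value = value, m = mm, tgt = tg)
    }
  }

  # shuffle: group by key; without combiner, order contributions canonically
  key <- unlist(lapply(chunk_out, `[[`, "key"), use.names = FALSE)
  value <- unlist(lapply(chunk_out, `[[`, "value"), use.names = FALSE)
  if (!use_combiner) {
    mm <- unlist(lapply(chunk_out, `[[`, "m"), use.names = FALSE)
    tg <- unlist(lapply(chunk_out, `[[`, "tgt"), use.names = FALSE)
    o <- order(key, mm, tg)
    key <- key[o]; value <- value[o]
  } else {
    o <- order(key)
    key <- key[o]; value <- value[o]
  }

  # reduce: per-key sum over contributions, divided by the heading counts
  agg <- rowsum(value, key, reorder = TRUE)
  ukey <- as.numeric(rownames(agg))
  rlo <- pair_key_lo(ukey, n)
  rhi <- pair_key_hi(ukey, n)
  ci <- match(sorted_ids[rlo], corpus$doc_ids)
  cj <- match(sorted_ids[rhi], corpus$doc_ids)
  sims <- agg[, 1L] / (sizes[ci] + sizes[cj])

  out <- matrix(0, n, n, dimnames = list(corpus$doc_ids, corpus$doc_ids))
  out[cbind(ci, cj)] <- sims
  out[cbind(cj, ci)] <- sims
  diag(out) <- 1
  attr(out, "counters") <- list(map_ops = map_ops,
                                reduce_keys = length(ukey))
  out
}

#' Operation counters of a map/reduce run
#'
#' Extracts the instrumented counters recorded by [run_docsim()]:
#' `map_ops`, the number of heading-to-document evaluations performed in
#' the map stage (equal to `k * n` for `k` vocabulary headings and `n`
#' documents), and `reduce_keys`, the number of distinct canonical pair
#' keys reduced (at most `n(n-1)/2`).
#'
#' @param result A matrix returned by [run_docsim()].
#' @return List with `map_ops` and `reduce_keys`.
#' @export
count_operations <- function(result) {
  ctr <- attr(result, "counters")
  if (is.null(ctr)) stop("no counters recorded on this object", call. = FALSE)
  ctr
}
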