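#' Read ontology records from MeSH descriptor ASCII format
#'
#' Parses the classic descriptor dump: records separated by `*NEWRECORD`,
#' the heading taken from the `MH = ` field and tree numbers from repeated
#' `MN = ` lines. All other fields are ignored. Records without any tree
#' number (e.g. check tags) are dropped.
#'
#' @param path Path to the ASCII file.
#' @return Named list (heading -> character vector of tree numbers),
#'   suitable for [build_ontology()].
#' @examples
#' # a small synthetic sample in the descriptor format ships with the package
#' f <- system.file("extdata", "synthetic_mesh_descriptors.txt",
#'                  package = "meshsim")
#' recs <- read_mesh_ascii(f)
#' names(recs)
#' @export
read_mesh_ascii <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  recs <- split(lines, cumsum(trimws(lines) == "*NEWRECORD"))
  out <- list()
  for (r in recs) {
    mh <- sub("^MH = ", "", grep("^MH = ", r, value = TRUE))
    mn <- sub("^MN = ", "", grep("^MN = ", r, value = TRUE))
    if (length(mh) == 1L && length(mn) >= 1L) out[[trimws(mh)]] <- trimws(mn)
  }
  if (length(out) == 0L) stop("no usable MH/MN records found", call. = FALSE)
  out
}

#' Read/write ontology records as two-column TSV
#'
#' Dialect: `heading<TAB>treeNum1;treeNum2;...`, one heading per line.
#'
#' @param path File path.
#' @return `read_ontology_tsv()` returns a named list (heading -> tree
#'   numbers) for [build_ontology()].
#' @export
read_ontology_tsv <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("empty ontology file", call. = FALSE)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 2L)
  if (length(bad) > 0L) {
    stop(sprintf("malformed ontology line %d: expected 2 tab-separated fields",
                 bad[1L]), call. = FALSE)
  }
  out <- lapply(parts, function(p) strsplit(p[2L], ";", fixed = TRUE)[[1L]])
  names(out) <- vapply(parts, `[`, character(1), 1L)
  out
}

#' @rdname read_ontology_tsv
#' @param records Named list (heading -> tree numbers).
#' @export
write_ontology_tsv <- function(records, path) {
  lines <- vapply(names(records), function(h) {
    paste0(h, "\t", paste(records[[h]], collapse = ";"))
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

# Resolve the heading tokens of one corpus line against a registry
# vocabulary, greedily and longest-first, so heading names that themselves
# contain commas (e.g. "Genetic diseases, inborn") survive the comma-
# separated dialect. Tab-separated heading lists need no resolution.
resolve_headings <- function(tokens, vocab, lineno) {
  out <- character(0)
  i <- 1L
  n <- length(tokens)
  while (i <= n) {
    hit <- NA_character_
    for (j in min(n, i + 5L):i) {
      cand <- trimws(paste(tokens[i:j], collapse = ","))
      if (cand %in% vocab) { hit <- cand; i <- j + 1L; break }
    }
    if (is.na(hit)) {
      stop(sprintf("corpus line %d: cannot resolve heading starting at '%s'",
                   lineno, trimws(tokens[i])), call. = FALSE)
    }
    out <- c(out, hit)
  }
  out
}

#' Parse corpus lines of the form `docID#h1,h2,...`
#'
#' Each line is a document id, a `#`, and its heading list. Headings are
#' separated by commas, or by tabs in the escaped dialect (use tabs when
#' heading names contain commas and no registry is available). With an
#' ontology supplied, comma-separated tokens are matched greedily against
#' the registered heading vocabulary, so multi-comma heading names resolve
#' correctly; unresolvable tokens are an error with the line number.
#'
#' @param lines Character vector of corpus lines.
#' @param ont Optional `mesh_ontology` whose heading registry validates and
#'   resolves heading names.
#' @return A `mesh_corpus`.
#' @export
read_corpus_lines <- function(lines, ont = NULL) {
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty corpus", call. = FALSE)
  vocab <- if (!is.null(ont)) names(ont$headings) else NULL
  docs <- vector("list", length(lines))
  ids <- character(length(lines))
  for (i in seq_along(lines)) {
    pos <- regexpr("#", lines[i], fixed = TRUE)
    if (pos < 1L) {
      stop(sprintf("corpus line %d: missing '#' separator", i), call. = FALSE)
    }
    ids[i] <- trimws(substr(lines[i], 1L, pos - 1L))
    rest <- substr(lines[i], pos + 1L, nchar(lines[i]))
    if (!nzchar(ids[i]) || !nzchar(trimws(rest))) {
      stop(sprintf("corpus line %d: empty doc id or heading list", i), call. = FALSE)
    }
    heads <- if (grepl("\t", rest, fixed = TRUE)) {
      trimws(strsplit(rest, "\t", fixed = TRUE)[[1L]])
    } else if (!is.null(vocab)) {
      resolve_headings(strsplit(rest, ",", fixed = TRUE)[[1L]], vocab, i)
    } else {
      trimws(strsplit(rest, ",", fixed = TRUE)[[1L]])
    }
    heads <- heads[nzchar(heads)]
    if (length(heads) == 0L) {
      stop(sprintf("corpus line %d: no headings", i), call. = FALSE)
    }
    if (!is.null(vocab)) {
      miss <- setdiff(heads, vocab)
      if (length(miss) > 0L) {
        stop(sprintf("corpus line %d: unknown heading '%s'", i, miss[1L]),
             call. = FALSE)
      }
    }
    docs[[i]] <- heads
  }
  if (anyDuplicated(ids)) {
    stop(sprintf("duplicate doc id '%s'", ids[duplicated(ids)][1L]), call. = FALSE)
  }
  names(docs) <- ids
  new_corpus(docs)
}

#' @rdname read_corpus_lines
#' @param path Path to a corpus file (one `docID#headings` line per doc).
#' @export
read_corpus <- function(path, ont = NULL) {
  read_corpus_lines(readLines(path, encoding = "UTF-8", warn = FALSE), ont)
}

#' @rdname read_corpus_lines
#' @param corpus A `mesh_corpus` to serialise.
#' @export
write_corpus <- function(corpus, path) {
  lines <- vapply(seq_along(corpus$doc_ids), function(i) {
    paste0(corpus$doc_ids[i], "#", paste(corpus$headings[[i]], collapse = ","))
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read/write an inverted index (`heading#doc1,doc2,...` lines)
#'
#' @param index An `inverted_index` (see [transform_corpus()]).
#' @param path File path.
#' @export
write_inverted_index <- function(index, path) {
  lines <- vapply(names(index), function(h) {
    paste0(h, "#", paste(index[[h]], collapse = ","))
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_inverted_index
#' @export
read_inverted_index <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "#", fixed = TRUE)
  bad <- which(lengths(parts) != 2L)
  if (length(bad) > 0L) {
    stop(sprintf("malformed index line %d", bad[1L]), call. = FALSE)
  }
  idx <- lapply(parts, function(p) sort(strsplit(p[2L], ",", fixed = TRUE)[[1L]]))
  names(idx) <- vapply(parts, `[`, character(1), 1L)
  structure(idx[sort(names(idx))], class = "inverted_index")
}

#' Read/write a heading similarity table as TSV
#'
#' Dialect: `headingA<TAB>headingB<TAB>similarity`, upper triangle
#' (including the diagonal) only; symmetry is restored on read.
#'
#' @param table A `heading_sim_table`.
#' @param path File path.
#' @export
write_heading_table <- function(table, path) {
  k <- length(table$headings)
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste0("# measure=", table$measure), con)
  for (i in seq_len(k)) {
    for (j in i:k) {
      writeLines(sprintf("%s\t%s\t%.17g", table$headings[i],
                         table$headings[j], table$mat[i, j]), con)
    }
  }
  invisible(path)
}

#' @rdname write_heading_table
#' @export
read_heading_table <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  measure <- sub("^# measure=", "", lines[1L])
  lines <- lines[-1L]
  parts <- strsplit(lines[nzchar(lines)], "\t", fixed = TRUE)
  a <- vapply(parts, `[`, character(1), 1L)
  b <- vapply(parts, `[`, character(1), 2L)
  v <- as.numeric(vapply(parts, `[`, character(1), 3L))
  heads <- sort(unique(c(a, b)))
  mat <- matrix(NA_real_, length(heads), length(heads),
                dimnames = list(heads, heads))
  ia <- match(a, heads); ib <- match(b, heads)
  mat[cbind(ia, ib)] <- v
  mat[cbind(ib, ia)] <- v
  if (anyNA(mat)) stop("heading table incomplete", call. = FALSE)
  structure(list(headings = heads, mat = mat, measure = measure),
            class = "heading_sim_table")
}

#' Read/write a document similarity matrix as TSV
#'
#' Dialect: header row of doc ids, then one row per document with its id in
#' the first column.
#'
#' @param mat Similarity matrix with doc-id dimnames.
#' @param path File path.
#' @export
write_sim_matrix <- function(mat, path) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(c("doc_id", colnames(mat)), collapse = "\t"), con)
  for (i in seq_len(nrow(mat))) {
    writeLines(paste(c(rownames(mat)[i], sprintf("%.17g", mat[i, ])),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' @rdname write_sim_matrix
#' @export
read_sim_matrix <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  header <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]][-1L]
  rows <- strsplit(lines[-1L], "\t", fixed = TRUE)
  ids <- vapply(rows, `[`, character(1), 1L)
  mat <- t(vapply(rows, function(r) as.numeric(r[-1L]), numeric(length(header))))
  dimnames(mat) <- list(ids, header)
  mat
}

#' Read/write a label file (`doc_id<TAB>label` lines)
#'
#' @param labels Named vector (names = doc ids).
#' @param path File path.
#' @export
write_labels <- function(labels, path) {
  writeLines(paste(names(labels), labels, sep = "\t"), path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_labels
#' @export
read_labels <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  parts <- strsplit(lines[nzchar(lines)], "\t", fixed = TRUE)
  out <- vapply(parts, `[`, character(1), 2L)
  names(out) <- vapply(parts, `[`, character(1), 1L)
  out
}

#' Pipeline configuration
#'
#' @param measure Similarity measure (see [MEASURES]).
#' @param workers Logical map partitions.
#' @param use_combiner Apply the pre-shuffle combiner.
#' @param algorithm Clustering algorithm (see [cluster_docs()]).
#' @param k Number of clusters.
#' @param seed Seed for stochastic clustering.
#' @param res_normalization Rescale an IC-scaled (Resnik) matrix to `[0, 1]`
#'   by its maximum before clustering; by default the raw matrix is
#'   clustered.
#' @param ic_children Children-count mode for the information content (see
#'   [build_ontology()]).
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(measure = "WP", workers = 1L, use_combiner = FALSE,
                            algorithm = "spectral", k = 2L, seed = 0L,
                            res_normalization = FALSE,
                            ic_children = "direct") {
  measure <- match.arg(measure, MEASURES)
  algorithm <- match.arg(algorithm, c("spectral", "agglomerative", "kmeans"))
  stopifnot(workers >= 1L, k >= 1L)
  structure(list(measure = measure, workers = as.integer(workers),
                 use_combiner = isTRUE(use_combiner), algorithm = algorithm,
                 k = as.integer(k), seed = as.integer(seed),
                 res_normalization = isTRUE(res_normalization),
                 ic_children = match.arg(ic_children, c("direct", "descendants"))),
            class = "pipeline_config")
}

#' Run the full document-clustering pipeline
#'
#' Preprocessing (inverted index), heading-table precomputation, parallel
#' document similarity, clustering, and — when true labels are supplied —
#' NMI evaluation. Intermediates are written under `out_dir` when given
#' (inverted index, heading table, similarity matrix, predicted labels).
#'
#' @param ont A `mesh_ontology`, or a path to an ontology TSV / MeSH ASCII
#'   file.
#' @param corpus A `mesh_corpus`, or a path to a corpus file.
#' @param config A [pipeline_config()].
#' @param true_labels Optional named vector of true classes (or a label
#'   file path); enables the NMI report.
#' @param out_dir Optional directory for intermediate files.
#' @param quiet Suppress stage logging.
#' @return List with `matrix`, `labels` (predicted, named by doc id),
#'   `nmi` (or `NA` when no true labels), `counters`, and `config`.
#' @export
run_pipeline <- function(ont, corpus, config = pipeline_config(),
                         true_labels = NULL, out_dir = NULL, quiet = FALSE) {
  say <- function(stage, fmt, ...) if (!quiet) log_stage(stage, fmt, ...)
  if (is.character(ont)) {
    recs <- if (any(grepl("^\\*NEWRECORD", readLines(ont, n = 5L, warn = FALSE)))) {
      read_mesh_ascii(ont)
    } else {
      read_ontology_tsv(ont)
    }
    ont <- build_ontology(recs, ic_children = config$ic_children)
  }
  if (is.character(corpus)) corpus <- read_corpus(corpus, ont)
  if (is.character(true_labels)) true_labels <- read_labels(true_labels)

  t0 <- proc.time()[["elapsed"]]
  index <- transform_corpus(corpus)
  say("index", "%d headings over %d documents", length(index),
      length(corpus$doc_ids))
  vocab <- corpus_vocabulary(corpus)
  table <- precompute_heading_table(ont, config$measure, vocab,
                                    workers = config$workers)
  say("headsim", "%d headings, %d pairs (%s)", length(vocab),
      length(vocab) * (length(vocab) + 1L) / 2L, config$measure)
  mat <- run_docsim(ont, config$measure, corpus, workers = config$workers,
                    use_combiner = config$use_combiner, table = table)
  ctr <- count_operations(mat)
  say("docsim", "map_ops=%d reduce_keys=%d", ctr$map_ops, ctr$reduce_keys)

  cmat <- mat
  attr(cmat, "counters") <- NULL
  if (config$res_normalization && max(cmat) > 1) cmat <- cmat / max(cmat)
  labels <- cluster_docs(cmat, algorithm = config$algorithm, k = config$k,
                         seed = config$seed)
  say("cluster", "%s, k=%d", config$algorithm, config$k)

  score <- NA_real_
  if (!is.null(true_labels)) {
    miss <- setdiff(corpus$doc_ids, names(true_labels))
    if (length(miss) > 0L) {
      warning(sprintf("no true label for %d documents; NMI skipped",
                      length(miss)))
    } else {
      score <- nmi(true_labels[corpus$doc_ids], labels)
      say("nmi", "%.4f", score)
    }
  } else {
    say("nmi", "no true labels supplied; skipped")
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_inverted_index(index, file.path(out_dir, "inverted_index.txt"))
    write_heading_table(table, file.path(out_dir, "heading_sim.tsv"))
    write_sim_matrix(cmat, file.path(out_dir, "doc_sim.tsv"))
    write_labels(labels, file.path(out_dir, "clusters.tsv"))
  }
  say("done", "elapsed %.2fs", proc.time()[["elapsed"]] - t0)

  list(matrix = cmat, labels = labels, nmi = score, counters = ctr,
       config = config)
}
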