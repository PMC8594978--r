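#' Parse a MeSH-style tree number
#'
#' A tree number is a dot-separated path code such as `"G02.111.222"`: each
#' component descends one level, so the number of components is the depth of
#' the node it names and every prefix names an ancestor.
#'
#' @param text Single non-empty character string, components separated by `"."`.
#' @return An object of class `tree_number`: a list with `text`, `components`
#'   (character vector) and `depth` (integer, `>= 1`).
#' @examples
#' tn <- parse_tree_number("G02.111.222")
#' tn$depth  # 3
#' @export
parse_tree_number <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text) || !nzchar(text)) {
    stop("malformed tree number: must be a single non-empty string", call. = FALSE)
  }
  check_tree_numbers(text)
  comps <- strsplit(text, ".", fixed = TRUE)[[1L]]
  if (length(comps) == 0L || any(!nzchar(comps))) {
    stop(sprintf("malformed tree number '%s': empty component", text), call. = FALSE)
  }
  structure(
    list(text = text, components = comps, depth = length(comps)),
    class = "tree_number"
  )
}

#' @export
print.tree_number <- function(x, ...) {
  cat("<tree number> ", x$text, " (depth ", x$depth, ")\n", sep = "")
  invisible(x)
}

# Vectorised validity check used by readers/builders; stops on first bad id.
check_tree_numbers <- function(ids) {
  bad <- !nzchar(ids) | grepl("(^\\.)|(\\.$)|(\\.\\.)", ids) | is.na(ids)
  if (any(bad)) {
    stop(sprintf("malformed tree number '%s'", ids[which(bad)[1L]]), call. = FALSE)
  }
  invisible(ids)
}

tree_number_depth <- function(ids) {
  # depth = component count = dots + 1
  nchar(ids) - nchar(gsub(".", "", ids, fixed = TRUE)) + 1L
}

tree_number_parent <- function(ids) {
  # "" for category roots (parent is the virtual root)
  sub("\\.[^.]*$", "", ids) |>
    (\(p) ifelse(p == ids, "", p))()
}

# All strict prefixes of each id, e.g. "A.1.1" -> c("A", "A.1").
tree_number_prefixes <- function(id) {
  comps <- strsplit(id, ".", fixed = TRUE)[[1L]]
  if (length(comps) <= 1L) return(character(0))
  vapply(seq_len(length(comps) - 1L), function(i) {
    paste(comps[seq_len(i)], collapse = ".")
  }, character(1))
}

#' Build an ontology forest from heading records
#'
#' Materialises the tree-number forest behind a set of named headings. Nodes
#' implied by a prefix but never listed (e.g. `"A.1"` when only `"A.1.1"`
#' appears) are created as unnamed internal nodes, so every node's parent
#' exists and ancestor queries are total. All category trees hang off a
#' synthetic virtual root of depth 0 and information content 0.
#'
#' The structure-based information content of every node is precomputed as
#' \deqn{IC(v) = H(v) \left(1 - \frac{\log(|C(v)| + 1)}{\log T_{total}}\right)}
#' where \eqn{H(v)} is the node's depth, \eqn{C(v)} its set of direct
#' children and \eqn{T_{total}} the number of (real) nodes in the forest.
#' Leaves therefore have \eqn{IC = H}; the ratio of logarithms makes the
#' value independent of the log base.
#'
#' @param records Named list: names are heading names, each element a
#'   character vector of tree numbers (at least one per heading). Duplicate
#'   heading names are allowed only with identical node sets.
#' @param ic_children How to count \eqn{|C(v)|}: `"direct"` (default) counts
#'   direct children only; `"descendants"` counts the whole subtree below
#'   the node.
#' @return An object of class `mesh_ontology` with components `nodes`
#'   (character vector of tree numbers), `depth`, `n_children`, `ic`
#'   (parallel vectors), `T_total`, `D` (maximum depth), and `headings`
#'   (named list heading name -> tree numbers).
#' @examples
#' ont <- build_ontology(list(
#'   hA = "A", h1 = "A.1", h2 = "A.2", h11 = "A.1.1", h12 = "A.1.2"
#' ))
#' ont$T_total  # 5
#' @export
build_ontology <- function(records, ic_children = c("direct", "descendants")) {
  ic_children <- match.arg(ic_children)
  if (length(records) == 0L) stop("no heading records supplied", call. = FALSE)
  if (is.null(names(records)) || any(!nzchar(names(records)))) {
    stop("records must be a named list (heading name -> tree numbers)", call. = FALSE)
  }
  ids <- unique(unlist(records, use.names = FALSE))
  check_tree_numbers(ids)

  # duplicate heading names must carry identical node sets
  nm <- names(records)
  if (anyDuplicated(nm)) {
    for (d in unique(nm[duplicated(nm)])) {
      sets <- lapply(records[nm == d], function(x) sort(unique(x)))
      if (length(unique(sets)) > 1L) {
        stop(sprintf("heading '%s' registered with conflicting node sets", d),
             call. = FALSE)
      }
    }
    records <- records[!duplicated(nm)]
    nm <- names(records)
  }

  # prefix closure: every ancestor implied by a tree number exists as a node
  all_ids <- unique(c(ids, unlist(lapply(ids, tree_number_prefixes),
                                  use.names = FALSE)))
  all_ids <- sort(all_ids)
  depth <- tree_number_depth(all_ids)
  parent <- tree_number_parent(all_ids)

  n_children <- integer(length(all_ids))
  names(n_children) <- all_ids
  tab <- table(parent[parent != ""])
  n_children[names(tab)] <- as.integer(tab)

  if (ic_children == "descendants") {
    # subtree size below each node: count ids having this id as strict prefix
    pref <- paste0(all_ids, ".")
    n_children <- vapply(pref, function(p) {
      sum(startsWith(all_ids, p))
    }, integer(1), USE.NAMES = FALSE)
    names(n_children) <- all_ids
  }

  T_total <- length(all_ids)
  D <- max(depth)
  ic <- if (T_total >= 2L) {
    unname(depth * (1 - log(n_children + 1) / log(T_total)))
  } else {
    rep(NA_real_, T_total)
  }

  index <- new.env(parent = emptyenv(), size = T_total)
  for (i in seq_along(all_ids)) assign(all_ids[i], i, envir = index)

  headings <- lapply(records, function(x) sort(unique(x)))

  structure(
    list(
      nodes = all_ids,
      depth = depth,
      parent = parent,
      n_children = unname(n_children),
      ic = ic,
      T_total = T_total,
      D = D,
      headings = headings,
      index = index,
      ic_children = ic_children
    ),
    class = "mesh_ontology"
  )
}

#' @export
print.mesh_ontology <- function(x, ...) {
  cat("<mesh_ontology> ", x$T_total, " nodes, max depth ", x$D, ", ",
      length(x$headings), " headings\n", sep = "")
  invisible(x)
}

node_index <- function(ont, id) {
  i <- get0(id, envir = ont$index, inherits = FALSE)
  if (is.null(i)) stop(sprintf("unknown ontology node '%s'", id), call. = FALSE)
  i
}

#' Depth of a node
#'
#' @param ont A `mesh_ontology`.
#' @param id Tree number of a node in the ontology.
#' @return Integer depth (component count of the tree number).
#' @export
node_depth <- function(ont, id) ont$depth[node_index(ont, id)]

#' Heading registry lookup
#'
#' @param ont A `mesh_ontology`.
#' @param name Heading name.
#' @return Character vector of the heading's tree numbers.
#' @export
heading_nodes <- function(ont, name) {
  nd <- ont$headings[[name]]
  if (is.null(nd)) stop(sprintf("unknown heading '%s'", name), call. = FALSE)
  nd
}

#' Least common ancestor of two nodes
#'
#' The LCA is the node named by the longest common component prefix of the
#' two tree numbers. Nodes from different category trees (first component
#' differs) meet only at the virtual root, reported with id `""`, depth 0
#' and information content 0.
#'
#' @param ont A `mesh_ontology`.
#' @param v,v2 Tree numbers of nodes in the ontology.
#' @return List with `id`, `depth`, `ic` of the LCA.
#' @export
lca <- function(ont, v, v2) {
  node_index(ont, v); node_index(ont, v2)
  d <- lca_depth_pair(v, v2)
  if (d == 0L) return(list(id = "", depth = 0L, ic = 0))
  a <- strsplit(v, ".", fixed = TRUE)[[1L]]
  id <- paste(a[seq_len(d)], collapse = ".")
  list(id = id, depth = d, ic = ont$ic[node_index(ont, id)])
}

# component count of the longest common prefix of two tree numbers
lca_depth_pair <- function(v, v2) {
  a <- strsplit(v, ".", fixed = TRUE)[[1L]]
  b <- strsplit(v2, ".", fixed = TRUE)[[1L]]
  mn <- min(length(a), length(b))
  eq <- a[seq_len(mn)] == b[seq_len(mn)]
  if (!eq[1L]) return(0L)
  w <- which(!eq)
  if (length(w) == 0L) mn else w[1L] - 1L
}

#' Path length between two nodes
#'
#' Number of edges on the unique path through the forest (via the virtual
#' root when the nodes sit in different category trees):
#' `depth(v) + depth(v2) - 2 * depth(lca(v, v2))`.
#'
#' @inheritParams lca
#' @return Non-negative integer; 0 iff `v == v2`.
#' @export
path_length <- function(ont, v, v2) {
  dv <- ont$depth[node_index(ont, v)]
  dw <- ont$depth[node_index(ont, v2)]
  dv + dw - 2L * lca_depth_pair(v, v2)
}

#' Structure-based information content of a node
#'
#' Returns the precomputed intrinsic IC (see [build_ontology()] for the
#' formula). The virtual root (`id = ""`) has IC 0.
#'
#' @inheritParams lca
#' @param v Tree number, or `""` for the virtual root.
#' @return Non-negative real.
#' @export
information_content <- function(ont, v) {
  if (identical(v, "")) return(0)
  if (ont$T_total < 2L) {
    stop("information content undefined: ontology has fewer than 2 nodes",
         call. = FALSE)
  }
  ont$ic[node_index(ont, v)]
}
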