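#' Similarity measure names and levels
#'
#' Six measures are supported. `WP` (Wu-Palmer), `Res` (Resnik), `Lin` and
#' `Sch` (Schlicker) are node-level: they compare two ontology nodes and are
#' lifted to headings and documents by average-maximum-match aggregation.
#' `SP` (shortest-path ratio) and `LC` (Leacock-Chodorow) are heading-level:
#' they are computed directly from the shortest/longest path lengths between
#' the two headings' node sets.
#'
#' @param measure Measure name, one of `"SP"`, `"WP"`, `"LC"`, `"Res"`,
#'   `"Lin"`, `"Sch"`.
#' @return `measure_level()` returns `"node"` or `"heading"`.
#' @export
measure_level <- function(measure) {
  measure <- match.arg(measure, MEASURES)
  if (measure %in% c("SP", "LC")) "heading" else "node"
}

#' @rdname measure_level
#' @format `MEASURES` is the character vector of supported measure names.
#' @export
MEASURES <- c("SP", "WP", "LC", "Res", "Lin", "Sch")

#' Wu-Palmer node similarity
#'
#' `2 * depth(lca(v, v2)) / (depth(v) + depth(v2))`, in `[0, 1]`. Nodes in
#' different category trees share only the virtual root (depth 0) and score 0.
#'
#' @param ont A `mesh_ontology`.
#' @param v,v2 Tree numbers of nodes in the ontology.
#' @export
sim_wp <- function(ont, v, v2) {
  dv <- ont$depth[node_index(ont, v)]
  dw <- ont$depth[node_index(ont, v2)]
  2 * lca_depth_pair(v, v2) / (dv + dw)
}

#' Resnik node similarity
#'
#' Information content of the least common ancestor. Unbounded above (up to
#' the maximum IC in the ontology); 0 across category trees.
#'
#' @inheritParams sim_wp
#' @export
sim_res <- function(ont, v, v2) {
  lca(ont, v, v2)$ic
}

#' Lin node similarity
#'
#' `2 * IC(lca) / (IC(v) + IC(v2))`, in `[0, 1]`. If both nodes have zero
#' information content the ratio is undefined and 0 is returned.
#'
#' @inheritParams sim_wp
#' @export
sim_lin <- function(ont, v, v2) {
  denom <- information_content(ont, v) + information_content(ont, v2)
  if (denom <= 0) return(0)
  2 * sim_res(ont, v, v2) / denom
}

#' Schlicker node similarity
#'
#' The Lin ratio damped by how specific the shared ancestor is:
#' `sim_lin(v, v2) * (1 - exp(-IC(lca(v, v2))))`. Strictly below 1 even for
#' identical nodes; penalises matches whose common ancestor is generic.
#'
#' @inheritParams sim_wp
#' @export
sim_sch <- function(ont, v, v2) {
  sim_lin(ont, v, v2) * (1 - exp(-sim_res(ont, v, v2)))
}

#' Shortest/longest path statistics between two headings
#'
#' A heading maps to one or more ontology nodes; `L_min`/`L_max` are the
#' minimum and maximum of [path_length()] over all node pairs drawn from the
#' two headings' node sets.
#'
#' @param ont A `mesh_ontology`.
#' @param m,m2 Heading names registered in the ontology.
#' @return List with integers `L_min` and `L_max` (`0 <= L_min <= L_max`).
#' @export
heading_path_stats <- function(ont, m, m2) {
  va <- heading_nodes(ont, m)
  vb <- heading_nodes(ont, m2)
  if (length(va) == 0L || length(vb) == 0L) {
    stop("heading with empty node set", call. = FALSE)
  }
  pl <- outer(va, vb, Vectorize(function(a, b) path_length(ont, a, b)))
  list(L_min = as.integer(min(pl)), L_max = as.integer(max(pl)))
}

#' Shortest-path heading similarity
#'
#' `(L_max - L_min) / L_max` over the two headings' node sets, implemented
#' exactly in that ratio form. When `L_max = 0` (both headings are the same
#' single node) the ratio is 0/0 and the similarity is defined as 1:
#' identical headings are maximally similar.
#'
#' @inheritParams heading_path_stats
#' @export
sim_sp <- function(ont, m, m2) {
  st <- heading_path_stats(ont, m, m2)
  if (st$L_max == 0L) return(1)
  (st$L_max - st$L_min) / st$L_max
}

#' Leacock-Chodorow heading similarity
#'
#' `1 - log(1 + L_min) / log(1 + 2 * D)` where `D` is the maximum node depth
#' of the ontology, so the longest possible path (leaf to leaf through the
#' virtual root) maps to 0 and identical headings to 1.
#'
#' @inheritParams heading_path_stats
#' @export
sim_lc <- function(ont, m, m2) {
  if (ont$D < 1L) stop("ontology has no nodes", call. = FALSE)
  st <- heading_path_stats(ont, m, m2)
  1 - log(1 + st$L_min) / log(1 + 2 * ont$D)
}

#' Node-level measure dispatch
#'
#' Routes a node pair to the chosen node-level measure. Heading-level
#' measures (`SP`, `LC`) are rejected: they are not defined on node pairs.
#'
#' @inheritParams sim_wp
#' @param measure One of `"WP"`, `"Res"`, `"Lin"`, `"Sch"`.
#' @export
node_sim <- function(ont, measure, v, v2) {
  measure <- match.arg(measure, MEASURES)
  if (measure_level(measure) != "node") {
    stop(sprintf("'%s' is a heading-level measure, not defined on node pairs",
                 measure), call. = FALSE)
  }
  switch(measure,
    WP  = sim_wp(ont, v, v2),
    Res = sim_res(ont, v, v2),
    Lin = sim_lin(ont, v, v2),
    Sch = sim_sch(ont, v, v2)
  )
}

# ---- vectorised node-pair statistics ---------------------------------------
# Precomputed matrices over a fixed node set; the heading-table stage derives
# every measure from these instead of calling the scalar functions per pair.
node_stats_cache <- function(ont, node_ids) {
  node_ids <- unique(node_ids)
  k <- length(node_ids)
  idx <- vapply(node_ids, function(id) node_index(ont, id), integer(1))
  depth <- ont$depth[idx]
  ic <- ont$ic[idx]
  comps <- strsplit(node_ids, ".", fixed = TRUE)

  lca_depth <- matrix(0L, k, k)
  lca_ic <- matrix(0, k, k)
  for (i in seq_len(k)) {
    a <- comps[[i]]
    lca_depth[i, i] <- depth[i]
    lca_ic[i, i] <- ic[i]
    if (i < k) for (j in seq.int(i + 1L, k)) {
      b <- comps[[j]]
      mn <- min(length(a), length(b))
      eq <- a[seq_len(mn)] == b[seq_len(mn)]
      d <- if (!eq[1L]) 0L else { w <- which(!eq); if (length(w)) w[1L] - 1L else mn }
      lca_depth[i, j] <- lca_depth[j, i] <- d
      if (d > 0L) {
        anc <- paste(a[seq_len(d)], collapse = ".")
        v <- ont$ic[node_index(ont, anc)]
        lca_ic[i, j] <- lca_ic[j, i] <- v
      }
    }
  }
  path_len <- outer(depth, depth, "+") - 2L * lca_depth
  list(ids = node_ids, depth = depth, ic = ic,
       lca_depth = lca_depth, lca_ic = lca_ic, path_len = path_len)
}

# k x k node-level similarity matrix from a node_stats_cache
node_sim_matrix <- function(cache, measure) {
  switch(measure,
    WP = 2 * cache$lca_depth / outer(cache$depth, cache$depth, "+"),
    Res = cache$lca_ic,
    Lin = {
      denom <- outer(cache$ic, cache$ic, "+")
      s <- 2 * cache$lca_ic / denom
      s[denom <= 0] <- 0
      s
    },
    Sch = {
      denom <- outer(cache$ic, cache$ic, "+")
      s <- 2 * cache$lca_ic / denom
      s[denom <= 0] <- 0
      s * (1 - exp(-cache$lca_ic))
    },
    stop(sprintf("'%s' is not a node-level measure", measure), call. = FALSE)
  )
}
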