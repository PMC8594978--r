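test_that("tree numbers parse into components and depth", {
  tn <- parse_tree_number("G02.111.222")
  expect_equal(tn$components, c("G02", "111", "222"))
  expect_equal(tn$depth, 3L)
  expect_equal(parse_tree_number("C16.320")$depth, 2L)
  expect_equal(parse_tree_number("A")$depth, 1L)
  # re-joining components reproduces the text
  expect_equal(paste(tn$components, collapse = "."), tn$text)
  expect_error(parse_tree_number(""), "malformed")
  expect_error(parse_tree_number("A..B"), "malformed")
  expect_error(parse_tree_number("A."), "malformed")
})

test_that("ontology construction counts nodes, closes prefixes, registers headings", {
  ont <- toy_ontology()
  expect_equal(ont$T_total, 5L)
  expect_equal(ont$D, 3L)

  # ancestors implied by a prefix are materialized as unnamed nodes
  ont2 <- build_ontology(list(h = "A.1.1"))
  expect_equal(ont2$T_total, 3L)
  expect_setequal(ont2$nodes, c("A", "A.1", "A.1.1"))

  # a heading may sit at several tree positions
  ont3 <- build_ontology(list(`DNA repair` = c("G02.111.222", "G05.219")))
  expect_length(heading_nodes(ont3, "DNA repair"), 2L)

  # duplicate heading names: identical sets tolerated, conflicting ones not
  dup_ok <- list(h = "A.1", h = "A.1", g = "A.2")
  expect_silent(build_ontology(dup_ok))
  dup_bad <- list(h = "A.1", h = "A.2")
  expect_error(build_ontology(dup_bad), "conflicting")
})

test_that("lca is the longest common prefix, with a virtual root across trees", {
  ont <- toy_ontology()
  expect_equal(lca(ont, "A.1.1", "A.1.2")$id, "A.1")
  expect_equal(lca(ont, "A.1.1", "A.1.1")$id, "A.1.1")
  tt <- twotree_ontology()
  root <- lca(tt, "A.1", "B.2")
  expect_equal(root$id, "")
  expect_equal(root$depth, 0L)
  expect_equal(root$ic, 0)
  expect_error(lca(ont, "A.1.1", "Z.9"), "unknown")
})

test_that("path length follows the lca decomposition", {
  ont <- toy_ontology()
  expect_equal(path_length(ont, "A.1.1", "A.2"), 3L)
  expect_equal(path_length(ont, "A.1.1", "A.1.1"), 0L)
  tt <- twotree_ontology()
  expect_equal(path_length(tt, "A.1", "B.1"), 4L)
  # symmetry + triangle inequality, exhaustively on the toy forest
  nodes <- ont$nodes
  pl <- outer(nodes, nodes, Vectorize(function(a, b) path_length(ont, a, b)))
  expect_equal(pl, t(pl))
  for (i in seq_along(nodes)) for (j in seq_along(nodes)) for (k in seq_along(nodes)) {
    expect_lte(pl[i, j], pl[i, k] + pl[k, j])
  }
  expect_true(all(diag(pl) == 0L))
})

test_that("lca and path length agree with graph/ancestor-set oracles", {
  skip_if_not_installed("igraph")
  for (seed in 1:5) {
    fx <- random_fixture(seed, n_headings = 15L)
    ont <- fx$ont
    nodes <- ont$nodes
    # oracle graph: parent-child edges plus virtual root joining categories
    parents <- ifelse(ont$parent == "", "<root>", ont$parent)
    g <- igraph::graph_from_data_frame(
      data.frame(from = parents, to = nodes), directed = FALSE
    )
    dmat <- igraph::distances(g)
    withr::with_seed(seed, {
      vi <- sample(nodes, 25L, replace = TRUE)
      vj <- sample(nodes, 25L, replace = TRUE)
    })
    for (p in seq_along(vi)) {
      expect_equal(path_length(ont, vi[p], vj[p]), unname(dmat[vi[p], vj[p]]))
      # ancestor-set oracle for the lca: deepest common member of the two
      # ancestor chains (virtual root if none)
      anc <- function(v) c("<root>", v, rev(meshsim:::tree_number_prefixes(v)))
      common <- intersect(anc(vi[p]), anc(vj[p]))
      depth_of <- function(x) if (x == "<root>") 0L else length(strsplit(x, ".", fixed = TRUE)[[1L]])
      best <- common[which.max(vapply(common, depth_of, integer(1)))]
      got <- lca(ont, vi[p], vj[p])
      expect_equal(got$depth, depth_of(best))
      expect_equal(got$id, if (best == "<root>") "" else best)
    }
  }
})

test_that("information content follows the structural formula", {
  ont <- toy_ontology()
  expect_equal(information_content(ont, "A"), 1 * (1 - log(3) / log(5)),
               tolerance = 1e-12)
  expect_equal(information_content(ont, "A.1"), 2 * (1 - log(3) / log(5)),
               tolerance = 1e-12)
  # leaves: |C| = 0, so IC = depth exactly
  expect_equal(information_content(ont, "A.1.1"), 3)
  expect_equal(information_content(ont, ""), 0) # virtual root
  expect_true(all(ont$ic >= 0))
  # one-node ontology: log(T_total) = 0, IC undefined
  tiny <- build_ontology(list(h = "A"))
  expect_error(information_content(tiny, "A"), "fewer than 2")
})

test_that("IC increases strictly with depth along a chain", {
  chain <- build_ontology(list(h = "A.1.1.1.1"))
  ics <- vapply(c("A", "A.1", "A.1.1", "A.1.1.1", "A.1.1.1.1"),
                function(v) information_content(chain, v), numeric(1))
  expect_true(all(diff(ics) > 0))
})

test_that("building from leaves only matches full listings", {
  full <- toy_ontology()
  leaves <- build_ontology(list(m1 = "A.1.1", m2 = c("A.1.2", "A.2")))
  for (pair in list(c("A.1.1", "A.1.2"), c("A.1.1", "A.2"), c("A", "A.1.2"))) {
    expect_equal(lca(full, pair[1], pair[2])$id, lca(leaves, pair[1], pair[2])$id)
    expect_equal(path_length(full, pair[1], pair[2]),
                 path_length(leaves, pair[1], pair[2]))
    expect_equal(node_depth(full, pair[1]), node_depth(leaves, pair[1]))
  }
})

test_that("descendant-count IC mode differs only for internal nodes", {
  direct <- build_ontology(list(h = "A.1.1", g = "A.1.2", f = "A.2"))
  desc <- build_ontology(list(h = "A.1.1", g = "A.1.2", f = "A.2"),
                         ic_children = "descendants")
  # A has 2 direct children but 4 descendants
  expect_lt(information_content(desc, "A"), information_content(direct, "A"))
  expect_equal(information_content(desc, "A.1.1"),
               information_content(direct, "A.1.1"))
})

test_that("mesh ascii reader extracts MH/MN fields", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c(
    "*NEWRECORD",
    "RECTYPE = D",
    "MH = DNA Repair",
    "MN = G02.111.222",
    "MN = G05.219",
    "AN = irrelevant",
    "*NEWRECORD",
    "MH = Humans",
    "MN = B01.050.150.900.649.313.988.400.112.400.400"
  ), path)
  recs <- read_mesh_ascii(path)
  expect_named(recs, c("DNA Repair", "Humans"))
  expect_equal(recs[["DNA Repair"]], c("G02.111.222", "G05.219"))
  ont <- build_ontology(recs)
  expect_length(heading_nodes(ont, "DNA Repair"), 2L)

  # the shipped synthetic sample builds into a queryable ontology
  sample_file <- system.file("extdata", "synthetic_mesh_descriptors.txt",
                             package = "meshsim")
  recs2 <- read_mesh_ascii(sample_file)
  expect_gte(length(recs2), 8L)
  ont2 <- build_ontology(recs2)
  expect_gt(sim_wp(ont2, "G02.111.222", "G02.111.221"), 0.5) # sibling repair/damage nodes
})
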