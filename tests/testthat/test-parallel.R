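test_that("corpus inversion groups documents under shared headings", {
  ont <- build_ontology(list(m1 = "A.1", m2 = "A.2", m3 = "B.1"))
  idx <- transform_corpus(c("d1#m1,m2", "d2#m1", "d4#m1,m3"), ont)
  expect_equal(idx[["m1"]], c("d1", "d2", "d4"))
  expect_equal(idx[["m2"]], "d1")
  expect_equal(idx[["m3"]], "d4")

  single <- transform_corpus(new_corpus(list(d9 = "m2")))
  expect_equal(unclass(single), list(m2 = "d9"), ignore_attr = TRUE)

  # conservation: sum of index list lengths = sum of document heading counts
  fx <- random_fixture(3, docs_per_topic = 30L)
  idx2 <- transform_corpus(fx$corpus)
  expect_equal(sum(lengths(idx2)), sum(lengths(fx$corpus$headings)))
  expect_setequal(unique(unlist(idx2)), fx$corpus$doc_ids)

  expect_error(transform_corpus("no separator here"), "line 1")
  expect_error(transform_corpus("d1#"), "line 1")
})

test_that("heading table covers all pairs and ignores worker partitioning", {
  ont <- toy_ontology()
  tab <- precompute_heading_table(ont, "WP", c("m1", "m2"))
  expect_equal(tab$mat["m1", "m2"], 0.5777778, tolerance = 1e-6)
  expect_symmetric(tab$mat)

  fx <- random_fixture(7)
  vocab <- corpus_vocab <- sort(unique(unlist(fx$corpus$headings)))
  t1 <- precompute_heading_table(fx$ont, "Lin", vocab, workers = 1L)
  t4 <- precompute_heading_table(fx$ont, "Lin", vocab, workers = 4L)
  expect_identical(t1$mat, t4$mat)
  k <- length(vocab)
  expect_equal(sum(upper.tri(t1$mat, diag = TRUE)), k * (k + 1) / 2)
  # table entries match direct heading_sim calls
  withr::with_seed(7, idx <- cbind(sample(k, 10, TRUE), sample(k, 10, TRUE)))
  for (r in seq_len(nrow(idx))) {
    expect_equal(t1$mat[idx[r, 1], idx[r, 2]],
                 heading_sim(fx$ont, "Lin", vocab[idx[r, 1]], vocab[idx[r, 2]]),
                 tolerance = 1e-12)
  }
})

test_that("map stage emits each heading-to-document contribution to canonical pairs", {
  ont <- toy_ontology()
  corpus <- toy_corpus()
  tab <- precompute_heading_table(ont, "WP", c("m1", "m2"))
  em <- docsim_map(tab, corpus, "m1", docs_with_m = "d1")
  expect_equal(nrow(em), 1L)
  expect_equal(em$doc_lo, "d1")
  expect_equal(em$doc_hi, "d2")
  expect_equal(em$value, 0.5777778, tolerance = 1e-6)

  # heading shared by all documents: n(n-1) emissions over n(n-1)/2 keys
  shared <- new_corpus(list(a = "m1", b = "m1", c = "m1"))
  em2 <- docsim_map(tab, shared, "m1")
  expect_equal(nrow(em2), 3L * 2L)
  expect_equal(length(unique(paste(em2$doc_lo, em2$doc_hi))), 3L)
  expect_true(all(em2$doc_lo < em2$doc_hi))

  # a single-document corpus has no pairs to emit
  em3 <- docsim_map(tab, new_corpus(list(only = "m1")), "m1")
  expect_equal(nrow(em3), 0L)

  expect_error(docsim_map(tab, corpus, "m2", docs_with_m = character(0)),
               "absent")
})

test_that("combiner sums per key, conserves totals, and is idempotent", {
  pairs <- data.frame(doc_lo = c("a", "a", "b"), doc_hi = c("b", "b", "c"),
                      value = c(0.2, 0.3, 0.5))
  out <- combiner(pairs)
  expect_equal(nrow(out), 2L)
  expect_equal(out$value[out$doc_lo == "a"], 0.5)
  expect_equal(sum(out$value), sum(pairs$value))
  expect_equal(combiner(out), out)
  empty <- combiner(pairs[0, ])
  expect_equal(nrow(empty), 0L)
})

test_that("reduce divides the pooled contributions by the heading counts", {
  corpus <- new_corpus(list(d1 = c("x", "y"), d2 = "z"))
  expect_equal(docsim_reduce("d1", "d2", c(0.6, 0.4, 0.5), corpus), 0.5)
  expect_equal(docsim_reduce("d1", "d2", rep(1, 3), corpus), 1)
  expect_error(docsim_reduce("d1", "zz", 1, corpus), "unknown doc id")
})

test_that("map/shuffle/reduce equals the brute-force matrix on the toy corpus", {
  ont <- toy_ontology()
  corpus <- toy_corpus()
  got <- run_docsim(ont, "WP", corpus)
  expect_equal(got["d1", "d2"], 0.5777778, tolerance = 1e-6)
  expect_equal(diag(got), c(d1 = 1, d2 = 1))
  oracle <- doc_sim_matrix_bruteforce(ont, "WP", corpus)
  expect_lt(max(abs(got - oracle)), 1e-12)
})

test_that("engine output is invariant to worker count and combiner", {
  fx <- random_fixture(21, docs_per_topic = 15L)
  strip <- function(m) { attr(m, "counters") <- NULL; m }
  base <- strip(run_docsim(fx$ont, "WP", fx$corpus, workers = 1L))
  for (w in c(2L, 4L, 8L)) {
    # without combiner the canonical summation order makes runs bitwise equal
    expect_identical(strip(run_docsim(fx$ont, "WP", fx$corpus, workers = w)),
                     base)
  }
  for (w in c(1L, 4L)) {
    withc <- run_docsim(fx$ont, "WP", fx$corpus, workers = w, use_combiner = TRUE)
    expect_lt(max(abs(withc - base)), 1e-9)
  }
})

test_that("pairs sharing no heading still reduce to a well-defined value", {
  ont <- twotree_ontology()
  corpus <- new_corpus(list(d1 = c("a1", "a11"), d2 = c("b1", "b2")))
  got <- run_docsim(ont, "WP", corpus)
  oracle <- doc_sim_matrix_bruteforce(ont, "WP", corpus)
  expect_equal(got["d1", "d2"], oracle["d1", "d2"])
  expect_equal(got["d1", "d2"], 0) # disjoint trees under WP
  expect_equal(count_operations(got)$reduce_keys, 1L)
})

test_that("operation counters match the k*n / n(n-1)/2 decomposition", {
  for (seed in 1:3) {
    fx <- random_fixture(seed * 100L, docs_per_topic = 12L)
    n <- length(fx$corpus$doc_ids)
    k <- length(unique(unlist(fx$corpus$headings)))
    got <- run_docsim(fx$ont, "WP", fx$corpus, workers = 2L)
    ctr <- count_operations(got)
    expect_equal(ctr$map_ops, k * n)
    expect_lte(ctr$reduce_keys, n * (n - 1) / 2)
  }
  one <- run_docsim(toy_ontology(), "WP", new_corpus(list(solo = "m1")))
  expect_equal(count_operations(one)$reduce_keys, 0L)
})

test_that("engine matches the pairwise oracle across measures", {
  for (seed in c(5, 6)) {
    fx <- random_fixture(seed, docs_per_topic = 10L)
    for (me in MEASURES) {
      got <- run_docsim(fx$ont, me, fx$corpus, workers = 3L)
      oracle <- doc_sim_matrix_bruteforce(fx$ont, me, fx$corpus)
      expect_lt(max(abs(got - oracle)), 1e-9)
    }
  }
})
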