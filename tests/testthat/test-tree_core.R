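test_that("Newick parsing validates input and fills default branch lengths", {
  t1 <- parse_newick("(A,B,(C,D));")
  expect_s3_class(t1, "phylo")
  expect_setequal(t1$tip.label, c("A", "B", "C", "D"))
  expect_false(ape::is.rooted(t1))
  expect_equal(t1$edge.length, rep(1, nrow(t1$edge)))  # default fill
  expect_equal(parse_newick("(A,B);", default_blen = 2.5)$edge.length, c(2.5, 2.5))

  t2 <- parse_newick("((A:1,B:1):0.5,C:1.5);")
  d <- ape::cophenetic.phylo(t2)
  expect_equal(d["A", "B"], 2)
  expect_equal(d["A", "C"], 3)

  expect_error(parse_newick("(A,(B;"), "unbalanced")
  expect_error(parse_newick("(A,B,A);"), "duplicate")
  expect_error(parse_newick("(A,B)"), "';'")
})

test_that("Newick round-trip preserves topology, labels and lengths", {
  set.seed(11)
  for (i in 1:10) {
    tr <- random_binary_tree(sample(4:15, 1))
    tr2 <- parse_newick(write_newick(tr))
    expect_setequal(tr2$tip.label, tr$tip.label)
    expect_equal(oracle_rf(tr, tr2), 0)
    d1 <- ape::cophenetic.phylo(tr)
    d2 <- ape::cophenetic.phylo(tr2)[rownames(d1), colnames(d1)]
    expect_equal(d1, d2, tolerance = 1e-12)
  }
})

test_that("bipartitions enumerate internal edges of the unrooted form", {
  expect_equal(tree_bipartitions(parse_newick("((A,B),(C,D));")), "A,B|C,D")
  expect_length(tree_bipartitions(parse_newick("(A,B,C,D);")), 0)
  # hand enumeration of the unrooted caterpillar: two internal edges
  expect_equal(tree_bipartitions(parse_newick("(((A,B),C),D,E);")),
               sort(c("A,B|C,D,E", "A,B,C|D,E")))
  expect_error(tree_bipartitions(parse_newick("(A,(B,C));")), "4 tips")
  # binary n-tip trees yield n - 3 bipartitions
  set.seed(3)
  for (n in c(5, 8, 12)) {
    tr <- random_binary_tree(n)
    expect_length(tree_bipartitions(tr), n - 3)
    expect_equal(tree_bipartitions(tr), oracle_bipartitions(tr))
  }
})

test_that("RF distance equals the bipartition symmetric difference and is a metric", {
  ta <- parse_newick("((A,B),(C,D));")
  tb <- parse_newick("((A,C),(B,D));")
  expect_equal(rf_distance(ta, ta), 0)
  expect_equal(rf_distance(ta, tb), 2)
  expect_equal(rf_distance(ta, tb, normalized = TRUE), 1)
  expect_error(rf_distance(ta, parse_newick("((A,B),(C,E));")), "differ")

  set.seed(21)
  for (i in 1:40) {
    t1 <- random_binary_tree(8)
    t2 <- random_binary_tree(8)
    t3 <- random_binary_tree(8)
    d12 <- rf_distance(t1, t2)
    expect_equal(d12, oracle_rf(t1, t2))
    expect_equal(rf_distance(t2, t1), d12)               # symmetry
    expect_equal(rf_distance(t1, t1), 0)                 # identity
    expect_lte(rf_distance(t1, t3), d12 + rf_distance(t2, t3))  # triangle
  }
})

test_that("quartet agreement counts shared and comparable 4-tip subsets", {
  t5 <- parse_newick("(((A,B),C),(D,E));")
  expect_equal(quartet_agreement(t5, t5), c(shared = 5L, comparable = 5L))
  expect_equal(quartet_agreement(parse_newick("((A,B),(C,D));"),
                                 parse_newick("((A,C),(B,D));")),
               c(shared = 0L, comparable = 1L))
  star <- parse_newick("(A,B,C,D);")
  expect_equal(quartet_agreement(t5, star)[["comparable"]], 0L)
  expect_error(quartet_agreement(parse_newick("((A,B),C);"), t5), "shared tips")
  # shared <= comparable <= C(n, 4), and agreement with the pruning oracle
  set.seed(5)
  for (i in 1:8) {
    t1 <- random_binary_tree(7)
    t2 <- random_binary_tree(7)
    qa <- quartet_agreement(t1, t2)
    expect_equal(qa, oracle_quartets(t1, t2))
    expect_lte(qa[["shared"]], qa[["comparable"]])
    expect_lte(qa[["comparable"]], choose(7, 4))
  }
})

test_that("NNI produces the two alternative resolutions around an edge", {
  t4 <- parse_newick("((A,B),(C,D));")
  e <- plastidscape:::internal_edges(t4)
  expect_length(e, 1)
  nn <- nni_neighbors(t4, e)
  keys <- sort(vapply(nn, function(x) tree_bipartitions(x), ""))
  expect_equal(keys, sort(c("A,C|B,D", "A,D|B,C")))
  for (x in nn) expect_equal(rf_distance(x, t4), 2)

  set.seed(9)
  t6 <- random_binary_tree(6)
  edges <- plastidscape:::internal_edges(t6)
  all_nb <- unlist(lapply(edges, nni_neighbors, tree = t6), recursive = FALSE)
  keys <- vapply(all_nb, function(x) paste(tree_bipartitions(x), collapse = ";"), "")
  expect_length(unique(keys), 2 * (6 - 3))

  ut <- ape::unroot(t6)
  pendant <- which(ut$edge[, 2] <= 6)[1]
  expect_error(nni_neighbors(t6, pendant), "pendant")
})

test_that("ultrametricize equalizes root-to-tip paths at depth 1", {
  spread <- plastidscape:::ultrametric_spread
  # an already ultrametric tree only gets rescaled
  u0 <- parse_newick("((A:1,B:1):1,(C:1.5,D:1.5):0.5);")
  u1 <- ultrametricize(u0)
  expect_lt(spread(u1), 1e-9)
  expect_equal(rf_distance(ape::unroot(u0), ape::unroot(u1)), 0)
  expect_equal(max(ape::node.depth.edgelength(u1)), 1)
  rel <- ape::cophenetic.phylo(u1) / ape::cophenetic.phylo(u0) * 2
  expect_lt(max(abs(rel - rel[1, 2]), na.rm = TRUE), 1e-9)  # uniform rescale

  # arbitrary input: zero variance of root-to-tip depths, unrooted handled
  set.seed(13)
  for (i in 1:5) {
    tr <- ape::unroot(random_binary_tree(8))
    u <- ultrametricize(tr)
    expect_lt(spread(u), 1e-9)
    expect_true(all(u$edge.length >= 0))  # clamped monotone ages
  }

  # a child whose mean tip path exceeds the parent's forces clamping
  v <- parse_newick("((A:0.1,(B:5,C:5):0.1):0.1,D:0.2);")
  uv <- ultrametricize(v)
  expect_lt(spread(uv), 1e-9)
  expect_true(all(uv$edge.length >= 0))

  z <- parse_newick("((A:0,B:0):0,C:0);")
  expect_error(ultrametricize(z), "zero-height")
})
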