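test_that("parse_newick reads topology, lengths and labels", {
  tr <- quartet()
  expect_s3_class(tr, "phylo")
  expect_length(tr$tip.label, 4L)
  expect_equal(nrow(tr$edge), 6L)
  expect_equal(total_edge_length(tr), 6)
  expect_true(is_rooted_tree(tr))

  t2 <- two_leaf()
  expect_length(t2$tip.label, 2L)
  expect_equal(total_edge_length(t2), 3)
})

test_that("parse_newick rejects malformed and invalid input", {
  expect_error(parse_newick("((a:1,b:1):1,(c:1,d:1):1)"),
               class = "phylodist_parse_error")
  expect_error(parse_newick("((a:1,b:1:1,(c:1,d:1):1);"),
               class = "phylodist_parse_error")
  expect_error(parse_newick("((a:1,b:1):1,(c:1,d:1):1));"),
               class = "phylodist_parse_error")
  # duplicate label, named in the message
  expect_error(parse_newick("((a:1,a:1):1,(c:1,d:1):1);"), "a")
  # missing branch length, naming the clade
  expect_error(parse_newick("((a,b:1):1,(c:1,d:1):1);"), "branch length")
  # negative length
  expect_error(parse_newick("((a:-1,b:1):1,(c:1,d:1):1);"), "negative")
  # single leaf
  expect_error(parse_newick("(a:1);"), "at least 2")
})

test_that("labels are trimmed and unquoted; underscores preserved", {
  tr <- parse_newick("(('a b':1,c_d:1):1,(e:1,f:1):1);")
  expect_true("a b" %in% tr$tip.label)
  expect_true("c_d" %in% tr$tip.label)
  rt <- parse_newick(write_newick(tr))
  expect_setequal(rt$tip.label, tr$tip.label)
})

test_that("Newick round-trip preserves topology and lengths", {
  for (txt in c("((a:1,b:1):1,(c:1,d:1):1);",
                "(a:1,b:2);",
                "(((a:1,b:1):1,c:2):1,d:3);",
                "((a:1,b:1,c:1):2,(d:0.5,e:0.5):2);")) { # with a polytomy
    tr <- parse_newick(txt)
    rt <- parse_newick(write_newick(tr))
    expect_setequal(rt$tip.label, tr$tip.label)
    expect_equal(total_edge_length(rt), total_edge_length(tr))
    # pairwise leaf distances pin down both topology and lengths
    expect_equal(ape::cophenetic.phylo(rt)[tr$tip.label, tr$tip.label],
                 ape::cophenetic.phylo(tr)[tr$tip.label, tr$tip.label])
  }
})

test_that("root branch length is stored but excluded from totals", {
  tr <- parse_newick("((a:1,b:1):1,(c:1,d:1):1):5;")
  expect_equal(tr$root.edge, 5)
  expect_equal(total_edge_length(tr), 6)
  expect_equal(sum(fair_proportion(tr)$fp), 6)
})

test_that("unroot_tree suppresses a degree-2 root and conserves length", {
  tr <- unroot_tree(quartet())
  expect_false(is_rooted_tree(tr))
  expect_equal(nrow(tr$edge), 5L)
  expect_equal(total_edge_length(tr), 6)
  expect_equal(sort(unname(pendant_lengths(tr))), rep(1, 4))
  # internal edge is the merge of the two root edges
  expect_equal(sort(tr$edge.length), c(1, 1, 1, 1, 2))

  t2 <- unroot_tree(two_leaf())
  expect_false(is_rooted_tree(t2))
  expect_equal(total_edge_length(t2), 3)

  # trifurcating root: topology unchanged, designation dropped
  t3 <- parse_newick("(a:1,b:1,c:2);")
  u3 <- unroot_tree(t3)
  expect_equal(nrow(u3$edge), nrow(t3$edge))
  expect_false(is_rooted_tree(u3))
})

test_that("phylogenetic diversity matches hand-traced values", {
  tr <- quartet()
  expect_equal(phylogenetic_diversity(tr, c("a", "b")), 2)
  expect_equal(phylogenetic_diversity(tr, c("a", "c")), 4)
  expect_equal(phylogenetic_diversity(tr, tr$tip.label), 6)
  expect_equal(phylogenetic_diversity(tr, character(0)), 0)
  expect_equal(phylogenetic_diversity(tr, "a"), 0)
  expect_error(phylogenetic_diversity(tr, "zz"), "zz")
})

test_that("PD is monotone under subset growth", {
  tr <- yule_tree(12, seed = 31)
  withr::with_seed(7, {
    for (i in 1:20) {
      y <- sample(tr$tip.label, sample(0:10, 1))
      z <- union(y, sample(tr$tip.label, sample(1:6, 1)))
      expect_lte(phylogenetic_diversity(tr, y),
                 phylogenetic_diversity(tr, z))
    }
  })
  expect_equal(phylogenetic_diversity(tr, tr$tip.label),
               total_edge_length(tr))
})

test_that("splits partition the taxon set", {
  tr <- quartet()
  pend_a <- which(tr$edge[, 2L] == which(tr$tip.label == "a"))
  sp <- split_of_edge(tr, pend_a, "a")
  expect_equal(sp$block, "a")
  expect_equal(sort(sp$co_block), c("b", "c", "d"))
  sp2 <- split_of_edge(tr, pend_a, "b") # other side of the same edge
  expect_equal(sort(sp2$block), c("b", "c", "d"))
  for (e in seq_len(nrow(tr$edge))) {
    s <- split_of_edge(tr, e, "a")
    expect_equal(sum(s$sizes), length(tr$tip.label))
    expect_setequal(c(s$block, s$co_block), tr$tip.label)
  }
})

test_that("unrooting preserves all leaf-set splits (PD of every pair)", {
  tr <- yule_tree(10, seed = 77)
  un <- unroot_tree(tr)
  pairs <- t(combn(tr$tip.label, 2))
  for (i in seq_len(nrow(pairs))) {
    expect_equal(phylogenetic_diversity(un, pairs[i, ]),
                 phylogenetic_diversity(tr, pairs[i, ]))
  }
})
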