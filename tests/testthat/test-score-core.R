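test_that("fair proportion matches hand-computed path sums", {
  fp <- fair_proportion(quartet())
  expect_equal(fp$fp, rep(1.5, 4))
  expect_equal(sum(fp$fp), 6)

  fp2 <- fair_proportion(caterpillar())
  expect_equal(by_taxon(fp2, "fp", "d"), 3)
  expect_equal(by_taxon(fp2, "fp", "c"), 2 + 1 / 3)
  expect_equal(by_taxon(fp2, "fp", c("a", "b")), rep(1 + 1 / 2 + 1 / 3, 2))
})

test_that("fair proportion agrees with an independent implementation", {
  tr <- yule_tree(40, seed = 404)
  fp <- fair_proportion(tr)
  ed <- picante::evol.distinct(tr, type = "fair.proportion")
  expect_lt(max_rel_err(fp$fp, ed$w[match(fp$taxon, ed$Species)]), 1e-9)
})

test_that("FP conservation holds and unrooted input is rejected", {
  for (seed in 1:5) {
    tr <- yule_tree(30, seed = seed)
    expect_lt(abs(sum(fair_proportion(tr)$fp) - total_edge_length(tr)) /
                total_edge_length(tr), 1e-12)
  }
  expect_error(fair_proportion(unroot_tree(quartet())), "root")
})

test_that("Shapley matches the hand-traced small cases", {
  expect_equal(shapley_linear(quartet())$shapley, rep(1.5, 4))
  expect_equal(shapley_linear(two_leaf())$shapley, rep(1.5, 2))
})

test_that("Shapley efficiency: scores sum to total edge length", {
  for (seed in c(2, 9, 23)) {
    tr <- yule_tree(150, seed = seed)
    sh <- shapley_linear(tr)
    expect_lt(abs(sum(sh$shapley) - total_edge_length(tr)) /
                total_edge_length(tr), 1e-9)
  }
})

test_that("linear and quadratic Shapley agree on mid-scale trees", {
  tr <- yule_tree(200, seed = 11)
  expect_lt(max_rel_err(shapley_linear(tr)$shapley,
                        shapley_quadratic(tr)$shapley), 1e-9)
})

test_that("HED matches the hand-traced quartet and limit cases", {
  tr <- quartet()
  expect_equal(hed_linear(tr, uniform_p(tr, 0.5))$hed, rep(2, 4))
  # everyone dies for sure: nothing left to be distinct from
  expect_equal(hed_linear(tr, uniform_p(tr, 1))$hed, rep(0, 4))
  # no one dies: only the pendant edge is at stake
  expect_equal(hed_linear(tr, uniform_p(tr, 0))$hed,
               unname(pendant_lengths(tr)))
})

test_that("linear and quadratic HED agree, including forced zeros", {
  tr <- yule_tree(200, seed = 12)
  for (k in c(0L, 1L, 5L)) {
    p <- random_probabilities(tr$tip.label, n_zeros = k, seed = 100 + k)
    expect_lt(max_rel_err(hed_linear(tr, p)$hed,
                          hed_quadratic(tr, p)$hed), 1e-9)
  }
})

test_that("hed_zero_prob equals the definitional edge form", {
  tr <- quartet()
  p <- c(a = 0, b = 0.5, c = 0.5, d = 0.5)
  expect_equal(hed_zero_prob(tr, p, "a"), hed_exhaustive(tr, p, "a"))
  p2 <- c(a = 0, b = 0, c = 0.5, d = 0.5)
  expect_equal(hed_zero_prob(tr, p2, "a"), hed_exhaustive(tr, p2, "a"))
  expect_equal(hed_zero_prob(tr, p2, "b"), hed_exhaustive(tr, p2, "b"))
  expect_error(hed_zero_prob(tr, p, "b"), "p = 0")
})

test_that("HED errors on missing or out-of-range probabilities", {
  tr <- quartet()
  expect_error(hed_linear(tr, c(a = 0.5, b = 0.5, c = 0.5)), "d")
  expect_error(hed_linear(tr, c(a = 1.5, b = 0.5, c = 0.5, d = 0.5)),
               "\\[0,1\\]")
  expect_warning(hed_linear(tr, c(a = 1e-310, b = .5, c = .5, d = .5)),
                 "treated as 0")
})

test_that("edge product multiplies FP by extinction probability", {
  fp <- fair_proportion(quartet())
  p <- c(a = 0.4, b = 0, c = 1, d = 0.5)
  ep <- edge_product(fp, p)
  expect_equal(by_taxon(ep, "edge_product", "a"), 1.5 * 0.4)
  expect_equal(by_taxon(ep, "edge_product", "b"), 0)
  expect_equal(by_taxon(ep, "edge_product", "c"), by_taxon(ep, "fp", "c"))
  expect_error(edge_product(fp, c(a = .1, b = .1, c = .1, zz = .1)), "zz")
})

test_that("leaf ordering follows the Newick order with short paths", {
  lo <- compute_leaf_ordering(quartet())
  expect_equal(lo$ordering, c("a", "b", "c", "d"))
  expect_equal(vapply(lo$paths, length, integer(1)), c(2L, 4L, 2L))
  expect_true(all(lo$edge_multiplicity <= 2L))

  lo2 <- compute_leaf_ordering(two_leaf())
  expect_equal(lo2$ordering, c("a", "b"))
  expect_length(lo2$paths, 1L)
})

test_that("every edge lies on at most two consecutive-leaf paths", {
  for (seed in c(5, 6)) {
    tr <- yule_tree(25, seed = seed)
    lo <- compute_leaf_ordering(tr)
    expect_true(all(lo$edge_multiplicity <= 2L))
    expect_setequal(lo$ordering, tr$tip.label)
  }
})

test_that("subtree products report both arc directions with zero counts", {
  tr <- quartet()
  sp <- subtree_products(tr, uniform_p(tr, 0.5))
  pend_a <- which(tr$edge[, 2L] == which(tr$tip.label == "a"))
  away_a <- sp[sp$edge == pend_a & sp$away_side == "clade", ]
  expect_equal(away_a$positive_product, 0.5)
  expect_equal(away_a$zero_count, 0)
  # factorisation: the two sides of any split multiply to the full product
  expect_equal(sp$product[sp$away_side == "clade"] *
                 sp$product[sp$away_side == "complement"],
               rep(0.5^4, nrow(tr$edge)))

  p0 <- c(a = 0, b = 0.5, c = 0.5, d = 0.5)
  sp0 <- subtree_products(tr, p0)
  away_a0 <- sp0[sp0$edge == pend_a & sp0$away_side == "clade", ]
  expect_equal(away_a0$zero_count, 1)
  expect_equal(away_a0$positive_product, 1)
  expect_equal(away_a0$product, 0)
})

test_that("scores are invariant to re-rooting and equivariant to scale", {
  tr <- yule_tree(40, seed = 55)
  p <- random_probabilities(tr$tip.label, n_zeros = 2L, seed = 56)
  sh <- shapley_linear(tr)
  he <- hed_linear(tr, p)
  tr2 <- ape::root(tr, node = 60, resolve.root = FALSE)
  expect_lt(max_rel_err(by_taxon(shapley_linear(tr2), "shapley", sh$taxon),
                        sh$shapley), 1e-9)
  expect_lt(max_rel_err(by_taxon(hed_linear(tr2, p), "hed", he$taxon),
                        he$hed), 1e-9)

  tr3 <- tr
  tr3$edge.length <- tr3$edge.length * 7.3
  expect_lt(max_rel_err(shapley_linear(tr3)$shapley, 7.3 * sh$shapley), 1e-9)
  expect_lt(max_rel_err(hed_linear(tr3, p)$hed, 7.3 * he$hed), 1e-9)
  expect_lt(max_rel_err(fair_proportion(tr3)$fp,
                        7.3 * fair_proportion(tr)$fp), 1e-9)
})

test_that("HED grows toward the pendant length as uniform p falls", {
  tr <- yule_tree(30, seed = 70)
  pend <- unname(pendant_lengths(tr))
  prev <- NULL
  for (pu in c(0.5, 0.1, 0.01)) {
    h <- hed_linear(tr, uniform_p(tr, pu))$hed
    expect_true(all(h >= pend - 1e-12))
    if (!is.null(prev)) expect_true(all(h <= prev + 1e-12))
    prev <- h
  }
})

test_that("zero-length edges are legal and contribute nothing", {
  tr <- parse_newick("((a:1,b:1):0,(c:1,d:1):0);")
  expect_equal(shapley_linear(tr)$shapley, rep(1, 4))
  expect_equal(sum(fair_proportion(tr)$fp), 4)
})

test_that("score tables export as TSV with headers", {
  tr <- quartet()
  tab <- score_tree(tr, c("fp", "shapley", "hed", "edge"),
                    p = uniform_p(tr, 0.5))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_score_table(tab, path)
  back <- utils::read.delim(path)
  expect_equal(names(back),
               c("taxon", "fp", "edge_product", "shapley", "hed",
                 "pendant_length"))
  expect_equal(back$shapley, tab$shapley, tolerance = 1e-10)
  expect_equal(back$taxon, tr$tip.label)
})
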