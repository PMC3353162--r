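test_that("a batch of identical trees has zero spread", {
  trees <- replicate(3, quartet(), simplify = FALSE)
  res <- score_batch(trees, scores = "shapley")
  expect_equal(res$n_trees, 3L)
  expect_equal(unname(res$mean[, "shapley"]), rep(1.5, 4))
  expect_equal(unname(res$sd[, "shapley"]), rep(0, 4))
})

test_that("a single-tree batch equals the single-tree scores", {
  tr <- yule_tree(20, seed = 8)
  res <- score_batch(list(tr), scores = c("fp", "shapley"))
  expect_equal(unname(res$mean[, "fp"]), fair_proportion(tr)$fp)
  expect_equal(unname(res$mean[, "shapley"]), shapley_linear(tr)$shapley)
  expect_true(all(res$sd == 0))
})

test_that("FP conservation holds for every tree of a batch", {
  trees <- lapply(1:10, function(i) yule_tree(50, seed = 600 + i))
  res <- score_batch(trees, scores = "fp", keep_per_tree = TRUE)
  sums <- vapply(seq_along(trees), function(i) {
    sum(res$per_tree[[i]]$fp)
  }, numeric(1))
  totals <- vapply(trees, total_edge_length, numeric(1))
  expect_lt(max_rel_err(sums, totals), 1e-9)
  expect_lt(max_rel_err(sum(res$mean[, "fp"]), mean(totals)), 1e-9)
})

test_that("streamed mean/SD matches a two-pass computation", {
  trees <- lapply(1:12, function(i) yule_tree(15, seed = 700 + i))
  res <- score_batch(trees, scores = "shapley")
  mat <- sapply(trees, function(tr) {
    by_taxon(shapley_linear(tr), "shapley", res$taxa)
  })
  expect_lt(max_rel_err(unname(res$mean[, "shapley"]), rowMeans(mat)), 1e-9)
  expect_lt(max_rel_err(unname(res$sd[, "shapley"]), apply(mat, 1, sd)),
            1e-9)
})

test_that("multi-tree files are scored line by line", {
  path <- withr::local_tempfile(fileext = ".nwk")
  trees <- lapply(1:4, function(i) yule_tree(12, seed = 800 + i))
  writeLines(vapply(trees, write_newick, character(1)), path)
  res <- score_batch(path, scores = "shapley")
  expect_equal(res$n_trees, 4L)
  two_pass <- rowMeans(sapply(trees, function(tr) {
    by_taxon(shapley_linear(tr), "shapley", res$taxa)
  }))
  expect_lt(max_rel_err(unname(res$mean[, "shapley"]), two_pass), 1e-9)
})

test_that("taxon-set mismatches are reported with the difference", {
  t1 <- quartet()
  t2 <- parse_newick("((a:1,b:1):1,(c:1,e:1):1);")
  expect_error(score_batch(list(t1, t2), scores = "shapley"),
               "tree 2.*only there.*\\{e\\}.*missing.*\\{d\\}")
})

test_that("intersect prunes to the common taxa with merged edges", {
  t1 <- parse_newick("((a:1,b:1):1,(c:1,d:1):1);")
  t2 <- parse_newick("(((a:1,x:1):1,b:2):1,(c:1,d:1):1);")
  res <- score_batch(list(t1, t2), scores = c("fp", "shapley"),
                     intersect = TRUE)
  expect_setequal(res$taxa, c("a", "b", "c", "d"))
  expect_equal(res$n_trees, 2L)
  # the pruned second tree keeps its a-b path length (a:1 + inner:1 + b:2)
  pruned <- ape::keep.tip(t2, c("a", "b", "c", "d"))
  expect_equal(unname(res$mean[, "fp"]),
               (fair_proportion(t1)$fp +
                  by_taxon(fair_proportion(pruned), "fp", res$taxa)) / 2)
})

test_that("batch results export with mean and sd columns", {
  trees <- lapply(1:3, function(i) yule_tree(8, seed = 900 + i))
  p <- random_probabilities(trees[[1]]$tip.label, seed = 99)
  res <- score_batch(trees, p = p, scores = c("fp", "shapley", "hed"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_batch_tsv(res, path)
  back <- utils::read.delim(path)
  expect_equal(names(back),
               c("taxon", "fp_mean", "fp_sd", "shapley_mean", "shapley_sd",
                 "hed_mean", "hed_sd", "pendant_mean"))
  expect_equal(nrow(back), 8L)
})

test_that("compare_report correlates scores and flags rank outliers", {
  tr <- basal_clade_fixture(5, 60, 50)
  res <- score_batch(list(tr), scores = c("fp", "shapley"))
  rep <- compare_report(res, top_k = 5L)
  expect_equal(dim(rep$correlations), c(3L, 3L))
  expect_equal(nrow(rep$outliers), 5L)

  # proportional scores correlate perfectly
  tab <- fair_proportion(tr)
  tab$double_fp <- tab$fp * 2
  rep2 <- compare_report(tab, pair = c("fp", "double_fp"))
  expect_equal(unname(rep2$correlations["fp", "double_fp"]), 1)

  expect_error(compare_report(fair_proportion(tr)), "two score")
  two <- score_batch(list(two_leaf()), scores = c("fp", "shapley"))
  expect_error(compare_report(two), "3 taxa")
})

test_that("HED at vanishing uniform risk tracks the pendant edge", {
  tr <- yule_tree(120, seed = 1234)
  p <- uniform_p(tr, 1e-6)
  res <- score_batch(list(tr), p = p, scores = c("fp", "hed"))
  rep <- compare_report(res, pair = c("hed", "fp"))
  r_pend <- rep$correlations["hed", "pendant_length"]
  expect_gte(r_pend, 1 - 1e-6)
  # and it tracks the pendant more tightly than FP does
  expect_gte(r_pend, rep$correlations["hed", "fp"])
})
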