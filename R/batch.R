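## Streaming multi-tree scoring and across-tree aggregation.

# A pull-based tree source: calling it yields the next phylo or NULL.
# Multi-tree Newick files are read one line (one tree) at a time so peak
# memory stays independent of the number of trees.
.tree_source <- function(trees) {
  if (is.character(trees) && length(trees) == 1L) {
    if (!file.exists(trees))
      pd_stop(paste0("tree file not found: ", trees))
    con <- file(trees, open = "r")
    done <- FALSE
    function() {
      if (done) return(NULL)
      repeat {
        line <- readLines(con, n = 1L)
        if (!length(line)) {
          close(con)
          done <<- TRUE
          return(NULL)
        }
        line <- trimws(line)
        if (nzchar(line) && !startsWith(line, "#")) return(parse_newick(line))
      }
    }
  } else if (inherits(trees, "phylo")) {
    pool <- list(trees)
    i <- 0L
    function() {
      i <<- i + 1L
      if (i > length(pool)) NULL else pool[[i]]
    }
  } else if (is.list(trees)) {
    pool <- trees
    i <- 0L
    function() {
      i <<- i + 1L
      if (i > length(pool)) NULL else validate_tree(pool[[i]])
    }
  } else {
    pd_stop("trees must be a file path, a phylo, or a list of phylo trees")
  }
}

#' Score a sample of trees and summarise across them
#'
#' Streams trees one at a time from a multi-tree Newick file (one tree per
#' line) or a list of `phylo` objects, computes the requested scores per
#' tree, and accumulates per-taxon running means and standard deviations
#' (Welford updates; the sample SD is reported, 0 when there is a single
#' tree).  All trees must share one taxon set; with `intersect = TRUE` the
#' trees are instead pruned to their common taxa (adjacent edges merged
#' with summed lengths) before scoring.
#'
#' @param trees file path, `phylo`, or list of `phylo` trees.
#' @param p extinction probabilities (required when `"hed"` or `"edge"` is
#'   requested).
#' @param scores character subset of `c("fp", "shapley", "hed", "edge")`.
#' @param intersect prune trees to the common taxon subset instead of
#'   erroring on mismatch.
#' @param keep_per_tree retain each tree's `score_table` in the result.
#' @return a `batch_result`: list with `n_trees`, `taxa`, matrices `mean`
#'   and `sd` (taxa by score, including `pendant_length`), and optionally
#'   `per_tree`.
#' @examples
#' trees <- replicate(3, yule_tree(6, seed = 7), simplify = FALSE)
#' score_batch(trees, scores = "shapley")
#' @export
score_batch <- function(trees, p = NULL, scores = "shapley",
                        intersect = FALSE, keep_per_tree = FALSE) {
  scores <- match.arg(scores, c("fp", "shapley", "hed", "edge"),
                      several.ok = TRUE)
  if (any(scores %in% c("hed", "edge")) && is.null(p))
    pd_stop("scores 'hed' and 'edge' require extinction probabilities")
  common <- NULL
  if (intersect) {
    src0 <- .tree_source(trees)
    repeat {
      tr <- src0()
      if (is.null(tr)) break
      common <- if (is.null(common)) tr$tip.label
                else intersect(common, tr$tip.label)
    }
    if (is.null(common) || length(common) < 2L)
      pd_stop("fewer than 2 taxa are shared by all trees")
  }
  src <- .tree_source(trees)
  # table column names behind each requested score
  cols <- c(ifelse(scores == "edge", "edge_product", scores),
            "pendant_length")
  taxa <- NULL
  mean_m <- sd_m <- m2 <- NULL
  k <- 0L
  per_tree <- if (keep_per_tree) list() else NULL
  repeat {
    tr <- src()
    if (is.null(tr)) break
    k <- k + 1L
    if (intersect && !setequal(tr$tip.label, common)) {
      rooted <- is_rooted_tree(tr)
      tr <- ape::keep.tip(tr, common)
      attr(tr, "rooted") <- rooted
    }
    if (is.null(taxa)) {
      taxa <- tr$tip.label
      mean_m <- matrix(0, length(taxa), length(cols),
                       dimnames = list(taxa, cols))
      m2 <- mean_m
    } else if (!setequal(tr$tip.label, taxa)) {
      only_new <- setdiff(tr$tip.label, taxa)
      only_ref <- setdiff(taxa, tr$tip.label)
      pd_stop(sprintf(
        "tree %d has a different taxon set; only there: {%s}; missing: {%s}",
        k, paste(only_new, collapse = ", "),
        paste(only_ref, collapse = ", ")))
    }
    p_tree <- p
    if (!is.null(p) && intersect) {
      pv <- if (inherits(p, "extinction_map")) unclass(p) else p
      p_tree <- pv[names(pv) %in% taxa]
    }
    tab <- score_tree(tr, scores = scores, p = p_tree)
    vals <- as.matrix(tab[match(taxa, tab$taxon), cols, drop = FALSE])
    delta <- vals - mean_m
    mean_m <- mean_m + delta / k
    m2 <- m2 + delta * (vals - mean_m)
    if (keep_per_tree) per_tree[[k]] <- tab
  }
  if (k == 0L) pd_stop("no trees in input")
  sd_m <- if (k > 1L) sqrt(m2 / (k - 1L)) else mean_m * 0
  structure(list(n_trees = k, taxa = taxa, scores = scores,
                 mean = mean_m, sd = sd_m, per_tree = per_tree),
            class = "batch_result")
}

#' @export
print.batch_result <- function(x, ...) {
  cat(sprintf("Batch of %d tree(s), %d taxa; scores: %s\n", x$n_trees,
              length(x$taxa), paste(x$scores, collapse = ", ")))
  print(utils::head(as.data.frame(x)))
  if (length(x$taxa) > 6L) cat("...\n")
  invisible(x)
}

#' @export
as.data.frame.batch_result <- function(x, ...) {
  out <- data.frame(taxon = x$taxa, stringsAsFactors = FALSE)
  for (sc in x$scores) {
    cl <- if (sc == "edge") "edge_product" else sc
    out[[paste0(sc, "_mean")]] <- unname(x$mean[, cl])
    out[[paste0(sc, "_sd")]] <- unname(x$sd[, cl])
  }
  out$pendant_mean <- unname(x$mean[, "pendant_length"])
  out
}

#' Write batch results as a tab-separated table
#'
#' Columns `taxon`, `<score>_mean`, `<score>_sd`, ..., `pendant_mean`, with
#' 12 significant digits, rows in the first tree's leaf order.
#'
#' @param result a `batch_result`.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_batch_tsv <- function(result, path) {
  out <- as.data.frame(result)
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], function(v) format(v, digits = 12, trim = TRUE))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Compare score types across a batch
#'
#' Pearson correlations among the per-taxon mean scores (and the mean
#' pendant edge length), plus the taxa whose ranks differ most between a
#' chosen pair of scores — the way outlier clades show up when two indices
#' mostly agree.
#'
#' @param result a `batch_result` (with at least two score types) or a
#'   single-tree `score_table` with at least two score columns.
#' @param pair character vector of two score names for the rank-difference
#'   listing; defaults to the first two available.
#' @param top_k number of outlier taxa to report.
#' @return a list with `correlations` (matrix), `outliers` (data frame of
#'   the top rank differences) and `pair`.
#' @export
compare_report <- function(result, pair = NULL, top_k = 10L) {
  if (inherits(result, "batch_result")) {
    vals <- result$mean
    taxa <- result$taxa
  } else if (is.data.frame(result)) {
    num <- vapply(result, is.numeric, logical(1))
    vals <- as.matrix(result[num])
    rownames(vals) <- result$taxon
    taxa <- result$taxon
  } else {
    pd_stop("compare_report() expects a batch_result or score_table")
  }
  score_cols <- setdiff(colnames(vals), "pendant_length")
  if (length(score_cols) < 2L)
    pd_stop("compare_report() needs at least two score types")
  if (length(taxa) < 3L)
    pd_stop("correlations are degenerate with fewer than 3 taxa")
  # a constant column (e.g. equal pendants on a synthetic tree) yields NA
  cors <- suppressWarnings(stats::cor(vals))
  if (is.null(pair)) pair <- score_cols[1:2]
  if (!all(pair %in% colnames(vals)))
    pd_stop(paste0("pair must name two of: ",
                   paste(colnames(vals), collapse = ", ")))
  ra <- rank(-vals[, pair[1L]])
  rb <- rank(-vals[, pair[2L]])
  ord <- order(abs(ra - rb), decreasing = TRUE)
  top <- head(ord, top_k)
  outliers <- data.frame(taxon = taxa[top],
                         rank_a = ra[top], rank_b = rb[top],
                         rank_difference = (ra - rb)[top],
                         row.names = NULL, stringsAsFactors = FALSE)
  names(outliers)[2:3] <- paste0("rank_", pair)
  list(correlations = cors, outliers = outliers, pair = pair)
}
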