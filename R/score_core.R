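## The three distinctiveness indices: fair proportion (rooted), Shapley
## value and HED (unrooted), with the linear-time arc-traversal engine for
## the latter two and independent quadratic implementations used as
## mid-scale oracles.

# Smallest extinction probability treated as genuinely positive; below it
# the division by p(x) in the HED arc form would amplify rounding error
# catastrophically, so the zero-probability route is used instead.
.TINY_P <- 1e-300

# Normalise a probability input (extinction_map or named numeric) to a
# plain numeric vector in tip order, validating coverage and range.
resolve_probs <- function(tree, p) {
  if (inherits(p, "extinction_map")) p <- unclass(p)
  if (is.null(names(p)))
    pd_stop("extinction probabilities must be named by taxon")
  names(p) <- trimws(names(p))
  if (!is.numeric(p) || anyNA(p))
    pd_stop("extinction probabilities must be numeric and non-missing")
  if (any(p < 0 | p > 1))
    pd_stop(paste0("extinction probabilities outside [0,1] for: ",
                   paste(names(p)[p < 0 | p > 1], collapse = ", ")))
  missing <- setdiff(tree$tip.label, names(p))
  if (length(missing))
    pd_stop(paste0("no extinction probability for: ",
                   paste(missing, collapse = ", ")))
  out <- unname(p[tree$tip.label])
  tiny <- out > 0 & out < .TINY_P
  if (any(tiny)) {
    pd_warn(paste0("extinction probabilities below ", .TINY_P,
                   " treated as 0 for: ",
                   paste(tree$tip.label[tiny], collapse = ", ")))
    out[tiny] <- 0
  }
  out
}

new_score_table <- function(tree, ..., update_count = NULL) {
  tab <- data.frame(taxon = tree$tip.label, ...,
                    stringsAsFactors = FALSE, row.names = NULL)
  class(tab) <- c("score_table", "data.frame")
  if (!is.null(update_count)) attr(tab, "update_count") <- update_count
  tab
}

#' Fair proportion (evolutionary distinctiveness) index
#'
#' On a rooted tree, each edge's length is shared equally among the taxa
#' descending from it; a taxon's FP score is the sum of its shares along
#' its root-to-tip path.  Summed over taxa, FP returns the total edge
#' length of the tree (excluding any root branch).
#'
#' @param tree a rooted `phylo` tree (as returned by [parse_newick()]).
#' @return a `score_table` data frame with columns `taxon`, `fp` and
#'   `pendant_length`, in the tree's tip order.
#' @examples
#' fair_proportion(parse_newick("((a:1,b:1):1,(c:1,d:1):1);"))
#' @export
fair_proportion <- function(tree) {
  validate_tree(tree)
  if (!is_rooted_tree(tree))
    pd_stop(paste0("fair_proportion() requires a rooted tree; root the ",
                   "tree (e.g. ape::root()) or parse a rooted Newick ",
                   "string first"))
  n <- length(tree$tip.label)
  nv <- n + tree$Nnode
  edge <- tree$edge
  below <- numeric(nv)
  below[seq_len(n)] <- 1
  po <- ape::reorder.phylo(tree, "postorder", index.only = TRUE)
  for (i in po) below[edge[i, 1L]] <- below[edge[i, 1L]] + below[edge[i, 2L]]
  share <- tree$edge.length / below[edge[, 2L]]
  acc <- numeric(nv)
  for (i in rev(po)) # preorder: parent before child
    acc[edge[i, 2L]] <- acc[edge[i, 1L]] + share[i]
  new_score_table(tree, fp = acc[seq_len(n)],
                  pendant_length = unname(pendant_lengths(tree)))
}

#' Shapley value of every taxon (linear time)
#'
#' The phylogenetic Shapley value: the expected marginal phylogenetic
#' diversity a taxon adds over all arrival orders of the taxa, computed on
#' the unrooted tree.  It equals, for taxon `x`, the sum over edges of
#' `|far block| / (n * |near block|) * length`, where the near block of an
#' edge's split is the one containing `x`.  The implementation evaluates
#' the first leaf of a planar leaf ordering directly and updates the
#' coefficient sums incrementally along the ordering, touching each edge at
#' most twice, so the whole score vector is obtained in linear time.
#'
#' A degree-2 root is suppressed internally (the index is defined on the
#' unrooted tree).  The attribute `update_count` on the result records the
#' instrumented number of per-edge coefficient updates in the incremental
#' phase (at most twice the number of edges).
#'
#' @param tree a `phylo` tree, rooted or unrooted.
#' @return a `score_table` with columns `taxon`, `shapley`,
#'   `pendant_length`.
#' @examples
#' shapley_linear(parse_newick("((a:1,b:1):1,(c:1,d:1):1);"))
#' @export
shapley_linear <- function(tree) {
  st <- score_struct(tree)
  res <- .shapley_vals(st)
  new_score_table(tree, shapley = res$values,
                  pendant_length = st$lambda[st$pendant_edge],
                  update_count = res$update_count)
}

.shapley_vals <- function(st) {
  n <- st$n
  s <- st$clade_size
  leaf_arc_sums(st, (n - s) / (n * s), s / (n * (n - s)))
}

#' Shapley value by direct per-taxon edge sums (quadratic time)
#'
#' Evaluates the edge-sum form of the Shapley value independently for every
#' taxon by iterating over all edges, without the incremental update
#' machinery of [shapley_linear()].  Intended as a mid-scale cross-check.
#'
#' @inheritParams shapley_linear
#' @return a `score_table` with columns `taxon`, `shapley`.
#' @export
shapley_quadratic <- function(tree) {
  validate_tree(tree)
  n <- length(tree$tip.label)
  edge <- tree$edge
  m <- nrow(edge)
  nv <- n + tree$Nnode
  below <- numeric(nv)
  below[seq_len(n)] <- 1
  po <- ape::reorder.phylo(tree, "postorder", index.only = TRUE)
  for (i in po) below[edge[i, 1L]] <- below[edge[i, 1L]] + below[edge[i, 2L]]
  s <- below[edge[, 2L]]
  lam <- tree$edge.length
  # root-to-tip ancestor edges of each taxon
  parent_edge <- integer(nv)
  parent_edge[edge[, 2L]] <- seq_len(m)
  vals <- numeric(n)
  for (x in seq_len(n)) {
    inside <- logical(m)
    v <- x
    while (parent_edge[v] != 0L) {
      inside[parent_edge[v]] <- TRUE
      v <- edge[parent_edge[v], 1L]
    }
    coef <- ifelse(inside, (n - s) / (n * s), s / (n * (n - s)))
    vals[x] <- sum(coef * lam)
  }
  new_score_table(tree, shapley = vals)
}

#' Heightened evolutionary distinctiveness (HED) in linear time
#'
#' HED is the expected marginal phylogenetic diversity a taxon adds to the
#' set of surviving taxa when every other taxon independently goes extinct
#' with its assigned probability.  In edge form, the score of taxon `x`
#' sums, over all edges, the probability that everyone between `x` and the
#' edge dies while someone beyond it survives, times the edge length.
#'
#' For taxa with positive extinction probability the score is obtained from
#' per-arc coefficients (products of extinction probabilities over the two
#' blocks of each split) via the same incremental leaf-ordering traversal
#' as [shapley_linear()], dividing the arc sum by `p(x)`.  Taxa with
#' `p(x) = 0` are handled by a dedicated coefficient set (see
#' [hed_zero_prob()]).  Probability products are maintained as
#' (zero-factor count, log-sum of positive factors) pairs, so zeros are
#' exact and long products cannot underflow.
#'
#' @param tree a `phylo` tree, rooted or unrooted.
#' @param p an [extinction_map()] or named numeric vector of extinction
#'   probabilities in `[0, 1]` covering every taxon.
#' @return a `score_table` with columns `taxon`, `hed`, `pendant_length`.
#' @examples
#' tr <- parse_newick("((a:1,b:1):1,(c:1,d:1):1);")
#' p <- setNames(rep(0.5, 4), tr$tip.label)
#' hed_linear(tr, p)
#' @export
hed_linear <- function(tree, p) {
  st <- score_struct(tree)
  pv <- resolve_probs(tree, p)
  res <- .hed_vals(st, pv)
  new_score_table(tree, hed = res$values,
                  pendant_length = st$lambda[st$pendant_edge],
                  update_count = res$update_count)
}

.hed_vals <- function(st, pv) {
  cp <- clade_prod_stats(st, pv)
  near <- .plain_prod(cp$zc, cp$ls)
  far <- .plain_prod(cp$far_zc, cp$far_ls)
  res <- leaf_arc_sums(st, near * (1 - far), far * (1 - near))
  vals <- numeric(st$n)
  posx <- pv > 0
  vals[posx] <- res$values[posx] / pv[posx]
  count <- res$update_count
  if (any(!posx)) {
    res0 <- leaf_arc_sums(st, .kappa_tilde_in(cp), .kappa_tilde_out(cp))
    vals[!posx] <- res0$values[!posx]
    count <- max(count, res0$update_count)
  }
  list(values = vals, update_count = count)
}

# Zero-probability HED coefficients: the near-side product is taken over
# the positive-probability taxa only, and is admissible only when the near
# side contains at most one zero-probability taxon (which is then the
# reference taxon itself); otherwise the coefficient is 0.  The far-side
# factor uses the plain product.
.kappa_tilde_in <- function(cp) {
  ifelse(cp$zc <= 1, exp(cp$ls), 0) * (1 - .plain_prod(cp$far_zc, cp$far_ls))
}
.kappa_tilde_out <- function(cp) {
  ifelse(cp$far_zc <= 1, exp(cp$far_ls), 0) * (1 - .plain_prod(cp$zc, cp$ls))
}

#' HED of a taxon with extinction probability zero
#'
#' The arc form of HED divides by `p(x)` and is unavailable when
#' `p(x) = 0`.  This route evaluates the dedicated zero-probability
#' coefficient set: on each arc the near-side product runs over the
#' positive-probability taxa only, and the coefficient is zeroed whenever
#' the near side contains more than one zero-probability taxon.  The result
#' equals the definitional edge form of HED for every taxon with
#' `p(x) = 0`.
#'
#' @inheritParams hed_linear
#' @param x a taxon label with `p[x] == 0`.
#' @return a single non-negative number.
#' @export
hed_zero_prob <- function(tree, p, x) {
  st <- score_struct(tree)
  pv <- resolve_probs(tree, p)
  if (!x %in% tree$tip.label)
    pd_stop(paste0("unknown taxon: ", x))
  ix <- match(x, tree$tip.label)
  if (pv[ix] > 0)
    pd_stop(paste0("hed_zero_prob() is only for taxa with p = 0; p(", x,
                   ") = ", pv[ix], " (use hed_linear())"))
  cp <- clade_prod_stats(st, pv)
  res <- leaf_arc_sums(st, .kappa_tilde_in(cp), .kappa_tilde_out(cp))
  res$values[ix]
}

#' HED by direct per-taxon edge sums (quadratic time)
#'
#' Evaluates the definitional edge form of HED independently for every
#' taxon by iterating over all edges, sharing nothing with the incremental
#' traversal of [hed_linear()].  Intended as a mid-scale cross-check.
#'
#' @inheritParams hed_linear
#' @return a `score_table` with columns `taxon`, `hed`.
#' @export
hed_quadratic <- function(tree, p) {
  validate_tree(tree)
  pv <- resolve_probs(tree, p)
  n <- length(tree$tip.label)
  edge <- tree$edge
  m <- nrow(edge)
  nv <- n + tree$Nnode
  zc <- numeric(nv); ls <- numeric(nv)
  pos <- pv > 0
  zc[seq_len(n)] <- as.numeric(!pos)
  ls[seq_len(n)] <- ifelse(pos, log(ifelse(pos, pv, 1)), 0)
  po <- ape::reorder.phylo(tree, "postorder", index.only = TRUE)
  for (i in po) {
    zc[edge[i, 1L]] <- zc[edge[i, 1L]] + zc[edge[i, 2L]]
    ls[edge[i, 1L]] <- ls[edge[i, 1L]] + ls[edge[i, 2L]]
  }
  tot_zc <- sum(!pos)
  tot_ls <- sum(ls[seq_len(n)])
  ezc <- zc[edge[, 2L]]
  els <- ls[edge[, 2L]]
  lam <- tree$edge.length
  parent_edge <- integer(nv)
  parent_edge[edge[, 2L]] <- seq_len(m)
  vals <- numeric(n)
  for (x in seq_len(n)) {
    inside <- logical(m)
    v <- x
    while (parent_edge[v] != 0L) {
      inside[parent_edge[v]] <- TRUE
      v <- edge[parent_edge[v], 1L]
    }
    # product over the block containing x, with x removed
    near_zc <- ifelse(inside, ezc, tot_zc - ezc) - as.numeric(!pos[x])
    near_ls <- ifelse(inside, els, tot_ls - els) -
      if (pos[x]) log(pv[x]) else 0
    far_zc <- ifelse(inside, tot_zc - ezc, ezc)
    far_ls <- ifelse(inside, tot_ls - els, els)
    term <- .plain_prod(near_zc, near_ls) *
      (1 - .plain_prod(far_zc, far_ls)) * lam
    vals[x] <- sum(term)
  }
  new_score_table(tree, hed = vals)
}

#' EDGE score: fair proportion times extinction probability
#'
#' Multiplies each taxon's FP score by its extinction probability, the
#' product used for Evolutionarily Distinct and Globally Endangered
#' rankings.
#'
#' @param fp_scores a `score_table` containing an `fp` column (from
#'   [fair_proportion()]).
#' @param p an [extinction_map()] or named probability vector over exactly
#'   the same taxon set.
#' @return the input table with an `edge_product` column appended.
#' @export
edge_product <- function(fp_scores, p) {
  if (!is.data.frame(fp_scores) || !all(c("taxon", "fp") %in% names(fp_scores)))
    pd_stop("fp_scores must be a score_table with columns 'taxon' and 'fp'")
  if (inherits(p, "extinction_map")) p <- unclass(p)
  if (is.null(names(p)))
    pd_stop("extinction probabilities must be named by taxon")
  names(p) <- trimws(names(p))
  extra <- setdiff(names(p), fp_scores$taxon)
  missing <- setdiff(fp_scores$taxon, names(p))
  if (length(extra) || length(missing))
    pd_stop(paste0("taxon sets differ; only in probabilities: {",
                   paste(extra, collapse = ", "), "}; only in scores: {",
                   paste(missing, collapse = ", "), "}"))
  fp_scores$edge_product <- fp_scores$fp * unname(p[fp_scores$taxon])
  fp_scores
}

#' Planar leaf ordering and consecutive-leaf paths
#'
#' The leaf sequence of a depth-first circuit of the tree as given (the
#' Newick left-to-right leaf order), together with the edge path connecting
#' each consecutive pair.  Summed over the sequence, every edge occurs in
#' at most two of these paths — the property that makes the incremental
#' score updates amortised linear.
#'
#' @param tree a `phylo` tree.
#' @return a list with elements `ordering` (taxon labels), `paths` (list of
#'   integer vectors of `tree$edge` row indices connecting consecutive
#'   leaves) and `edge_multiplicity` (per-edge path counts).
#' @export
compute_leaf_ordering <- function(tree) {
  validate_tree(tree)
  n <- length(tree$tip.label)
  edge <- tree$edge
  m <- nrow(edge)
  nv <- n + tree$Nnode
  root <- n + 1L
  fac <- factor(edge[, 1L], levels = seq_len(nv))
  rows_by_parent <- split(seq_len(m), fac)
  # Euler tour over the tree as given (no root suppression here)
  tr <- integer(2L * m)
  leaf_pos <- integer(n)
  leaf_seq <- integer(n)
  tcount <- 0L; lcount <- 0L
  sv <- integer(nv); si <- integer(nv); se <- integer(nv)
  sp <- 1L; sv[1L] <- root
  while (sp > 0L) {
    v <- sv[sp]
    i <- si[sp] + 1L
    rows <- rows_by_parent[[v]]
    if (i <= length(rows)) {
      si[sp] <- i
      r <- rows[i]
      w <- edge[r, 2L]
      tcount <- tcount + 1L; tr[tcount] <- r
      if (w <= n) {
        lcount <- lcount + 1L
        leaf_seq[lcount] <- w
        leaf_pos[lcount] <- tcount
        tcount <- tcount + 1L; tr[tcount] <- r
      } else {
        sp <- sp + 1L
        sv[sp] <- w; si[sp] <- 0L; se[sp] <- r
      }
    } else {
      if (sp > 1L) { tcount <- tcount + 1L; tr[tcount] <- se[sp] }
      sp <- sp - 1L
    }
  }
  paths <- vector("list", n - 1L)
  mult <- integer(m)
  for (i in seq_len(n - 1L)) {
    seg <- tr[(leaf_pos[i] + 1L):leaf_pos[i + 1L]]
    paths[[i]] <- seg
    mult[seg] <- mult[seg] + 1L
  }
  list(ordering = tree$tip.label[leaf_seq], paths = paths,
       edge_multiplicity = mult)
}

#' Per-arc extinction-probability products
#'
#' Every edge gives rise to two directed arcs.  For each arc this reports
#' the product of the extinction probabilities over the taxa on the side
#' the arc points away from, decomposed as (product of the strictly
#' positive factors, count of zero factors); the plain product is the
#' positive product when the zero count is 0 and exactly 0 otherwise.  The
#' clade-side values come from one rootward (postorder) sweep and the
#' opposite side from its complement against the full-set product.
#'
#' @inheritParams hed_linear
#' @return a data frame with one row per arc: `edge` (row of `tree$edge`),
#'   `away_side` (`"clade"` for the arc pointing away from the taxa below
#'   the edge, `"complement"` for its partner), `positive_product`,
#'   `zero_count`, `product`.
#' @export
subtree_products <- function(tree, p) {
  validate_tree(tree)
  pv <- resolve_probs(tree, p)
  n <- length(tree$tip.label)
  edge <- tree$edge
  nv <- n + tree$Nnode
  zc <- numeric(nv); ls <- numeric(nv)
  pos <- pv > 0
  zc[seq_len(n)] <- as.numeric(!pos)
  ls[seq_len(n)] <- ifelse(pos, log(ifelse(pos, pv, 1)), 0)
  po <- ape::reorder.phylo(tree, "postorder", index.only = TRUE)
  for (i in po) {
    zc[edge[i, 1L]] <- zc[edge[i, 1L]] + zc[edge[i, 2L]]
    ls[edge[i, 1L]] <- ls[edge[i, 1L]] + ls[edge[i, 2L]]
  }
  tot_zc <- sum(!pos)
  tot_ls <- sum(ls[seq_len(n)])
  m <- nrow(edge)
  near_zc <- zc[edge[, 2L]]; near_ls <- ls[edge[, 2L]]
  data.frame(
    edge = rep(seq_len(m), 2L),
    away_side = rep(c("clade", "complement"), each = m),
    positive_product = c(exp(near_ls), exp(tot_ls - near_ls)),
    zero_count = c(near_zc, tot_zc - near_zc),
    product = c(.plain_prod(near_zc, near_ls),
                .plain_prod(tot_zc - near_zc, tot_ls - near_ls)),
    stringsAsFactors = FALSE)
}

#' Score a single tree with any combination of indices
#'
#' Convenience wrapper assembling one `score_table` with the requested
#' columns; `fp` and `edge` require a rooted tree, `hed` and `edge` require
#' extinction probabilities.
#'
#' @param tree a `phylo` tree.
#' @param scores character subset of `c("fp", "shapley", "hed", "edge")`.
#' @param p extinction probabilities (required for `hed`/`edge`).
#' @return a `score_table` with the requested columns plus
#'   `pendant_length`.
#' @export
score_tree <- function(tree, scores = c("fp", "shapley"), p = NULL) {
  scores <- match.arg(scores, c("fp", "shapley", "hed", "edge"),
                      several.ok = TRUE)
  if (any(scores %in% c("hed", "edge")) && is.null(p))
    pd_stop("scores 'hed' and 'edge' require extinction probabilities")
  tab <- new_score_table(tree)
  counts <- integer(0)
  st <- score_struct(tree) # shared by every unrooted index below
  if ("fp" %in% scores || "edge" %in% scores) {
    fp <- fair_proportion(tree)
    tab$fp <- fp$fp
    if ("edge" %in% scores)
      tab$edge_product <- edge_product(fp, p)$edge_product
    if (!"fp" %in% scores) tab$fp <- NULL
  }
  if ("shapley" %in% scores) {
    sh <- .shapley_vals(st)
    tab$shapley <- sh$values
    counts <- c(counts, sh$update_count)
  }
  if ("hed" %in% scores) {
    he <- .hed_vals(st, resolve_probs(tree, p))
    tab$hed <- he$values
    counts <- c(counts, he$update_count)
  }
  tab$pendant_length <- st$lambda[st$pendant_edge]
  if (length(counts)) attr(tab, "update_count") <- max(counts)
  tab
}

#' Write a score table to a tab-separated file
#'
#' One row per taxon in the table's (input Newick) order, header included,
#' numbers printed with 12 significant digits.
#'
#' @param tab a `score_table` data frame.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_score_table <- function(tab, path) {
  out <- as.data.frame(tab)
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], function(v) format(v, digits = 12, trim = TRUE))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
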