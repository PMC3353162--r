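## Definitional brute-force oracles.
##
## These evaluate the subset-sum definitions of the Shapley value and HED
## literally, over all subsets of the taxon set, using a phylogenetic
## diversity routine of their own (union of leaf-to-leaf paths) so that no
## code is shared with the production scoring engine beyond the tree
## container.  They are exponential by construction and refuse trees with
## more than 12 leaves.

.ORACLE_CAP <- 12L

.check_oracle_size <- function(tree) {
  n <- length(tree$tip.label)
  if (n > .ORACLE_CAP)
    pd_stop(sprintf(
      "exhaustive oracles enumerate all subsets and accept at most %d leaves (got %d)",
      .ORACLE_CAP, n))
  n
}

# Phylogenetic diversity of every subset of the taxa, as a vector indexed
# by bitmask + 1.  PD(Y) is computed as the total length of the union of
# the edge paths from the first member of Y to every other member —
# independent of the split-counting route used elsewhere.
pd_all_subsets <- function(tree) {
  n <- .check_oracle_size(tree)
  edge <- tree$edge
  m <- nrow(edge)
  nv <- n + tree$Nnode
  # parent pointers via BFS from the root of the edge table
  parent <- integer(nv)
  parent_edge <- integer(nv)
  parent[edge[, 2L]] <- edge[, 1L]
  parent_edge[edge[, 2L]] <- seq_len(m)
  depth <- integer(nv)
  ord <- rev(ape::reorder.phylo(tree, "postorder", index.only = TRUE))
  for (i in ord) depth[edge[i, 2L]] <- depth[edge[i, 1L]] + 1L
  # edge path between two leaves by walking up to the common ancestor
  path_edges <- function(a, b) {
    ea <- integer(0); eb <- integer(0)
    while (depth[a] > depth[b]) { ea <- c(ea, parent_edge[a]); a <- parent[a] }
    while (depth[b] > depth[a]) { eb <- c(eb, parent_edge[b]); b <- parent[b] }
    while (a != b) {
      ea <- c(ea, parent_edge[a]); a <- parent[a]
      eb <- c(eb, parent_edge[b]); b <- parent[b]
    }
    c(ea, eb)
  }
  paths <- vector("list", n)
  for (a in seq_len(n)) {
    paths[[a]] <- vector("list", n)
    for (b in seq_len(n)) if (b != a) paths[[a]][[b]] <- path_edges(a, b)
  }
  lam <- tree$edge.length
  nmask <- bitwShiftL(1L, n)
  pd <- numeric(nmask)
  for (mask in seq_len(nmask - 1L)) {
    members <- which(bitwAnd(mask, bitwShiftL(1L, seq_len(n) - 1L)) != 0L)
    if (length(members) < 2L) next
    hub <- members[1L]
    used <- logical(m)
    for (b in members[-1L]) used[paths[[hub]][[b]]] <- TRUE
    pd[mask + 1L] <- sum(lam[used])
  }
  pd
}

#' Exhaustive Shapley value by subset enumeration
#'
#' Literal evaluation of the Shapley definition: for each taxon, sum over
#' all subsets containing it of the marginal phylogenetic diversity it
#' contributes, weighted by `(|Z|-1)! (n-|Z|)! / n!`.  Factorials are
#' computed exactly (they fit a double for the 12-leaf cap) and the
#' division is performed last.  Test oracle only.
#'
#' @param tree a `phylo` tree with at most 12 leaves.
#' @param x optional taxon label; if given, the single score is returned.
#' @return a named numeric vector over all taxa, or one number if `x` is
#'   given.
#' @export
shapley_exhaustive <- function(tree, x = NULL) {
  validate_tree(tree)
  n <- .check_oracle_size(tree)
  pd <- pd_all_subsets(tree)
  nmask <- bitwShiftL(1L, n)
  masks <- seq_len(nmask - 1L)
  size <- vapply(masks, function(mm) sum(
    bitwAnd(mm, bitwShiftL(1L, seq_len(n) - 1L)) != 0L), numeric(1))
  facts <- factorial(0:n)
  vals <- numeric(n)
  for (j in seq_len(n)) {
    bit <- bitwShiftL(1L, j - 1L)
    zs <- masks[bitwAnd(masks, bit) != 0L]
    k <- size[zs]
    w <- facts[k] * facts[n - k + 1L]  # (|Z|-1)! (n-|Z|)!
    vals[j] <- sum(w * (pd[zs + 1L] - pd[zs - bit + 1L])) / facts[n + 1L]
  }
  names(vals) <- tree$tip.label
  if (is.null(x)) return(vals)
  if (!x %in% tree$tip.label) pd_stop(paste0("unknown taxon: ", x))
  unname(vals[x])
}

#' Shapley value by averaging over all arrival orders
#'
#' Second, independent oracle: the marginal phylogenetic diversity each
#' taxon adds when taxa arrive in a given order, averaged over all `n!`
#' permutations.  Only practical for very small trees.
#'
#' @param tree a `phylo` tree with at most 7 leaves.
#' @return a named numeric vector over all taxa.
#' @export
shapley_permutation <- function(tree) {
  validate_tree(tree)
  n <- length(tree$tip.label)
  if (n > 7L)
    pd_stop("shapley_permutation() enumerates all n! orders; at most 7 leaves")
  pd <- pd_all_subsets(tree)
  perms <- .all_permutations(n)
  bits <- bitwShiftL(1L, seq_len(n) - 1L)
  acc <- numeric(n)
  prefix <- integer(nrow(perms))
  for (pos in seq_len(n)) {
    arriving <- perms[, pos]
    newmask <- prefix + bits[arriving]
    marg <- pd[newmask + 1L] - pd[prefix + 1L]
    for (j in seq_len(n)) acc[j] <- acc[j] + sum(marg[arriving == j])
    prefix <- newmask
  }
  setNames(acc / nrow(perms), tree$tip.label)
}

.all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- .all_permutations(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  row <- 0L
  for (j in seq_len(n)) {
    rows <- row + seq_len(nrow(sub))
    out[rows, 1L] <- j
    rest <- seq_len(n)[-j]
    out[rows, -1L] <- matrix(rest[sub], nrow(sub), n - 1L)
    row <- row + nrow(sub)
  }
  out
}

#' Exhaustive HED by subset enumeration
#'
#' Literal evaluation of the HED definition: for a taxon `x`, enumerate
#' every subset `Z` of the other taxa, weight it by the probability that
#' exactly the taxa in `Z` survive (product of survival probabilities over
#' `Z` times extinction probabilities over the rest), and accumulate the
#' marginal diversity `PD(Z + x) - PD(Z)`.  Empty products are 1 and the
#' diversity of sets of size at most one is 0.  Test oracle only.
#'
#' @param tree a `phylo` tree with at most 12 leaves.
#' @param p extinction probabilities (named vector or [extinction_map()]).
#' @param x a taxon label.
#' @return a single non-negative number.
#' @export
hed_exhaustive <- function(tree, p, x) {
  validate_tree(tree)
  n <- .check_oracle_size(tree)
  pv <- resolve_probs(tree, p)
  if (!x %in% tree$tip.label) pd_stop(paste0("unknown taxon: ", x))
  j <- match(x, tree$tip.label)
  pd <- pd_all_subsets(tree)
  nmask <- bitwShiftL(1L, n)
  # survive[mask+1] = prod over mask of (1-p); die[mask+1] = prod of p
  survive <- numeric(nmask); die <- numeric(nmask)
  survive[1L] <- 1; die[1L] <- 1
  for (mask in seq_len(nmask - 1L)) {
    low <- bitwAnd(mask, -mask)
    tip <- 1L + as.integer(round(log2(low)))
    rest <- mask - low
    survive[mask + 1L] <- survive[rest + 1L] * (1 - pv[tip])
    die[mask + 1L] <- die[rest + 1L] * pv[tip]
  }
  bit <- bitwShiftL(1L, j - 1L)
  others <- bitwAnd(nmask - 1L, bitwNot(bit))
  zs <- Filter(function(mm) bitwAnd(mm, bit) == 0L, 0:(nmask - 1L))
  zs <- as.integer(zs)
  w <- survive[zs + 1L] * die[bitwAnd(others - zs, others) + 1L]
  sum(w * (pd[zs + bit + 1L] - pd[zs + 1L]))
}

# Total weight across subsets (should be exactly 1); exposed for tests.
hed_subset_weight_total <- function(tree, p, x) {
  n <- .check_oracle_size(tree)
  pv <- resolve_probs(tree, p)
  j <- match(x, tree$tip.label)
  others <- setdiff(seq_len(n), j)
  total <- 0
  for (mask in 0:(bitwShiftL(1L, length(others)) - 1L)) {
    inZ <- bitwAnd(mask, bitwShiftL(1L, seq_along(others) - 1L)) != 0L
    total <- total + prod(1 - pv[others[inZ]]) * prod(pv[others[!inZ]])
  }
  total
}
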