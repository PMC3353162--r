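## Internal scoring structure for the linear-time arc-traversal engine.
##
## The unrooted view of a tree is materialised once per tree: a degree-2
## root is suppressed (its two incident edges merged), every remaining edge
## is given a "clade side" (the tips below it in the rooted representation),
## and an Euler tour of the tree is recorded.  Each edge corresponds to two
## directed arcs; an arc coefficient depends only on which side of the
## edge's split the reference taxon lies, so a score is two numbers per
## edge (coef_in for taxa inside the clade side, coef_out for the rest).
##
## Per-taxon scores are then: a direct evaluation for the first leaf of the
## tour, plus incremental updates along the tour — when the walk crosses an
## edge the reference taxon changes sides, contributing
## (coef_new - coef_old) * lambda.  Each edge is crossed exactly twice in
## the full tour, so the update work between the first and last leaf is at
## most 2|E|: the amortised-linearity bound.

score_struct <- function(tree) {
  validate_tree(tree)
  n <- length(tree$tip.label)
  nv <- n + tree$Nnode
  root <- n + 1L
  edge <- tree$edge
  m <- nrow(edge)

  # tips below each node (counts), postorder
  po <- ape::reorder.phylo(tree, "postorder", index.only = TRUE)
  below <- numeric(nv)
  below[seq_len(n)] <- 1
  for (i in po) below[edge[i, 1L]] <- below[edge[i, 1L]] + below[edge[i, 2L]]

  root_rows <- which(edge[, 1L] == root)
  merged <- length(root_rows) == 2L

  if (merged) {
    r1 <- root_rows[1L]; r2 <- root_rows[2L]
    c1 <- edge[r1, 2L];  c2 <- edge[r2, 2L]
    keep <- setdiff(seq_len(m), c(r1, r2))
    score_id <- integer(m)
    score_id[keep] <- seq_along(keep)
    merged_id <- length(keep) + 1L
    score_id[c(r1, r2)] <- merged_id
    m_s <- merged_id
    lambda <- c(tree$edge.length[keep],
                tree$edge.length[r1] + tree$edge.length[r2])
    clade_node <- c(edge[keep, 2L], c2)
    start <- c1
  } else {
    score_id <- seq_len(m)
    m_s <- m
    lambda <- tree$edge.length
    clade_node <- edge[, 2L]
    start <- root
  }
  clade_size <- below[clade_node]

  # per-vertex outgoing (score edge, target) adjacency in flat CSR form,
  # preserving input edge order within each vertex
  if (merged) {
    pvec <- c(edge[keep, 1L], start)
    cvec <- c(edge[keep, 2L], c2)
    svec <- c(score_id[keep], merged_id)
  } else {
    pvec <- edge[, 1L]
    cvec <- edge[, 2L]
    svec <- score_id
  }
  ordp <- order(pvec)
  fe <- svec[ordp]
  ft <- cvec[ordp]
  nkids <- tabulate(pvec, nbins = nv)
  ptr <- c(0L, cumsum(nkids))

  # Euler tour from `start`; record every arc traversal and leaf visits
  tr_e <- integer(2L * m_s)
  tr_d <- integer(2L * m_s)   # +1 entering the clade side, -1 leaving it
  leaf_order <- integer(n)
  leaf_pos <- integer(n)
  tcount <- 0L
  lcount <- 0L
  if (start <= n) { # a leaf can be the start vertex (two-leaf trees)
    lcount <- 1L
    leaf_order[1L] <- start
    leaf_pos[1L] <- 0L
  }
  sv <- integer(nv); si <- integer(nv); se <- integer(nv)
  sp <- 1L
  sv[1L] <- start; si[1L] <- 0L; se[1L] <- 0L
  while (sp > 0L) {
    v <- sv[sp]
    i <- si[sp] + 1L
    if (i <= nkids[v]) {
      si[sp] <- i
      j <- ptr[v] + i
      eid <- fe[j]
      w <- ft[j]
      tcount <- tcount + 1L
      tr_e[tcount] <- eid
      tr_d[tcount] <- 1L
      if (w <= n) {
        lcount <- lcount + 1L
        leaf_order[lcount] <- w
        leaf_pos[lcount] <- tcount
        tcount <- tcount + 1L
        tr_e[tcount] <- eid
        tr_d[tcount] <- -1L
      } else {
        sp <- sp + 1L
        sv[sp] <- w; si[sp] <- 0L; se[sp] <- eid
      }
    } else {
      if (sp > 1L) {
        tcount <- tcount + 1L
        tr_e[tcount] <- se[sp]
        tr_d[tcount] <- -1L
      }
      sp <- sp - 1L
    }
  }
  stopifnot(tcount == 2L * m_s, lcount == n)

  # edges whose clade side contains the first leaf of the tour: the
  # all-down prefix of the tour leading to it
  onpath_x1 <- if (leaf_pos[1L] > 0L) tr_e[seq_len(leaf_pos[1L])] else integer(0)

  # pendant (merged) edge of every tip
  pendant_edge <- integer(n)
  pendant_edge[edge[, 2L][edge[, 2L] <= n]] <-
    score_id[which(edge[, 2L] <= n)]

  list(tree = tree, n = n, m_s = m_s, lambda = lambda,
       clade_node = clade_node, clade_size = clade_size,
       postorder = po, below = below,
       tr_e = tr_e, tr_d = tr_d,
       leaf_order = leaf_order, leaf_pos = leaf_pos,
       onpath_x1 = onpath_x1, pendant_edge = pendant_edge,
       tip_labels = tree$tip.label,
       update_count = leaf_pos[n] - leaf_pos[1L])
}

# Evaluate, for every leaf, sum over the arcs directed away from it of
# coefficient * length.  coef_in applies to edges whose clade side contains
# the reference leaf.  Returns values in tip order plus the instrumented
# count of per-edge coefficient updates spent on the incremental phase.
leaf_arc_sums <- function(st, coef_in, coef_out) {
  lam <- st$lambda
  diff <- (coef_in - coef_out) * lam
  s1 <- sum(coef_out * lam)
  if (length(st$onpath_x1)) s1 <- s1 + sum(diff[st$onpath_x1])
  cum <- c(0, cumsum(diff[st$tr_e] * st$tr_d))
  vals <- s1 + cum[st$leaf_pos + 1L] - cum[st$leaf_pos[1L] + 1L]
  out <- numeric(st$n)
  out[st$leaf_order] <- vals
  list(values = out, update_count = st$update_count)
}

# Per-clade extinction-probability products for every score edge, kept as
# (count of zero factors, sum of logs of the positive factors) so that
# products over thousands of taxa neither underflow nor require division
# when factors are exactly zero.
clade_prod_stats <- function(st, p) {
  tree <- st$tree
  n <- st$n
  nv <- n + tree$Nnode
  edge <- tree$edge
  zc <- numeric(nv)
  ls <- numeric(nv)
  pos <- p > 0
  zc[seq_len(n)] <- as.numeric(!pos)
  ls[seq_len(n)] <- ifelse(pos, log(ifelse(pos, p, 1)), 0)
  for (i in st$postorder) {
    a <- edge[i, 1L]; b <- edge[i, 2L]
    zc[a] <- zc[a] + zc[b]
    ls[a] <- ls[a] + ls[b]
  }
  tot_zc <- sum(!pos)
  tot_ls <- sum(log(p[pos]))
  list(zc = zc[st$clade_node], ls = ls[st$clade_node],
       far_zc = tot_zc - zc[st$clade_node],
       far_ls = tot_ls - ls[st$clade_node])
}

# plain product from a (zero count, log sum) pair
.plain_prod <- function(zc, ls) ifelse(zc > 0, 0, exp(ls))
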