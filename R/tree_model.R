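## Tree container, Newick I/O, splits and phylogenetic diversity.
##
## Trees are ape "phylo" objects.  A logical attribute "rooted" records
## whether the tree carries a designated root: trees parsed from Newick are
## always rooted (the outermost pair of parentheses designates the root,
## which may have any number of children); unroot_tree() drops the
## designation.  All split-based indices ignore the rooting, suppressing a
## degree-2 root internally; fair_proportion() requires it.

#' Parse a Newick string into a phylogenetic tree
#'
#' Reads a single Newick tree with branch lengths and validates it: leaf
#' labels must be unique (after trimming surrounding whitespace and removing
#' Newick single quotes), every edge must carry a non-negative length, and
#' the tree must have at least two leaves.  Underscores in labels are
#' preserved as-is.  Internal node labels are accepted and ignored by all
#' scores.  A trailing root branch length is stored in `$root.edge` but is
#' excluded from every index and from [total_edge_length()].
#'
#' @param text a single character string containing one Newick tree.
#' @return an object of class `phylo` with attribute `rooted = TRUE`.
#' @seealso [write_newick()], [unroot_tree()]
#' @examples
#' tr <- parse_newick("((a:1,b:1):1,(c:1,d:1):1);")
#' total_edge_length(tr)
#' @export
parse_newick <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text))
    pd_stop("parse_newick() expects a single character string")
  text <- trimws(text)
  .newick_prescan(text)
  tree <- tryCatch(
    ape::read.tree(text = text),
    error = function(e) pd_stop(paste0("Newick parse failure: ", conditionMessage(e)),
                                class = "phylodist_parse_error"),
    warning = function(w) pd_stop(paste0("Newick parse failure: ", conditionMessage(w)),
                                  class = "phylodist_parse_error")
  )
  if (is.null(tree) || !inherits(tree, "phylo"))
    pd_stop("Newick parse failure: string did not yield a tree",
            class = "phylodist_parse_error")
  tree$tip.label <- clean_labels(tree$tip.label)
  validate_tree(tree)
  attr(tree, "rooted") <- TRUE
  tree
}

# Cheap structural scan so malformed strings are reported with a character
# position (ape's messages carry none).
.newick_prescan <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  depth <- 0L
  quoted <- FALSE
  semi <- NA_integer_
  for (i in seq_along(chars)) {
    ch <- chars[i]
    if (quoted) {
      if (ch == "'") quoted <- FALSE
      next
    }
    if (ch == "'") quoted <- TRUE
    else if (ch == "(") depth <- depth + 1L
    else if (ch == ")") {
      depth <- depth - 1L
      if (depth < 0L)
        pd_stop(sprintf("Newick parse failure at character %d: unmatched ')'", i),
                class = "phylodist_parse_error")
    } else if (ch == ";") { semi <- i; break }
  }
  if (quoted)
    pd_stop("Newick parse failure: unterminated quoted label",
            class = "phylodist_parse_error")
  if (is.na(semi))
    pd_stop(sprintf("Newick parse failure at character %d: missing ';'",
                    length(chars)),
            class = "phylodist_parse_error")
  if (depth != 0L)
    pd_stop(sprintf("Newick parse failure at character %d: %d unclosed '('",
                    semi, depth),
            class = "phylodist_parse_error")
  invisible(TRUE)
}

# Trim surrounding whitespace and strip Newick single quotes ('' -> ').
clean_labels <- function(labels) {
  labels <- trimws(labels)
  quoted <- grepl("^'.*'$", labels)
  labels[quoted] <- gsub("''", "'", sub("^'(.*)'$", "\\1", labels[quoted]))
  labels
}

# Shared structural validation used by every entry point taking a tree.
validate_tree <- function(tree) {
  if (!inherits(tree, "phylo"))
    pd_stop("expected a 'phylo' tree object")
  n <- length(tree$tip.label)
  if (n < 2L)
    pd_stop(sprintf("trees must have at least 2 leaves (got %d)", n))
  dup <- unique(tree$tip.label[duplicated(tree$tip.label)])
  if (length(dup))
    pd_stop(paste0("duplicate leaf label(s): ", paste(dup, collapse = ", ")))
  if (is.null(tree$edge.length))
    pd_stop("tree has no branch lengths; every edge must carry one")
  bad <- which(is.na(tree$edge.length) | is.nan(tree$edge.length))
  if (length(bad))
    pd_stop(paste0("missing branch length on the edge above ",
                   .clade_name(tree, tree$edge[bad[1L], 2L])))
  neg <- which(tree$edge.length < 0)
  if (length(neg))
    pd_stop(paste0("negative branch length (", tree$edge.length[neg[1L]],
                   ") on the edge above ",
                   .clade_name(tree, tree$edge[neg[1L], 2L])))
  invisible(tree)
}

# Human-readable name for the clade below a node (for error messages).
.clade_name <- function(tree, node) {
  n <- length(tree$tip.label)
  if (node <= n) return(paste0("leaf '", tree$tip.label[node], "'"))
  tips <- clade_tips_below(tree, node)
  paste0("the clade containing '", tree$tip.label[tips[1L]], "' (",
         length(tips), " leaves)")
}

# Tip indices below an internal node (node itself if a tip).
clade_tips_below <- function(tree, node) {
  n <- length(tree$tip.label)
  if (node <= n) return(node)
  kids <- vector("list", n + tree$Nnode)
  for (i in seq_len(nrow(tree$edge)))
    kids[[tree$edge[i, 1L]]] <- c(kids[[tree$edge[i, 1L]]], tree$edge[i, 2L])
  out <- integer(0)
  stack <- node
  while (length(stack)) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    if (v <= n) out <- c(out, v) else stack <- c(stack, rev(kids[[v]]))
  }
  out
}

#' Serialise a tree to a Newick string
#'
#' Labels containing characters with a syntactic meaning in Newick are
#' single-quoted.  `parse_newick(write_newick(tree))` reproduces the tree's
#' topology, labels and branch lengths.
#'
#' @param tree a `phylo` tree.
#' @return a single Newick string (terminated by `;`).
#' @export
write_newick <- function(tree) {
  validate_tree(tree)
  out <- tree
  needs_quote <- grepl("[][ (){},;:']", out$tip.label)
  out$tip.label[needs_quote] <-
    paste0("'", gsub("'", "''", out$tip.label[needs_quote]), "'")
  # shield quoted spaces from the writer's underscore substitution
  out$tip.label[needs_quote] <- gsub(" ", "\a", out$tip.label[needs_quote])
  out$node.label <- NULL
  gsub("\a", " ", ape::write.tree(out))
}

#' Drop the root designation of a tree
#'
#' If the root has degree 2 it is suppressed and its two incident edges are
#' merged into a single edge whose length is their sum; otherwise only the
#' root designation is dropped.  Total edge length and every leaf-set split
#' are preserved.  Two-leaf trees keep their internal degree-2 vertex as a
#' representation artefact; all quantities treat them as a single edge.
#'
#' @param tree a `phylo` tree.
#' @return the unrooted tree, with attribute `rooted = FALSE`.
#' @export
unroot_tree <- function(tree) {
  validate_tree(tree)
  n <- length(tree$tip.label)
  root <- n + 1L
  root_deg <- sum(tree$edge[, 1L] == root)
  out <- tree
  if (n > 2L && root_deg == 2L) {
    out <- ape::unroot(tree)
  }
  out$root.edge <- NULL
  attr(out, "rooted") <- FALSE
  out
}

#' Is the tree rooted?
#'
#' Reports the package's root designation: trees from [parse_newick()] are
#' rooted; [unroot_tree()] clears the flag.  Trees built elsewhere (e.g. by
#' ape) default to rooted, since a `phylo` edge table always encodes a root
#' vertex.
#'
#' @param tree a `phylo` tree.
#' @return `TRUE` or `FALSE`.
#' @export
is_rooted_tree <- function(tree) {
  flag <- attr(tree, "rooted")
  if (is.null(flag)) TRUE else isTRUE(flag)
}

#' Total edge length of a tree
#'
#' Sum of all branch lengths, excluding any root branch (`$root.edge`),
#' which is associated with no split of the taxon set.
#'
#' @param tree a `phylo` tree.
#' @return a non-negative number.
#' @export
total_edge_length <- function(tree) {
  validate_tree(tree)
  sum(tree$edge.length)
}

#' Pendant edge length of every taxon
#'
#' The length of the terminal edge attaching each leaf to the rest of the
#' unrooted tree.  If the rooted representation places a degree-2 root on
#' that edge, the two half-edges are merged (summed) first, matching the
#' unrooted view in which HED at extinction probability 0 equals the
#' pendant length.
#'
#' @param tree a `phylo` tree.
#' @return a named numeric vector in tip order.
#' @export
pendant_lengths <- function(tree) {
  st <- score_struct(tree)
  setNames(st$lambda[st$pendant_edge], tree$tip.label)
}

#' Phylogenetic diversity of a taxon subset
#'
#' The total length of the smallest subtree of the (unrooted) tree
#' connecting the given taxa: an edge is included exactly when both blocks
#' of its split contain a member of the subset.  The empty set and
#' singletons have diversity 0.  A root branch is never included.
#'
#' @param tree a `phylo` tree.
#' @param taxa character vector of taxon labels (may be empty).
#' @return a non-negative number.
#' @examples
#' tr <- parse_newick("((a:1,b:1):1,(c:1,d:1):1);")
#' phylogenetic_diversity(tr, c("a", "c"))
#' @export
phylogenetic_diversity <- function(tree, taxa) {
  validate_tree(tree)
  taxa <- unique(trimws(as.character(taxa)))
  unknown <- setdiff(taxa, tree$tip.label)
  if (length(unknown))
    pd_stop(paste0("unknown taxon in subset: ",
                   paste(unknown, collapse = ", ")))
  k <- length(taxa)
  if (k < 2L) return(0)
  n <- length(tree$tip.label)
  member <- tree$tip.label %in% taxa
  # postorder accumulation of subset counts below each edge
  cnt <- numeric(n + tree$Nnode)
  cnt[seq_len(n)] <- as.numeric(member)
  ord <- ape::reorder.phylo(tree, "postorder", index.only = TRUE)
  for (i in ord) {
    cnt[tree$edge[i, 1L]] <- cnt[tree$edge[i, 1L]] + cnt[tree$edge[i, 2L]]
  }
  below <- cnt[tree$edge[, 2L]]
  sum(tree$edge.length[below > 0 & below < k])
}

#' Split induced by an edge
#'
#' Deleting an edge bipartitions the taxon set; the block containing the
#' reference taxon is reported first.
#'
#' @param tree a `phylo` tree.
#' @param edge the row index of the edge in `tree$edge`.
#' @param x a taxon label.
#' @return a list of class `phylo_split` with elements `block` (labels of
#'   the block containing `x`), `co_block`, and their `sizes`.
#' @export
split_of_edge <- function(tree, edge, x) {
  validate_tree(tree)
  if (!is.numeric(edge) || length(edge) != 1L || edge < 1L ||
      edge > nrow(tree$edge))
    pd_stop(sprintf("edge must be a row index of tree$edge (1..%d)",
                    nrow(tree$edge)))
  if (!x %in% tree$tip.label)
    pd_stop(paste0("unknown taxon: ", x))
  below <- tree$tip.label[clade_tips_below(tree, tree$edge[edge, 2L])]
  above <- setdiff(tree$tip.label, below)
  if (x %in% below) {
    block <- below; co_block <- above
  } else {
    block <- above; co_block <- below
  }
  structure(
    list(edge = as.integer(edge), block = block, co_block = co_block,
         sizes = c(block = length(block), co_block = length(co_block))),
    class = "phylo_split")
}

#' @export
print.phylo_split <- function(x, ...) {
  cat(sprintf("Split of edge %d: {%s} | {%s}\n", x$edge,
              paste(x$block, collapse = ","),
              paste(x$co_block, collapse = ",")))
  invisible(x)
}
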