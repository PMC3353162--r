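## Generators for test inputs: Yule (pure-birth) trees, random extinction
## probabilities, and the basal-clade fixture.  All generators are pure
## functions of their parameters and seed.

#' Simulate a Yule (pure-birth) tree conditioned on its tip count
#'
#' Starting from two lineages at the root (crown start, so there is no root
#' stem), every extant lineage splits after an exponential waiting time
#' with the given birth rate; the simulation stops when `n_tips` lineages
#' exist and a final exponential epoch is appended so that every pendant
#' edge has positive length.  The result is a rooted, binary, ultrametric
#' tree with tips labelled `t1 ... tn` in left-to-right order.
#'
#' @param n_tips number of leaves (at least 2).
#' @param birth_rate positive speciation rate; time units are arbitrary
#'   (every index is scale-equivariant, so the rate only sets the scale).
#' @param seed optional integer; when given, the tree is a deterministic
#'   function of `(n_tips, birth_rate, seed)` and the caller's RNG state is
#'   left untouched.
#' @return a rooted `phylo` tree.
#' @examples
#' yule_tree(8, seed = 1)
#' @export
yule_tree <- function(n_tips, birth_rate = 1, seed = NULL) {
  n_tips <- as.integer(n_tips)
  if (is.na(n_tips) || n_tips < 2L)
    pd_stop("yule_tree() needs n_tips >= 2")
  if (!is.numeric(birth_rate) || birth_rate <= 0)
    pd_stop("yule_tree() needs a positive birth_rate")
  sim <- function() .yule_sim(n_tips, birth_rate)
  if (is.null(seed)) sim() else withr::with_seed(seed, sim())
}

.yule_sim <- function(n_tips, birth_rate) {
  n_nodes <- 2L * n_tips - 1L
  parent <- integer(n_nodes)
  btime <- numeric(n_nodes)
  split_t <- rep(NA_real_, n_nodes)
  kid1 <- integer(n_nodes)
  kid2 <- integer(n_nodes)
  # crown start: the root (node 1) splits at time 0
  split_t[1L] <- 0
  kid1[1L] <- 2L; kid2[1L] <- 3L
  parent[2L] <- 1L; parent[3L] <- 1L
  btime[2L] <- 0; btime[3L] <- 0
  nn <- 3L
  active <- c(2L, 3L)
  t <- 0
  while (length(active) < n_tips) {
    k <- length(active)
    t <- t + stats::rexp(1L, rate = birth_rate * k)
    pick <- sample.int(k, 1L)
    i <- active[pick]
    split_t[i] <- t
    c1 <- nn + 1L; c2 <- nn + 2L
    nn <- nn + 2L
    parent[c1] <- i; parent[c2] <- i
    btime[c1] <- t; btime[c2] <- t
    kid1[i] <- c1; kid2[i] <- c2
    active <- c(active[-pick], c1, c2)
  }
  t_end <- t + stats::rexp(1L, rate = birth_rate * n_tips)

  # renumber: tips 1..n in preorder visit order, internals n+1..2n-1
  edge <- matrix(0L, 2L * n_tips - 2L, 2L)
  elen <- numeric(2L * n_tips - 2L)
  newid <- integer(nn)
  tipc <- 0L
  intc <- n_tips + 1L
  newid[1L] <- intc
  erow <- 0L
  # iterative preorder with explicit child emission
  svert <- integer(nn); schild <- integer(nn)
  sp <- 1L; svert[1L] <- 1L; schild[1L] <- 0L
  while (sp > 0L) {
    v <- svert[sp]
    ci <- schild[sp] + 1L
    if (ci > 2L) { sp <- sp - 1L; next }
    schild[sp] <- ci
    w <- if (ci == 1L) kid1[v] else kid2[v]
    is_tip <- kid1[w] == 0L
    if (is_tip) {
      tipc <- tipc + 1L
      newid[w] <- tipc
    } else {
      intc <- intc + 1L
      newid[w] <- intc
    }
    erow <- erow + 1L
    edge[erow, 1L] <- newid[v]
    edge[erow, 2L] <- newid[w]
    elen[erow] <- (if (is_tip) t_end else split_t[w]) - btime[w]
    if (!is_tip) {
      sp <- sp + 1L
      svert[sp] <- w
      schild[sp] <- 0L
    }
  }
  tree <- list(edge = edge, edge.length = elen,
               tip.label = paste0("t", seq_len(n_tips)),
               Nnode = n_tips - 1L)
  class(tree) <- "phylo"
  attr(tree, "order") <- "cladewise"
  attr(tree, "rooted") <- TRUE
  tree
}

#' Random extinction probabilities for a taxon set
#'
#' Draws per-taxon extinction probabilities: `"uniform01"` draws from
#' U\[0, 1\]; `"category_sample"` draws one of the five IUCN categories
#' uniformly per taxon and maps it through `value_set`.  `n_zeros` then
#' forces exactly that many taxa (chosen at random) to probability 0,
#' exercising the zero-probability HED route.
#'
#' @param taxa character vector of taxon labels.
#' @param scheme `"uniform01"` or `"category_sample"`.
#' @param n_zeros number of taxa forced to probability zero.
#' @param value_set value set for `"category_sample"`.
#' @param seed optional integer for deterministic output.
#' @return an [extinction_map()].
#' @export
random_probabilities <- function(taxa, scheme = c("uniform01",
                                                  "category_sample"),
                                 n_zeros = 0L,
                                 value_set = builtin_value_set("isaac"),
                                 seed = NULL) {
  scheme <- match.arg(scheme)
  taxa <- as.character(taxa)
  if (!length(taxa)) pd_stop("taxa must be non-empty")
  n_zeros <- as.integer(n_zeros)
  if (is.na(n_zeros) || n_zeros < 0L || n_zeros > length(taxa))
    pd_stop(sprintf("n_zeros must be between 0 and %d", length(taxa)))
  draw <- function() {
    p <- switch(scheme,
      uniform01 = stats::runif(length(taxa)),
      category_sample = unname(
        value_set$values[sample(names(value_set$values), length(taxa),
                                replace = TRUE)]))
    if (n_zeros > 0L) p[sample.int(length(taxa), n_zeros)] <- 0
    extinction_map(setNames(p, taxa),
                   provenance = if (scheme == "uniform01") "direct"
                                else "category-mapped",
                   value_set_name = if (scheme == "uniform01") "custom"
                                    else value_set$name)
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Basal-clade fixture tree
#'
#' A rooted tree whose root joins a small clade of `k_basal` tips and a
#' large balanced clade of `n_rest` tips through two long stem edges —
#' the configuration of a species-poor sister group attached at the root
#' of a species-rich tree (as with the monotremes in mammals).  Members of
#' the small clade receive Shapley values above their fair proportion
#' scores because the stem between the groups contributes to the unrooted
#' Shapley sum but not to their rooted root-to-tip FP paths.
#'
#' @param k_basal number of tips in the small basal clade (at least 1).
#' @param n_rest number of tips in the large clade (at least 3).
#' @param stem_length length of each of the two stem edges.
#' @return a rooted `phylo` tree with tips `basal1..` and `rest1..`; all
#'   non-stem edges have length 1.
#' @export
basal_clade_fixture <- function(k_basal, n_rest, stem_length = 50) {
  k_basal <- as.integer(k_basal)
  n_rest <- as.integer(n_rest)
  if (is.na(k_basal) || k_basal < 1L) pd_stop("k_basal must be >= 1")
  if (is.na(n_rest) || n_rest < 3L) pd_stop("n_rest must be >= 3")
  if (!is.numeric(stem_length) || stem_length <= 0)
    pd_stop("stem_length must be positive")
  balanced <- function(labels) {
    if (length(labels) == 1L) return(labels)
    half <- ceiling(length(labels) / 2)
    paste0("(", balanced(labels[seq_len(half)]), ":1,",
           balanced(labels[-seq_len(half)]), ":1)")
  }
  left <- paste0(balanced(paste0("basal", seq_len(k_basal))), ":",
                 stem_length)
  right <- paste0(balanced(paste0("rest", seq_len(n_rest))), ":",
                  stem_length)
  parse_newick(paste0("(", left, ",", right, ");"))
}
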