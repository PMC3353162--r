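# Shared fixtures and comparison helpers; everything is built in code.

quartet <- function() parse_newick("((a:1,b:1):1,(c:1,d:1):1);")

two_leaf <- function() parse_newick("(a:1,b:2);")

caterpillar <- function() parse_newick("(((a:1,b:1):1,c:2):1,d:3);")

# largest relative discrepancy, with an absolute floor near zero
max_rel_err <- function(a, b) {
  max(abs(a - b) / pmax(abs(a), abs(b), 1e-12))
}

uniform_p <- function(tree, value) {
  stats::setNames(rep(value, length(tree$tip.label)), tree$tip.label)
}

# a tree's scores reordered to a reference label order
by_taxon <- function(tab, column, taxa) {
  tab[[column]][match(taxa, tab$taxon)]
}
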