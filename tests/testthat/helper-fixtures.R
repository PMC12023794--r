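# Shared fixtures and independent oracles used across the suite.

# three-tip example tree used by the cophenetic/covariance oracles
toy_tree <- function() ape::read.tree(text = "((A:1,B:1):1,C:2);")

# balanced four-taxon tree for explicit-matrix regression oracles
quartet_tree <- function() {
  ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
}

# hand-built curation fixture: 6 passing records plus exactly one designed
# failure per quality rule (site, completeness, contamination, single-copy,
# coding), enumerated by hand before the filter was written
curation_fixture <- function() {
  pass <- function(id, species = paste0("sp_", id), habitat = "fungi") {
    data.frame(genome_id = id, habitat = habitat, host_type = "host_associated",
               species = species, isolation_site_known = TRUE,
               completeness = 98, contamination = 1, single_copy_hits = 90L,
               coding_fraction = 90, stringsAsFactors = FALSE)
  }
  recs <- do.call(rbind, lapply(sprintf("ok%02d", 1:6), pass))
  f_site <- pass("f_site"); f_site$isolation_site_known <- FALSE
  f_comp <- pass("f_comp"); f_comp$completeness <- 94.9
  f_cont <- pass("f_cont"); f_cont$contamination <- 5.1
  f_scg <- pass("f_scg"); f_scg$single_copy_hits <- 82L
  f_cod <- pass("f_cod"); f_cod$coding_fraction <- 84.9
  rbind(recs, f_site, f_comp, f_cont, f_scg, f_cod)
}

# exhaustive upper-tail hypergeometric probability: enumerate every size-n
# subset of N genomes (the first K carry the gene) and count those with at
# least k carriers
enum_hyper_upper <- function(N, K, n, k) {
  subsets <- utils::combn(N, n)
  carriers <- colSums(subsets <= K)
  mean(carriers >= k)
}

# patristic distances by explicit shortest paths on the tree graph,
# independent of any cophenetic routine
graph_patristic <- function(tree) {
  g <- igraph::graph_from_edgelist(apply(tree$edge, 2, as.character),
                                   directed = FALSE)
  igraph::E(g)$weight <- tree$edge.length
  n <- length(tree$tip.label)
  d <- igraph::distances(g, v = as.character(seq_len(n)),
                         to = as.character(seq_len(n)))
  dimnames(d) <- list(tree$tip.label, tree$tip.label)
  d
}

# brute-force silhouette widths straight from the definition
brute_silhouette <- function(m, labels) {
  n <- nrow(m)
  vapply(seq_len(n), function(i) {
    mine <- labels == labels[i]
    if (sum(mine) == 1L) return(0)
    a <- mean(m[i, mine & seq_len(n) != i])
    b <- min(vapply(setdiff(unique(labels), labels[i]), function(g)
      mean(m[i, labels == g]), numeric(1)))
    (b - a) / max(a, b)
  }, numeric(1))
}

# tip labels descending from the first child of the root
root_child_tips <- function(tree) {
  root <- length(tree$tip.label) + 1L
  kid <- tree$edge[tree$edge[, 1L] == root, 2L][1L]
  if (kid <= length(tree$tip.label)) tree$tip.label[kid]
  else ape::extract.clade(tree, kid)$tip.label
}

# tiny union-find giving connected components of a pair list
uf_components <- function(ids, pairs) {
  parent <- stats::setNames(ids, ids)
  find <- function(x) { while (parent[[x]] != x) x <- parent[[x]]; x }
  for (r in seq_len(nrow(pairs))) {
    a <- find(pairs[r, 1L]); b <- find(pairs[r, 2L])
    if (a != b) parent[[a]] <- b
  }
  split(ids, vapply(ids, find, character(1)))
}
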