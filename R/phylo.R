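# Tree-derived quantities and genome clustering: cophenetic (patristic)
# distances, the Brownian-motion covariance used by the phylogenetic
# regression, agglomerative clustering of genomes, and silhouette/gap-based
# selection of the number of clusters.

check_tree <- function(tree) {
  if (!inherits(tree, "phylo")) abort_fmt("`tree` must be an ape phylo object")
  if (is.null(tree$tip.label) || anyDuplicated(tree$tip.label)) {
    abort_fmt("tree tips must be uniquely labelled")
  }
  if (!is.null(tree$edge.length) && any(tree$edge.length < 0)) {
    abort_fmt("tree has negative branch lengths")
  }
  invisible(tree)
}

#' Cophenetic (patristic) distance matrix of a tree
#'
#' Entry (i, j) is the sum of branch lengths on the unique path between
#' tips i and j.
#'
#' @param tree `ape::phylo` tree with >= 2 uniquely labelled tips.
#' @return Symmetric numeric matrix with tip labels as dimnames.
#' @examples
#' cophenetic_distances(ape::read.tree(text = "((A:1,B:1):1,C:2);"))
#' @export
cophenetic_distances <- function(tree) {
  check_tree(tree)
  if (length(tree$tip.label) < 2L) abort_fmt("tree must have >= 2 tips")
  ape::cophenetic.phylo(tree)
}

#' Brownian-motion covariance matrix of a rooted tree
#'
#' `V[i, j]` is the depth (root-to-node path length) of the most recent
#' common ancestor of tips i and j: the covariance of a unit-rate Brownian
#' motion evolving along the tree. For ultrametric trees of height `h`,
#' `2 * (h - V[i, j])` equals the cophenetic distance.
#'
#' @param tree Rooted `ape::phylo` tree.
#' @return Symmetric positive semi-definite matrix, tip labels as dimnames.
#' @export
bm_covariance <- function(tree) {
  check_tree(tree)
  # star topologies (a single root node) are rooted by construction
  if (!ape::is.rooted(tree) && tree$Nnode > 1L) {
    abort_fmt("tree must be rooted")
  }
  ape::vcv(tree)
}

check_dist_matrix <- function(dist) {
  if (inherits(dist, "dist")) dist <- as.matrix(dist)
  if (!is.matrix(dist) || nrow(dist) != ncol(dist)) {
    abort_fmt("`dist` must be a square matrix or dist object")
  }
  if (max(abs(dist - t(dist))) > 1e-8 || any(abs(diag(dist)) > 1e-8)) {
    abort_fmt("`dist` must be symmetric with zero diagonal")
  }
  if (is.null(rownames(dist))) {
    rownames(dist) <- colnames(dist) <- paste0("s", seq_len(nrow(dist)))
  }
  dist
}

#' Agglomerative clustering of genomes from a distance matrix
#'
#' @param dist Symmetric distance matrix (or `dist`) over genomes.
#' @param k Number of clusters, `1 <= k <= n`.
#' @param linkage Agglomeration rule: `"complete"` (default), `"average"`,
#'   or `"single"`.
#' @return Object of class `cluster_assignment`: list with `labels` (named
#'   integer vector in `1..k`), `k`, `silhouette` (per genome; 0 for
#'   singleton clusters, `NA` when `k` is 1 or n), `mean_silhouette`, and
#'   the `hclust` tree.
#' @export
hierarchical_cluster <- function(dist, k,
                                 linkage = c("complete", "average", "single")) {
  linkage <- match.arg(linkage)
  m <- check_dist_matrix(dist)
  n <- nrow(m)
  check_scalar_number(k, "k", min = 1)
  if (k > n) abort_fmt("k (%d) exceeds number of genomes (%d)", k, n)
  hc <- stats::hclust(stats::as.dist(m), method = linkage)
  labels <- stats::cutree(hc, k = k)
  sil <- silhouette_widths(m, labels)
  structure(list(labels = labels, k = as.integer(k), silhouette = sil,
                 mean_silhouette = if (all(is.na(sil))) NA_real_
                                   else mean(sil),
                 hclust = hc, linkage = linkage),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("Hierarchical clustering (%s linkage): k = %d, sizes: %s\n",
              x$linkage, x$k,
              paste(tabulate(x$labels, x$k), collapse = ", ")))
  if (!is.na(x$mean_silhouette)) {
    cat(sprintf("  mean silhouette: %.3f\n", x$mean_silhouette))
  }
  invisible(x)
}

# per-sample silhouette widths; singleton clusters get 0 by convention,
# NA vector when k == 1 or k == n makes no between/within contrast
silhouette_widths <- function(m, labels) {
  n <- nrow(m)
  k <- length(unique(labels))
  if (k < 2L || k >= n) return(rep(NA_real_, n))
  sil <- cluster::silhouette(as.integer(factor(labels)), dmatrix = m)
  out <- sil[, "sil_width"]
  sizes <- table(labels)
  out[sizes[as.character(labels)] == 1L] <- 0
  unname(out)
}

#' Select the number of clusters by silhouette (with gap diagnostics)
#'
#' Clusters the genomes at each `k` in `k_min:k_max`, computes the mean
#' silhouette width (singletons counted as 0), and returns the `k`
#' maximizing it. A gap statistic is reported for diagnostics: the data
#' are embedded by principal coordinates, reference datasets are drawn
#' uniformly from the embedding's bounding box, and
#' `gap(k) = mean_b log W_k(ref_b) - log W_k` with `W_k` the sum over
#' clusters of mean within-cluster squared distances.
#'
#' @inheritParams hierarchical_cluster
#' @param k_min,k_max Range of cluster numbers examined
#'   (`2 <= k_min < k_max <= n - 1`).
#' @param n_ref Number of gap-statistic reference datasets.
#' @param seed Optional integer seed for the gap reference draws.
#' @return List with `k_best`, `silhouette` (named per-k mean widths),
#'   `gap` (named per-k gap values), and the `cluster_assignment` at
#'   `k_best`.
#' @export
select_k <- function(dist, k_min = 2, k_max = 10,
                     linkage = c("complete", "average", "single"),
                     n_ref = 20, seed = NULL) {
  linkage <- match.arg(linkage)
  m <- check_dist_matrix(dist)
  n <- nrow(m)
  if (all(m == 0)) abort_fmt("all distances are zero; clustering is degenerate")
  k_max <- min(k_max, n - 1L)
  if (!(k_min >= 2 && k_min < k_max)) {
    abort_fmt("need 2 <= k_min < k_max <= n - 1")
  }
  ks <- seq(k_min, k_max)
  hc <- stats::hclust(stats::as.dist(m), method = linkage)
  sil <- vapply(ks, function(k) {
    lab <- stats::cutree(hc, k = k)
    mean(silhouette_widths(m, lab))
  }, numeric(1))
  names(sil) <- ks

  # gap statistic in PCoA space with a uniform bounding-box reference
  wk <- function(dm, lab) {
    sum(vapply(split(seq_len(nrow(dm)), lab), function(ix) {
      if (length(ix) < 2L) return(0)
      sum(dm[ix, ix]^2) / (2 * length(ix))
    }, numeric(1)))
  }
  obs_w <- vapply(ks, function(k) wk(m, stats::cutree(hc, k = k)), numeric(1))
  emb <- suppressWarnings(stats::cmdscale(stats::as.dist(m),
                                          k = min(n - 1L, 10L)))
  gap <- with_seed(seed, {
    ref_w <- matrix(NA_real_, n_ref, length(ks))
    for (b in seq_len(n_ref)) {
      ref <- apply(emb, 2, function(col)
        stats::runif(n, min(col), max(col)))
      dref <- as.matrix(stats::dist(ref))
      hr <- stats::hclust(stats::as.dist(dref), method = linkage)
      ref_w[b, ] <- vapply(ks, function(k) wk(dref, stats::cutree(hr, k = k)),
                           numeric(1))
    }
    colMeans(log(pmax(ref_w, .Machine$double.xmin))) -
      log(pmax(obs_w, .Machine$double.xmin))
  })
  names(gap) <- ks
  k_best <- ks[which.max(sil)]
  list(k_best = k_best, silhouette = sil, gap = gap,
       assignment = hierarchical_cluster(m, k_best, linkage))
}
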