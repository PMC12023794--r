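# Habitat-association scoring of gene orthologs: upper-tail hypergeometric
# tests of presence/absence, odds ratios with one-sided Fisher p-values,
# counts-per-thousand-genomes normalization, and calling of
# habitat-specific genes by the disjunction of the two FDR-corrected tests.

check_margins <- function(N, K, n, k) {
  ok <- N >= 0 & K >= 0 & n >= 0 & k >= 0 & K <= N & n <= N &
    k <= pmin(n, K) & k >= pmax(0, n + K - N)
  if (!all(ok)) abort_fmt("inconsistent hypergeometric margins (N=%s, K=%s, n=%s, k=%s)",
                          N[!ok][1], K[!ok][1], n[!ok][1], k[!ok][1])
}

#' Upper-tail hypergeometric test
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: the probability of
#' observing at least `k` gene-carrying genomes in a habitat of `n`
#' genomes, when `K` of all `N` genomes carry the gene. Computed in
#' log-space so the score stays finite for extreme enrichment.
#'
#' @param N Total genomes. @param K Genomes carrying the gene.
#' @param n Genomes in the habitat. @param k Carriers in the habitat.
#'   All vectorized.
#' @return List with `p_upper` and `score = -log10(p_upper)`.
#' @examples
#' hypergeom_test(10, 4, 5, 4)  # 6/252
#' @export
hypergeom_test <- function(N, K, n, k) {
  check_margins(N, K, n, k)
  logp <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE, log.p = TRUE)
  list(p_upper = exp(logp), score = -logp / log(10))
}

#' Odds ratio and one-sided Fisher test of habitat association
#'
#' Forms the 2x2 table `[[k, n-k], [K-k, (N-n)-(K-k)]]` of gene presence
#' in and out of a habitat. The sample odds ratio gets the
#' Haldane-Anscombe +0.5 correction only when some cell is zero. The
#' one-sided (overrepresentation) Fisher exact p equals the upper-tail
#' hypergeometric probability on the same margins.
#'
#' @inheritParams hypergeom_test
#' @return List with `odds_ratio`, `fisher_p`, and the `table` cells
#'   (`a`, `b`, `c`, `d`), all vectorized.
#' @export
odds_ratio_test <- function(N, K, n, k) {
  check_margins(N, K, n, k)
  a <- k; b <- n - k; c <- K - k; d <- (N - n) - (K - k)
  zero <- a == 0 | b == 0 | c == 0 | d == 0
  or <- ifelse(zero,
               ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c + 0.5)),
               a * d / (b * c))
  list(odds_ratio = or,
       fisher_p = hypergeom_test(N, K, n, k)$p_upper,
       a = a, b = b, c = c, d = d)
}

#' Counts per thousand genomes
#'
#' Normalizes per-habitat gene (or category) counts by habitat sample
#' size: `CPT = 1000 * count / n_genomes`.
#'
#' @param counts_by_habitat Numeric matrix (genes or categories x
#'   habitats) or vector of counts.
#' @param n_genomes_by_habitat Positive genome counts, one per habitat
#'   (recycled across rows of a matrix).
#' @return Same shape as `counts_by_habitat`.
#' @export
cpt_transform <- function(counts_by_habitat, n_genomes_by_habitat) {
  if (any(n_genomes_by_habitat <= 0)) {
    abort_fmt("every habitat must have > 0 genomes")
  }
  if (is.matrix(counts_by_habitat)) {
    if (length(n_genomes_by_habitat) != ncol(counts_by_habitat)) {
      abort_fmt("one genome count per habitat column is required")
    }
    sweep(counts_by_habitat, 2, n_genomes_by_habitat, function(x, n)
      1000 * x / n)
  } else {
    1000 * counts_by_habitat / n_genomes_by_habitat
  }
}

#' Habitat association of every gene
#'
#' Builds presence/absence profiles (a gene is present in a genome when
#' its count is at least `presence_min`), runs the hypergeometric and
#' odds-ratio tests per gene and habitat, and FDR-corrects within each
#' habitat across genes.
#'
#' @param counts Genes x genomes count matrix.
#' @param habitats Named habitat vector over the genomes.
#' @param presence_min Minimum count for presence (default 1).
#' @return Data frame with one row per gene x habitat: `gene`, `habitat`,
#'   `N`, `K`, `n`, `k`, `hyper_p`, `hyper_score`, `odds_ratio`,
#'   `fisher_p`, `q_hyper`, `q_fisher`.
#' @export
associate_genes <- function(counts, habitats, presence_min = 1) {
  counts <- as.matrix(counts)
  if (!all(colnames(counts) %in% names(habitats))) {
    abort_fmt("habitats must cover all genomes in counts")
  }
  habitats <- habitats[colnames(counts)]
  pres <- counts >= presence_min
  N <- ncol(counts)
  K <- rowSums(pres)
  habs <- sort(unique(unname(habitats)))
  out <- lapply(habs, function(h) {
    in_h <- habitats == h
    n <- sum(in_h)
    k <- rowSums(pres[, in_h, drop = FALSE])
    ht <- hypergeom_test(N, K, n, k)
    ot <- odds_ratio_test(N, K, n, k)
    data.frame(gene = rownames(counts), habitat = h, N = N, K = K,
               n = n, k = k, hyper_p = ht$p_upper, hyper_score = ht$score,
               odds_ratio = ot$odds_ratio, fisher_p = ot$fisher_p,
               q_hyper = bh_fdr(ht$p_upper), q_fisher = bh_fdr(ot$fisher_p),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Call habitat-specific genes
#'
#' A gene is specific to a habitat when either FDR-corrected test falls
#' below `alpha` (`q_hyper < alpha` or `q_fisher < alpha`).
#'
#' @param results Data frame from [associate_genes()].
#' @param alpha Significance threshold on the q-values.
#' @return List with `specific` (the input rows flagged, plus a `specific`
#'   column), `sets` (per-habitat character vectors of specific genes),
#'   and `overlap` (matrix counting genes shared between habitat sets).
#' @export
call_specific_genes <- function(results, alpha = 0.05) {
  need <- c("gene", "habitat", "q_hyper", "q_fisher")
  if (!all(need %in% names(results))) {
    abort_fmt("results must carry columns %s", paste(need, collapse = ", "))
  }
  results$specific <- results$q_hyper < alpha | results$q_fisher < alpha
  sets <- lapply(split(results, results$habitat),
                 function(d) d$gene[d$specific])
  habs <- names(sets)
  overlap <- matrix(0L, length(habs), length(habs),
                    dimnames = list(habs, habs))
  for (i in seq_along(habs)) for (j in seq_along(habs)) {
    overlap[i, j] <- length(intersect(sets[[i]], sets[[j]]))
  }
  list(specific = results, sets = sets, overlap = overlap)
}
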