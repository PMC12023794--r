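# Simulation studies that validate the pipeline's statistical properties
# on synthetic data with known ground truth. These are the package's own
# benchmarks: each returns the quantities a user would inspect to convince
# themselves the method behaves as claimed at desk scale.

#' Type-I error of the phylogenetic regression under clade confounding
#'
#' Simulates a null dataset (no habitat effects) whose habitats are whole
#' clades — the worst case for shared-ancestry confounding — standardizes
#' the counts, and fits every gene against the first habitat's one-vs-rest
#' contrast twice: with the phylogenetic model (Pagel's lambda by grid ML)
#' and with naive OLS (identity covariance). Returns both rejection rates
#' at `alpha`; a calibrated method stays near `alpha` while OLS inflates.
#'
#' @param n_genomes,n_genes Size of the null simulation.
#' @param alpha Nominal level.
#' @param seed Integer seed.
#' @return List: `rej_phylo`, `rej_ols`, `alpha`, `n_genes`, and the 99%
#'   binomial confidence band `band` around `alpha`.
#' @export
calibration_study <- function(n_genomes = 200, n_genes = 500, alpha = 0.05,
                              seed = 1L) {
  tr <- simulate_tree(n_genomes, seed = seed)
  hab <- assign_habitats(tr, 5, "clade_confounded")
  sim <- simulate_gene_counts(tr, hab, n_genes, seed = seed + 1L)
  z <- t(standardize_counts(sim$counts)$z)
  V <- bm_covariance(tr)
  X <- cbind(1, as.numeric(hab[tr$tip.label] == hab[[1L]]))
  ml <- phylo_lm_many(z, X, V, lambda = "ml")
  ols <- phylo_lm_many(z, X, diag(n_genomes), lambda = "fixed")
  half <- stats::qnorm(0.995) * sqrt(alpha * (1 - alpha) / ncol(z))
  list(rej_phylo = mean(ml$p[2L, ] < alpha),
       rej_ols = mean(ols$p[2L, ] < alpha),
       alpha = alpha, n_genes = ncol(z),
       band = c(alpha - half, alpha + half))
}

#' Recovery of planted habitat effects
#'
#' Plants a `+effect` log-link habitat effect on one gene, fits the
#' phylogenetic regression on the raw counts, and compares the estimated
#' habitat contrast with the closed-form model-implied mean-count
#' difference `exp(mu + sigma2 H / 2) (exp(effect) - 1)` (H the tree
#' height). Repeated over `n_seeds` independent simulations.
#'
#' @param n_seeds Number of replicates.
#' @param n_genomes Genomes per replicate.
#' @param effect Planted log-link effect.
#' @param seed Base integer seed.
#' @return List: `sign_rate` (fraction of replicates with the correct
#'   sign), `mean_ratio` (mean estimated/true effect), `ratios`.
#' @export
effect_recovery_study <- function(n_seeds = 100, n_genomes = 200,
                                  effect = 2, seed = 1L) {
  mu <- log(5); s2 <- 0.05
  ratios <- vapply(seq_len(n_seeds), function(i) {
    tr <- simulate_tree(n_genomes, seed = seed + 3L * i)
    hab <- assign_habitats(tr, 5, "random", seed = seed + 3L * i + 1L)
    et <- data.frame(gene = 1, habitat = "fungi", effect = effect)
    sim <- simulate_gene_counts(tr, hab, 1, mu, s2, et,
                                seed = seed + 3L * i + 2L)
    V <- bm_covariance(tr)
    truth <- exp(mu + s2 * max(diag(V)) / 2) * (exp(effect) - 1)
    X <- cbind(1, as.numeric(hab[tr$tip.label] == "fungi"))
    unname(stats::coef(phylo_lm(sim$counts[1L, tr$tip.label], X, V))[2L]) /
      truth
  }, numeric(1))
  list(sign_rate = mean(ratios > 0), mean_ratio = mean(ratios),
       ratios = ratios)
}

#' Dereplication of planted near-clone genomes
#'
#' Simulates datasets with injected near-clones and checks that curation
#' keeps exactly one representative per clone group.
#'
#' @param n_seeds Number of replicate datasets.
#' @param n_genomes,n_clones Dataset size and clones per dataset.
#' @param seed Base integer seed.
#' @return List: `group_success` (fraction of clone groups reduced to one
#'   representative), `dataset_success` (fraction of datasets fully
#'   correct).
#' @export
dedup_study <- function(n_seeds = 50, n_genomes = 40, n_clones = 4,
                        seed = 1L) {
  ok_groups <- 0L; n_groups <- 0L; ok_sets <- 0L
  for (i in seq_len(n_seeds)) {
    ds <- simulate_dataset(sim_config(n_tips = n_genomes, n_genes = 20,
                                      n_duplicates = n_clones,
                                      seed = seed + i))
    cur <- curate_genomes(ds$records, ds$ani_pairs, seed = seed + i)
    hits <- vapply(seq_len(nrow(ds$truth$duplicates)), function(r) {
      pair <- unlist(ds$truth$duplicates[r, c("source", "clone")])
      sum(pair %in% cur$kept$genome_id) == 1L
    }, logical(1))
    ok_groups <- ok_groups + sum(hits)
    n_groups <- n_groups + length(hits)
    ok_sets <- ok_sets + all(hits)
  }
  list(group_success = ok_groups / n_groups,
       dataset_success = ok_sets / n_seeds)
}

#' PERMANOVA calibration and power on gene-content dissimilarities
#'
#' Null: one count matrix without habitat structure, labels redrawn
#' `n_reps` times (labels are exchangeable under the null), p-values
#' collected — their mean should be near 0.5. Power: a strongly separated
#' two-habitat simulation, where the permutation p must reach its floor
#' `1 / (n_perm + 1)`.
#'
#' @param n_reps Null replicates.
#' @param n_genomes,n_genes Null dataset size.
#' @param n_perm_null,n_perm_power Permutation counts.
#' @param seed Base integer seed.
#' @return List: `mean_null_p`, `null_p` (vector), `power_p`,
#'   `power_floor`.
#' @export
permanova_calibration_study <- function(n_reps = 500, n_genomes = 30,
                                        n_genes = 40, n_perm_null = 199,
                                        n_perm_power = 999, seed = 1L) {
  tr <- simulate_tree(n_genomes, seed = seed)
  hab0 <- assign_habitats(tr, 2, "random", seed = seed + 1L,
                          weights = c(1, 1))
  sim <- simulate_gene_counts(tr, hab0, n_genes, bm_sigma2 = 0,
                              seed = seed + 2L)
  d <- bray_curtis(sim$counts)
  ids <- colnames(sim$counts)
  null_p <- with_seed(seed + 3L, vapply(seq_len(n_reps), function(i) {
    lab <- stats::setNames(sample(rep(c("a", "b"), length.out =
                                        length(ids))), ids)
    permanova_dbrda(d, lab, n_perm = n_perm_null,
                    seed = sample.int(2^30, 1))$p
  }, numeric(1)))

  et <- data.frame(gene = seq_len(n_genes %/% 2), habitat = "fungi",
                   effect = 1.5)
  hab2 <- assign_habitats(tr, 2, "random", seed = seed + 4L,
                          weights = c(1, 1))
  sim2 <- simulate_gene_counts(tr, hab2, n_genes, bm_sigma2 = 0,
                               effect_table = et, seed = seed + 5L)
  d2 <- bray_curtis(sim2$counts)
  power <- permanova_dbrda(d2, hab2, n_perm = n_perm_power,
                           seed = seed + 6L)
  list(mean_null_p = mean(null_p), null_p = null_p, power_p = power$p,
       power_floor = 1 / (n_perm_power + 1))
}

#' Recovery of the planted number of clades by silhouette selection
#'
#' Simulates trees of `n_clades` well-separated clades (between-to-within
#' cophenetic ratio `separation`) and checks how often [select_k()] picks
#' the planted number.
#'
#' @param n_seeds Number of replicate trees.
#' @param n_clades,tips_per_clade,separation Planted geometry.
#' @param seed Base integer seed.
#' @return List: `recovery_rate`, `k_hat` (vector of selected k).
#' @export
cluster_recovery_study <- function(n_seeds = 100, n_clades = 4,
                                   tips_per_clade = 15, separation = 5,
                                   seed = 1L) {
  k_hat <- vapply(seq_len(n_seeds), function(i) {
    tr <- simulate_clustered_tree(n_clades, tips_per_clade, separation,
                                  seed = seed + i)
    d <- cophenetic_distances(tr)
    select_k(d, 2, 8, n_ref = 5, seed = seed + i)$k_best
  }, numeric(1))
  list(recovery_rate = mean(k_hat == n_clades), k_hat = k_hat)
}

#' Maximum deviation of the hypergeometric tail from exhaustive enumeration
#'
#' Enumerates every size-`n` genome subset for all margins with
#' `N <= n_max` and compares the enumerated upper-tail probability with
#' [hypergeom_test()].
#'
#' @param n_max Largest population size enumerated.
#' @return List: `max_abs_error`, `n_margins` (number of margin
#'   combinations checked).
#' @export
hypergeom_enumeration_check <- function(n_max = 12) {
  worst <- 0; n_checked <- 0L
  for (N in 2:n_max) {
    for (n in 1:N) {
      subsets <- utils::combn(N, n)
      for (K in 0:N) {
        carriers <- colSums(subsets <= K)
        ks <- max(0, n + K - N):min(n, K)
        p_enum <- vapply(ks, function(k) mean(carriers >= k), numeric(1))
        p_imp <- hypergeom_test(N, K, n, ks)$p_upper
        worst <- max(worst, max(abs(p_enum - p_imp)))
        n_checked <- n_checked + length(ks)
      }
    }
  }
  list(max_abs_error = worst, n_margins = n_checked)
}
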