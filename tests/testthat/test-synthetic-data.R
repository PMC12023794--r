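test_that("Yule trees are ultrametric, labelled, and seed-deterministic", {
  tr <- simulate_tree(50, seed = 3)
  expect_s3_class(tr, "phylo")
  expect_length(tr$tip.label, 50)
  expect_equal(tr$Nnode, 49)
  depths <- ape::node.depth.edgelength(tr)[seq_len(50)]
  expect_lt(max(depths) - min(depths), 1e-9)

  expect_identical(ape::write.tree(simulate_tree(20, seed = 7)),
                   ape::write.tree(simulate_tree(20, seed = 7)))
  expect_false(identical(ape::write.tree(simulate_tree(20, seed = 7)),
                         ape::write.tree(simulate_tree(20, seed = 8))))

  single <- simulate_tree(1)
  expect_length(single$tip.label, 1)
  expect_equal(sum(single$edge.length), 0)
  expect_error(simulate_tree(0), "n_tips")
})

test_that("habitat assignment covers tips and respects both modes", {
  tr <- simulate_tree(24, seed = 5)
  h1 <- assign_habitats(tr, 1)
  expect_length(unique(h1), 1)
  expect_named(h1, tr$tip.label)

  expect_error(assign_habitats(tr, 25), "exceeds")

  # clade_confounded with k = 2 on a balanced tree splits at the root
  bal <- ape::stree(8, type = "balanced")
  bal$edge.length <- rep(1, nrow(bal$edge))
  hb <- assign_habitats(bal, 2, "clade_confounded")
  left <- root_child_tips(bal)   # one root subtree
  expect_length(unique(hb[left]), 1)
  expect_length(unique(hb[setdiff(bal$tip.label, left)]), 1)
  expect_false(hb[left][1] == hb[setdiff(bal$tip.label, left)][1])

  # clade_confounded habitats are connected clades (monophyletic tip sets)
  tr2 <- simulate_tree(40, seed = 9)
  hc <- assign_habitats(tr2, 4, "clade_confounded")
  for (h in unique(hc)) {
    expect_true(ape::is.monophyletic(tr2, names(hc)[hc == h]))
  }
})

test_that("random habitat labels are exchangeable w.r.t. the tree", {
  # association between random labels and the root bipartition should be
  # rejected at about the nominal 5% rate
  tr <- simulate_tree(40, seed = 21)
  in_root <- tr$tip.label %in% root_child_tips(tr)
  reps <- 1000
  rej <- vapply(seq_len(reps), function(i) {
    h <- assign_habitats(tr, 2, "random", seed = 5000 + i,
                         weights = c(1, 1))
    tab <- table(h[tr$tip.label], in_root)
    suppressWarnings(stats::chisq.test(tab, correct = FALSE)$p.value) < 0.05
  }, logical(1))
  ci <- 0.05 + c(-1, 1) * stats::qnorm(0.995) * sqrt(0.05 * 0.95 / reps)
  expect_gte(mean(rej), ci[1])
  expect_lte(mean(rej), ci[2])
})

test_that("gene counts track the Poisson/Brownian/habitat model", {
  tr <- simulate_tree(200, seed = 31)
  hab <- assign_habitats(tr, 2, "random", seed = 32, weights = c(1, 1))
  # no noise, no effects: overall mean close to the baseline of 5
  sim <- simulate_gene_counts(tr, hab, n_genes = 1, baseline_log_mean = log(5),
                              bm_sigma2 = 0, seed = 33)
  expect_true(mean(sim$counts) >= 4 && mean(sim$counts) <= 6)
  expect_true(all(sim$counts >= 0 & sim$counts == round(sim$counts)))

  # a planted +2 log effect always lifts that habitat's mean count
  tr2 <- simulate_tree(100, seed = 41)
  et <- data.frame(gene = 1, habitat = "fungi", effect = 2)
  wins <- vapply(seq_len(100), function(s) {
    h <- assign_habitats(tr2, 2, "random", seed = 600 + s, weights = c(1, 1))
    cnt <- simulate_gene_counts(tr2, h, 1, log(5), 0.05, et,
                                seed = 700 + s)$counts
    mean(cnt[1, h == "fungi"]) > mean(cnt[1, h != "fungi"])
  }, logical(1))
  expect_true(all(wins))

  # empty gene set keeps genome columns
  empty <- simulate_gene_counts(tr2, assign_habitats(tr2, 2, seed = 1), 0)
  expect_equal(dim(empty$counts), c(0L, 100L))
  expect_identical(colnames(empty$counts), tr2$tip.label)

  expect_error(simulate_gene_counts(tr2, c(x = "fungi"), 2), "cover")
})

test_that("simulate_dataset plants QC failures, clones, and is deterministic", {
  cfg <- sim_config(n_tips = 30, n_genes = 40, n_duplicates = 4,
                    qc_fail_spec = list(completeness = 3, contamination = 1),
                    seed = 77)
  ds <- simulate_dataset(cfg)
  expect_equal(sum(ds$records$completeness < 95), 3)
  expect_equal(sum(ds$records$contamination > 5), 1)
  over <- ds$ani_pairs$ani > 0.99995 & ds$ani_pairs$af > 0.90
  expect_equal(sum(over), 4)
  expect_setequal(ds$tree$tip.label, ds$records$genome_id)
  expect_identical(colnames(ds$counts), ds$tree$tip.label)

  ds2 <- simulate_dataset(cfg)
  expect_identical(ape::write.tree(ds$tree), ape::write.tree(ds2$tree))
  expect_identical(ds$records, ds2$records)
  expect_identical(ds$counts, ds2$counts)
  expect_identical(ds$cazyme, ds2$cazyme)
  expect_identical(ds$ani_pairs, ds2$ani_pairs)
})

test_that("clustered trees have the stated separation geometry", {
  tr <- simulate_clustered_tree(3, 5, separation = 5, seed = 2)
  d <- cophenetic_distances(tr)
  clade <- attr(tr, "clade")
  same <- outer(clade, clade, "==") & upper.tri(d)
  diff <- outer(clade, clade, "!=") & upper.tri(d)
  expect_lte(max(d[same]), 2 + 1e-9)
  expect_equal(unname(min(d[diff])), 10, tolerance = 1e-9)
  # newick serialization rounds branch lengths; allow float slack
  expect_gte(min(d[diff]) / max(d[same]), 5 - 1e-6)
})
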