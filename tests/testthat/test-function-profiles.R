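test_that("pathway copy number follows the min-over-required-genes rule", {
  pw <- c("A", "B", "C")
  expect_equal(pathway_copy_number(c(A = 2, B = 1, C = 3), pw), 1L)
  expect_equal(pathway_copy_number(c(A = 2, B = 0, C = 3), pw), 0L)
  expect_equal(pathway_copy_number(c(A = 2, B = 2, C = 2), pw), 2L)
  # a required gene absent from the vector counts as zero
  expect_equal(pathway_copy_number(c(A = 2, C = 3), pw), 0L)
  expect_error(pathway_copy_number(c(A = 1), character(0)), "no required")

  # monotone in every count, zero iff incomplete
  set.seed(4)
  for (i in 1:20) {
    cnt <- setNames(rpois(3, 1), pw)
    v <- pathway_copy_number(cnt, pw)
    expect_equal(v == 0, any(cnt == 0))
    bump <- cnt; bump[sample(3, 1)] <- bump[sample(3, 1)] + 1
    expect_gte(pathway_copy_number(bump, pw), v)
  }

  counts <- matrix(c(2, 1, 3, 0, 5, 5), nrow = 3,
                   dimnames = list(pw, c("g1", "g2")))
  tab <- pathway_copy_table(counts, list(p1 = pw))
  expect_equal(unname(tab[, "p1"]), c(1L, 0L))
})

test_that("chi-squared habitat comparison matches the hand computation", {
  # presence table [[10,40],[30,20]]: E = [[20,30],[20,30]], X2 = 16.667
  cn <- c(rep(0L, 10), rep(1L, 30), rep(0L, 40), rep(1L, 20))
  ids <- paste0("g", seq_along(cn))
  copy_table <- matrix(cn, ncol = 1, dimnames = list(ids, "pw"))
  hab <- setNames(rep(c("fungi", "plants"), c(40, 60)), ids)
  out <- pathway_habitat_comparison(copy_table, hab, mode = "presence")
  expect_equal(out$chisq, 50 / 3, tolerance = 1e-10)
  expect_equal(out$df, 1L)

  # proportional tables give exactly zero
  cn2 <- rep(c(0L, 1L), 50)
  copy2 <- matrix(cn2, ncol = 1, dimnames = list(ids, "pw"))
  out2 <- pathway_habitat_comparison(copy2, hab, mode = "presence")
  expect_equal(out2$chisq, 0, tolerance = 1e-12)
  expect_equal(out2$p, 1)
})

test_that("habitat-exclusive planted pathways are flagged and significant", {
  ds <- simulate_dataset(sim_config(n_tips = 250, n_genes = 5, seed = 61))
  ct <- pathway_copy_table(ds$pathway_content, ds$pathway_defs)
  hab <- setNames(ds$records$habitat, ds$records$genome_id)
  cmp <- pathway_habitat_comparison(ct, hab)
  galf <- cmp[cmp$pathway == "abc_galactofuranose", ]
  expect_equal(galf$exclusive, "fungi")
  expect_lt(galf$q, 0.05)
})

test_that("consensus filtering keeps multi-algorithm hits and is idempotent", {
  ann <- data.frame(
    protein_id = c("p1", "p2", "p3"), genome_id = "g1",
    family = c("GH32", "GT4", "GH18"),
    algorithms = c("HMMER,DIAMOND", "eCAMI", "DIAMOND,HMMER,eCAMI"))
  kept <- cazy_consensus_filter(ann)
  expect_equal(kept$protein_id, c("p1", "p3"))
  expect_identical(cazy_consensus_filter(kept), kept)
  empty <- ann[0, ]
  expect_identical(cazy_consensus_filter(empty), empty)
})

test_that("substrate rollup assigns full family counts to every substrate", {
  ann <- data.frame(
    protein_id = paste0("p", 1:5), genome_id = c("g1", "g1", "g1", "g2", "g2"),
    family = c("GH32", "GH32", "GH32", "GT4", "GH32"),
    algorithms = "HMMER,DIAMOND")
  fam <- cazy_family_counts(ann, c("g1", "g2"))
  expect_equal(unname(fam["GH32", ]), c(3L, 1L))

  smap <- list(sucrose = "GH32", sweets = c("GH32", "GT4"))
  guilds <- c(g1 = "ectomycorrhizal", g2 = "saprotrophic")
  prof <- substrate_profile(ann, smap, guilds)
  expect_equal(unname(prof$substrate_counts["sucrose", "g1"]), 3)
  # shared family contributes fully to both substrates
  expect_equal(unname(prof$substrate_counts["sweets", "g2"]), 2)
  expect_equal(unname(prof$substrate_counts["sucrose", "g2"]), 1)
  expect_gte(sum(prof$substrate_counts, na.rm = TRUE),
             sum(fam[unique(unlist(smap)), ]))
  # substrate with no mapped family present reports NA, not an error
  prof2 <- substrate_profile(ann, c(smap, list(chitin = "GH18")), guilds)
  expect_true(is.na(prof2$comparison$p[prof2$comparison$substrate ==
                                         "chitin"]))
})

test_that("a planted guild effect on plant substrates is starred", {
  fams <- unlist(fab_substrate_map())
  plant_fams <- unique(unlist(fab_substrate_map()[
    c("sucrose", "cellulose", "hemicellulose", "starch")]))
  hits <- vapply(1:100, function(s) {
    set.seed(4000 + s)
    ids <- paste0("g", 1:40)
    guilds <- setNames(rep(c("ectomycorrhizal", "saprotrophic"), each = 20),
                       ids)
    fam_u <- unique(fams)
    grid <- expand.grid(genome_id = ids, family = fam_u,
                        stringsAsFactors = FALSE)
    lam <- 1 + 2 * (guilds[grid$genome_id] == "ectomycorrhizal" &
                      grid$family %in% plant_fams)
    cnt <- rpois(nrow(grid), lam)
    ann <- grid[rep(seq_len(nrow(grid)), cnt), ]
    ann$protein_id <- paste0("p", seq_len(nrow(ann)))
    ann$algorithms <- "HMMER,DIAMOND"
    prof <- substrate_profile(ann, fab_substrate_map(), guilds)
    cmp <- prof$comparison
    all(cmp$starred[cmp$substrate %in% c("sucrose", "cellulose",
                                         "hemicellulose", "starch")])
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})
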