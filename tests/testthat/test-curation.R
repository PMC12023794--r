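test_that("quality thresholds are inclusive on the passing side", {
  boundary <- curation_fixture()[1, ]
  boundary$completeness <- 95.0
  boundary$contamination <- 5.0
  boundary$single_copy_hits <- 83L
  boundary$coding_fraction <- 85.0
  out <- filter_quality(boundary)
  expect_equal(nrow(out$kept), 1)

  failing <- boundary
  failing$completeness <- 94.9
  out2 <- filter_quality(failing)
  expect_equal(nrow(out2$kept), 0)
  expect_equal(unname(out2$report$removed_by_rule[["completeness"]]), 1)
})

test_that("the hand-enumerated fixture filters exactly as designed", {
  recs <- curation_fixture()
  out <- filter_quality(recs)
  expect_setequal(out$kept$genome_id, sprintf("ok%02d", 1:6))
  expect_equal(unname(out$report$removed_by_rule),
               rep(1L, 5))
  expect_equal(out$report$removed_ids$site, "f_site")
  expect_equal(out$report$removed_ids$completeness, "f_comp")
  expect_equal(out$report$removed_ids$contamination, "f_cont")
  expect_equal(out$report$removed_ids$single_copy, "f_scg")
  expect_equal(out$report$removed_ids$coding, "f_cod")
  # conservation and idempotence
  expect_equal(length(out$report$kept_ids) + sum(out$report$removed_by_rule),
               nrow(recs))
  again <- filter_quality(out$kept)
  expect_identical(again$kept, out$kept)
  expect_error(filter_quality(recs[0, ]), "empty")
})

test_that("attribution goes to the first failing rule", {
  rec <- curation_fixture()[1, ]
  rec$isolation_site_known <- FALSE
  rec$coding_fraction <- 10      # also fails coding, but site comes first
  rep <- filter_quality(rec)$report
  expect_equal(unname(rep$removed_by_rule[["site"]]), 1)
  expect_equal(unname(rep$removed_by_rule[["coding"]]), 0)
})

test_that("species subsampling keeps at most five per species and habitat", {
  base <- curation_fixture()[1, ]
  mk <- function(id, species, habitat) {
    r <- base; r$genome_id <- id; r$species <- species; r$habitat <- habitat; r
  }
  small <- do.call(rbind, lapply(1:3, function(i)
    mk(paste0("s", i), "spA", "soil")))
  expect_equal(nrow(subsample_species(small, seed = 1)), 3)

  big <- do.call(rbind, lapply(1:12, function(i)
    mk(paste0("b", i), "spB", "soil")))
  kept <- subsample_species(big, seed = 1)
  expect_equal(nrow(kept), 5)
  # uniform sampling: over many seeds every member is kept at least once
  seen <- unique(unlist(lapply(1:200, function(s)
    subsample_species(big, seed = s)$genome_id)))
  expect_setequal(seen, big$genome_id)

  # grouping is per species x habitat pair
  two_hab <- rbind(
    do.call(rbind, lapply(1:7, function(i) mk(paste0("x", i), "spC", "soil"))),
    do.call(rbind, lapply(1:7, function(i) mk(paste0("y", i), "spC", "water"))))
  kept2 <- subsample_species(two_hab, seed = 2)
  expect_equal(as.vector(table(kept2$habitat)[c("soil", "water")]),
               c(5L, 5L))
})

test_that("ANI dedup applies strict thresholds and collapses components", {
  base <- curation_fixture()
  recs <- base[1:3, ]
  recs$genome_id <- c("A", "B", "C")
  over <- data.frame(genome_a = "A", genome_b = "B",
                     ani = 0.99996, af = 0.91)
  dd <- deduplicate_ani(recs, over, seed = 1)
  expect_equal(nrow(dd$kept), 2)
  expect_length(dd$removed_ids, 1)
  expect_true(dd$removed_ids %in% c("A", "B"))

  under <- data.frame(genome_a = "A", genome_b = "B",
                      ani = 0.99990, af = 0.95)
  expect_equal(nrow(deduplicate_ani(recs, under, seed = 1)$kept), 3)

  # exact equality at a threshold is not redundancy (strict inequality)
  at <- data.frame(genome_a = "A", genome_b = "B", ani = 0.99995, af = 0.95)
  expect_equal(nrow(deduplicate_ani(recs, at, seed = 1)$kept), 3)

  # chain A-B, B-C: one survivor, matching a union-find oracle
  chain <- data.frame(genome_a = c("A", "B"), genome_b = c("B", "C"),
                      ani = 0.99999, af = 0.95)
  for (s in 1:5) {
    ddc <- deduplicate_ani(recs, chain, seed = s)
    expect_equal(nrow(ddc$kept), 1)
  }
  oracle <- uf_components(c("A", "B", "C"),
                          as.matrix(chain[, c("genome_a", "genome_b")]))
  expect_length(oracle, 1)      # single component of size three
  expect_setequal(unlist(oracle), c("A", "B", "C"))
  expect_setequal(unlist(deduplicate_ani(recs, chain,
                                         seed = 1)$redundant_groups),
                  c("A", "B", "C"))

  bad <- data.frame(genome_a = "A", genome_b = "Z", ani = 1, af = 1)
  expect_error(deduplicate_ani(recs, bad), "unknown")
})

test_that("curation removes planted clones, one survivor per clone group", {
  ds <- simulate_dataset(sim_config(n_tips = 25, n_genes = 10,
                                    n_duplicates = 3, seed = 11))
  cur <- curate_genomes(ds$records, ds$ani_pairs, seed = 4)
  for (r in seq_len(nrow(ds$truth$duplicates))) {
    pair <- unlist(ds$truth$duplicates[r, c("source", "clone")])
    expect_equal(sum(pair %in% cur$kept$genome_id), 1)
  }
  expect_equal(length(cur$report$kept_ids) +
                 sum(cur$report$removed_by_rule), nrow(ds$records))
})
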