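test_that("Bray-Curtis dissimilarities follow the formula and its bounds", {
  m <- cbind(g1 = c(6, 2), g2 = c(2, 2), g3 = c(5, 0), g4 = c(0, 5))
  rownames(m) <- c("a", "b")
  d <- bray_curtis(m)
  expect_equal(d["g1", "g2"], 4 / 12, tolerance = 1e-12)
  expect_equal(d["g3", "g4"], 1)
  expect_equal(d["g1", "g1"], 0)

  set.seed(11)
  r <- matrix(rpois(200, 3), nrow = 10,
              dimnames = list(NULL, paste0("g", 1:20)))
  dr <- bray_curtis(r)
  expect_true(all(dr >= -1e-12 & dr <= 1 + 1e-12))
  expect_equal(dr, t(dr))

  expect_error(bray_curtis(cbind(a = c(0, 0), b = c(0, 0))), "all-zero")
  expect_warning(bray_curtis(cbind(a = c(0, 0), b = c(1, 2))), "all-zero")
})

test_that("richness counts present orthologs and separates planted habitats", {
  m <- cbind(g1 = c(0, 3, 1, 0), g2 = c(0, 0, 0, 0))
  expect_equal(unname(richness(m)), c(2L, 0L))

  # one habitat with a 20% larger repertoire gets the top distinct letter
  set.seed(21)
  n_per <- 30
  ids <- paste0("g", 1:(3 * n_per))
  hab <- setNames(rep(c("fungi", "soil", "water"), each = n_per), ids)
  pres_p <- ifelse(hab == "fungi", 0.72, 0.60)
  counts <- sapply(seq_along(ids), function(i)
    rbinom(200, 1, pres_p[i]) * rpois(200, 3))
  colnames(counts) <- ids
  rc <- richness_compare(counts, hab)
  gi <- rc$groups
  expect_equal(gi$group[which.max(gi$mean)], "fungi")
  others <- gi$letters[gi$group != "fungi"]
  fl <- strsplit(gi$letters[gi$group == "fungi"], "")[[1]]
  expect_false(any(fl %in% unlist(strsplit(others, ""))))
})

test_that("PCoA reproduces known geometries", {
  # three equidistant points: two equal positive eigenvalues, third ~ 0
  d3 <- matrix(1, 3, 3) - diag(3)
  p3 <- pcoa(d3)
  ev <- sort(p3$eigenvalues, decreasing = TRUE)
  expect_equal(ev[1], ev[2], tolerance = 1e-10)
  expect_lt(abs(ev[3]), 1e-10)

  # Euclidean input distances are reproduced exactly
  set.seed(31)
  pts <- matrix(rnorm(30), 10, 3)
  de <- as.matrix(dist(pts))
  pe <- pcoa(de)
  expect_equal(as.matrix(dist(pe$coordinates)), de, tolerance = 1e-8,
               ignore_attr = TRUE)

  # duplicated sample lands on identical coordinates
  dd <- as.matrix(dist(pts[c(1, 1, 2:10), ]))
  pd <- pcoa(dd)
  expect_equal(pd$coordinates[1, ], pd$coordinates[2, ], tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("PERMANOVA decomposes variance and matches vegan", {
  set.seed(41)
  counts <- matrix(rpois(50 * 24, 4), nrow = 50,
                   dimnames = list(NULL, paste0("g", 1:24)))
  hab <- setNames(rep(c("a", "b", "c"), each = 8), colnames(counts))
  d <- bray_curtis(counts)
  pv <- permanova_dbrda(d, hab, n_perm = 199, seed = 5)
  expect_equal(unname(pv$ss["between"] + pv$ss["within"]),
               unname(pv$ss["total"]), tolerance = 1e-10)
  ad <- vegan::adonis2(as.dist(d) ~ grp,
                       data = data.frame(grp = factor(hab)),
                       permutations = 99)
  expect_equal(pv$F, ad$F[1], tolerance = 1e-8)
  expect_equal(pv$R2, ad$R2[1], tolerance = 1e-8)
  expect_equal(pv$R2, pv$dbrda_R2, tolerance = 1e-6)

  # identical composition in both groups: no between-group inertia
  prof <- matrix(rpois(50 * 4, 4), nrow = 50)
  counts2 <- cbind(prof, prof)
  colnames(counts2) <- paste0("g", 1:8)
  lab2 <- setNames(rep(c("x", "y"), each = 4), colnames(counts2))
  d2 <- bray_curtis(counts2)
  pv2 <- permanova_dbrda(d2, lab2, n_perm = 199, seed = 6)
  expect_lt(pv2$R2, 0.05)
  expect_gt(pv2$p, 0.5)

  expect_error(permanova_dbrda(d, setNames(rep("a", 24), colnames(counts))),
               "2 groups")
})

test_that("exact enumeration agrees with Monte Carlo permutation p", {
  set.seed(51)
  counts <- matrix(rpois(30 * 8, 3) +
                     rep(c(2, 0), each = 4)[col(matrix(0, 30, 8))] *
                       rbinom(30 * 8, 1, 0.3),
                   nrow = 30, dimnames = list(NULL, paste0("g", 1:8)))
  lab <- setNames(rep(c("a", "b"), each = 4), colnames(counts))
  d <- bray_curtis(counts)
  ex <- permanova_dbrda(d, lab, n_perm = "exact")
  expect_equal(ex$n_perm, choose(8, 4))
  mc <- permanova_dbrda(d, lab, n_perm = 4999, seed = 3)
  expect_lt(abs(ex$p - mc$p), 0.03)
})

test_that("group comparisons produce valid compact-letter displays", {
  set.seed(61)
  for (rep in 1:8) {
    k <- sample(3:5, 1)
    n <- 15
    shift <- cumsum(runif(k, 0, 1.5))
    ids <- paste0("g", 1:(k * n))
    vals <- setNames(rnorm(k * n, rep(shift, each = n)), ids)
    labs <- setNames(rep(paste0("grp", 1:k), each = n), ids)
    gc <- group_compare(vals, labs)
    lets <- setNames(gc$groups$letters, gc$groups$group)
    for (r in seq_len(nrow(gc$pairwise))) {
      pr <- strsplit(gc$pairwise$pair[r], "-", fixed = TRUE)[[1]]
      share <- length(intersect(strsplit(lets[[pr[1]]], "")[[1]],
                                strsplit(lets[[pr[2]]], "")[[1]])) > 0
      expect_equal(share, gc$pairwise$q[r] >= 0.05)
    }
  }
})

test_that("genome size and GC comparisons flag a shifted habitat", {
  set.seed(71)
  ids <- paste0("g", 1:90)
  hab <- rep(c("fungi", "soil", "water"), each = 30)
  recs <- data.frame(genome_id = ids, habitat = hab,
                     genome_size = rnorm(90, 5e6, 2e5) +
                       (hab == "plants") * 0,
                     gc_content = rnorm(90, 55, 2) + (hab == "fungi") * 6)
  out <- genome_summary_compare(recs)
  gc_letters <- out$gc_content$groups
  fl <- strsplit(gc_letters$letters[gc_letters$group == "fungi"], "")[[1]]
  rest <- unlist(strsplit(gc_letters$letters[gc_letters$group != "fungi"],
                          ""))
  expect_false(any(fl %in% rest))
  # identical distributions share one letter
  size_letters <- out$genome_size$groups
  expect_equal(length(unique(size_letters$letters)), 1)
})
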