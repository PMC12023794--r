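test_that("standardization is centered, scaled, and drops constants", {
  m <- rbind(gene1 = c(0, 0, 4, 4), gene2 = c(3, 3, 3, 3),
             gene3 = c(1, 2, 3, 10))
  colnames(m) <- paste0("g", 1:4)
  out <- standardize_counts(m)
  expect_equal(unname(out$z["gene1", ]), c(-1, -1, 1, 1))
  expect_equal(out$constant_genes, "gene2")
  expect_lt(abs(mean(out$z["gene3", ])), 1e-12)

  samp <- standardize_counts(m, sd_type = "sample")
  expect_equal(unname(samp$z["gene1", ]),
               c(-1, -1, 1, 1) / sqrt(4 / 3))
  expect_error(standardize_counts(m[, 1, drop = FALSE]), "2 genomes")
})

test_that("GLS reduces to OLS on a star tree and matches a matrix oracle", {
  # V proportional to the identity: whitening is a scalar, so OLS exactly
  set.seed(42)
  n <- 12
  y <- rnorm(n)
  X <- cbind(1, rep(c(0, 1), each = n / 2))
  V <- diag(2.5, n)
  f <- phylo_lm(y, X, V)
  ols <- lm(y ~ X[, 2])
  expect_equal(unname(coef(f)), unname(coef(ols)), tolerance = 1e-10)
  expect_equal(unname(f$se), unname(summary(ols)$coefficients[, 2]),
               tolerance = 1e-10)
  expect_equal(unname(f$p), unname(summary(ols)$coefficients[, 4]),
               tolerance = 1e-10)

  # four-taxon fixture against explicit V-inverse arithmetic
  tr <- quartet_tree()
  V4 <- bm_covariance(tr)[tr$tip.label, tr$tip.label]
  y4 <- c(1, 2, 3, 4)
  X4 <- cbind(1, as.numeric(tr$tip.label %in% c("C", "D")))
  Vi <- solve(V4)
  beta_oracle <- solve(t(X4) %*% Vi %*% X4) %*% t(X4) %*% Vi %*% y4
  f4 <- phylo_lm(y4, X4, V4)
  expect_equal(unname(coef(f4)), drop(beta_oracle), tolerance = 1e-10)
  r <- y4 - X4 %*% beta_oracle
  s2_oracle <- drop(t(r) %*% Vi %*% r) / (4 - 2)
  expect_equal(f4$sigma2, s2_oracle, tolerance = 1e-10)
  se_oracle <- sqrt(diag(s2_oracle * solve(t(X4) %*% Vi %*% X4)))
  expect_equal(unname(f4$se), se_oracle, tolerance = 1e-10)

  expect_error(phylo_lm(y4, X4[, c(1, 1)], V4), "rank")
  expect_error(phylo_lm(y4, X4, matrix(0, 4, 4) - 1), "positive definite")
})

test_that("phylo_lm agrees with an independent GLS implementation", {
  skip_if_not_installed("nlme")
  tr <- simulate_tree(30, seed = 3)
  V <- bm_covariance(tr)
  set.seed(9)
  b <- drop(crossprod(chol(V), rnorm(30)))
  x <- rnorm(30)
  y <- 1 + 0.5 * x + b
  dat <- data.frame(y = y, x = x, tip = tr$tip.label)
  g <- nlme::gls(y ~ x, data = dat,
                 correlation = ape::corBrownian(1, tr, form = ~tip))
  f <- phylo_lm(y, cbind(1, x), V)
  expect_equal(unname(coef(f)), unname(coef(g)), tolerance = 1e-6)
  expect_equal(unname(f$se),
               unname(sqrt(diag(g$varBeta))), tolerance = 1e-4)
})

test_that("model methods behave like a classed fit object", {
  tr <- simulate_tree(20, seed = 8)
  V <- bm_covariance(tr)
  set.seed(2)
  y <- rnorm(20)
  X <- cbind(1, rnorm(20))
  f <- phylo_lm(y, X, V)
  expect_s3_class(f, "phylo_lm")
  expect_length(coef(f), 2)
  expect_equal(dim(vcov(f)), c(2L, 2L))
  expect_equal(fitted(f) + residuals(f), y)
  expect_equal(unname(predict(f, X)), unname(fitted(f)))
  expect_output(print(f), "lambda")
  expect_output(print(summary(f)), "Coefficients")
  expect_s3_class(logLik(f), "logLik")
})

test_that("grid ML recovers boundary lambda values", {
  tr <- simulate_tree(50, seed = 19)
  V <- bm_covariance(tr)
  R <- chol(V)
  X <- cbind(1, rnorm(50))
  at0 <- at1 <- logical(100)
  set.seed(31)
  for (i in 1:100) {
    y_iid <- rnorm(50)                      # lambda = 0 truth
    y_bm <- drop(crossprod(R, rnorm(50)))   # lambda = 1 truth
    at0[i] <- phylo_lm(y_iid, X, V, lambda = "ml")$lambda <= 0.05
    at1[i] <- phylo_lm(y_bm, X, V, lambda = "ml")$lambda >= 0.95
  }
  expect_gte(mean(at0), 0.9)
  expect_gte(mean(at1), 0.9)
})

test_that("BH adjustment matches the hand-computed step-up", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.37), 0.37)
  set.seed(5)
  p <- runif(50)
  q <- bh_fdr(p)
  expect_true(all(q >= p))
  expect_true(all(diff(q[order(p)]) >= -1e-12))
  expect_error(bh_fdr(c(0.5, 1.2)), "outside")
})

test_that("enrich_all recovers a planted category enrichment", {
  tr <- simulate_tree(120, seed = 51)
  hab <- assign_habitats(tr, 3, "random", seed = 52, weights = c(1, 1, 1))
  n_genes <- 40
  et <- data.frame(gene = 1:8, habitat = "fungi", effect = 2)
  sim <- simulate_gene_counts(tr, hab, n_genes, log(5), 0.05, et, seed = 53)
  cmap <- data.frame(gene = rownames(sim$counts),
                     category = c(rep("G", 8), rep("R", n_genes - 8)))
  enr <- enrich_all(sim$counts, hab, tr, cmap)
  cell <- enr$categories[enr$categories$category == "G" &
                           enr$categories$habitat == "fungi", ]
  expect_gt(cell$median_effect, 0)
  expect_gt(cell$frac_q05, 0.5)
  # genes are never invented for empty categories
  expect_false(any(enr$categories$category == "Z"))

  # permuting genome order leaves results unchanged
  perm <- sample(ncol(sim$counts))
  enr2 <- enrich_all(sim$counts[, perm], hab, tr, cmap)
  expect_equal(enr$genes, enr2$genes)

  # unknown genes fall into the Unknown function bucket with a warning
  expect_warning(
    enr3 <- enrich_all(sim$counts, hab, tr, cmap[1:10, ]),
    "Unknown function")
  expect_true("Unknown function" %in% enr3$categories$category)
})
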