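# Gene-content ordination and group statistics: Bray-Curtis dissimilarity,
# ortholog richness, principal-coordinate embedding, one-way PERMANOVA with
# dbRDA axes, and ANOVA/Tukey group summaries with compact-letter displays.

#' Bray-Curtis dissimilarity between genomes
#'
#' `BC(u, v) = sum |u - v| / sum (u + v)` over gene counts; genomes are
#' the columns of `counts`.
#'
#' @param counts Genes x genomes non-negative matrix.
#' @return Symmetric genomes x genomes matrix in \[0, 1\]. All-zero
#'   genomes trigger a warning (one) or an error (two or more, the pair
#'   dissimilarity being undefined).
#' @export
bray_curtis <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) abort_fmt("counts must be non-negative")
  zero <- colSums(counts) == 0
  if (sum(zero) >= 2L) {
    abort_fmt("dissimilarity undefined between all-zero genomes: %s",
              paste(colnames(counts)[zero], collapse = ", "))
  }
  if (any(zero)) {
    warning(sprintf("all-zero genome: %s", colnames(counts)[zero]),
            call. = FALSE)
  }
  # vegan re-warns about empty rows; the validation above already did
  as.matrix(suppressWarnings(vegan::vegdist(t(counts), method = "bray")))
}

#' Gene-ortholog richness per genome
#'
#' @param counts Genes x genomes matrix.
#' @param presence_min Minimum count for an ortholog to count as present.
#' @return Named integer vector of per-genome richness.
#' @export
richness <- function(counts, presence_min = 1) {
  counts <- as.matrix(counts)
  colSums(counts >= presence_min)
}

#' Compare a per-genome quantity across habitats
#'
#' One-way ANOVA followed by Tukey's HSD (Tukey-Kramer for unbalanced
#' groups), BH-corrected, summarized as a compact-letter display in which
#' two groups share a letter iff their corrected pairwise q-value is at
#' least `alpha`.
#'
#' @param values Named numeric vector (e.g. richness, genome size, GC).
#' @param labels Named group vector over the same ids.
#' @param alpha Significance threshold.
#' @return List with `groups` (data frame: group, n, mean, letters),
#'   `anova_p`, and `pairwise` (data frame with Tukey p and BH q per
#'   pair).
#' @export
group_compare <- function(values, labels, alpha = 0.05) {
  ids <- intersect(names(values), names(labels))
  if (length(ids) < length(values)) abort_fmt("labels must cover all values")
  g <- factor(labels[ids])
  if (nlevels(g) < 2L) abort_fmt("need >= 2 groups to compare")
  y <- as.numeric(values[ids])
  fit <- stats::aov(y ~ g)
  anova_p <- summary(fit)[[1L]][["Pr(>F)"]][1L]
  tk <- stats::TukeyHSD(fit)$g
  pw <- data.frame(pair = rownames(tk), diff = tk[, "diff"],
                   p = tk[, "p adj"], stringsAsFactors = FALSE)
  pw$q <- bh_fdr(pw$p)
  lev <- levels(g)
  sig <- matrix(FALSE, nlevels(g), nlevels(g), dimnames = list(lev, lev))
  halves <- strsplit(pw$pair, "-", fixed = TRUE)
  for (i in seq_len(nrow(pw))) {
    a <- halves[[i]][1L]; b <- halves[[i]][2L]
    sig[a, b] <- sig[b, a] <- pw$q[i] < alpha
  }
  letters <- letter_display(sig)
  groups <- data.frame(group = lev, n = as.integer(table(g)),
                       mean = tapply(y, g, mean), letters = letters,
                       stringsAsFactors = FALSE)
  rownames(groups) <- NULL
  list(groups = groups, anova_p = anova_p, pairwise = pw)
}

#' Compare richness across habitats
#'
#' @inheritParams richness
#' @param habitats Named habitat vector over the genomes.
#' @param alpha Significance threshold for the letter display.
#' @return As [group_compare()], plus the `richness` vector.
#' @export
richness_compare <- function(counts, habitats, presence_min = 1,
                             alpha = 0.05) {
  r <- richness(counts, presence_min)
  out <- group_compare(r, habitats, alpha)
  out$richness <- r
  out
}

#' Compare genome size and GC content across habitats
#'
#' @param records Metadata data frame with `genome_id`, `genome_size`,
#'   `gc_content`.
#' @param labels Named group vector (defaults to the records' habitats).
#' @param alpha Significance threshold.
#' @return List with one [group_compare()] result per trait
#'   (`genome_size`, `gc_content`).
#' @export
genome_summary_compare <- function(records, labels = NULL, alpha = 0.05) {
  need <- c("genome_id", "genome_size", "gc_content")
  if (!all(need %in% names(records))) {
    abort_fmt("records must carry columns %s", paste(need, collapse = ", "))
  }
  if (is.null(labels)) {
    labels <- stats::setNames(records$habitat, records$genome_id)
  }
  lapply(stats::setNames(c("genome_size", "gc_content"),
                         c("genome_size", "gc_content")),
         function(tr) {
           v <- stats::setNames(records[[tr]], records$genome_id)
           group_compare(v, labels, alpha)
         })
}

# compact-letter display by insert-and-absorb: from a logical
# significant-difference matrix, produce letters such that two groups
# share a letter iff they are NOT significantly different
letter_display <- function(sig) {
  lev <- rownames(sig)
  sets <- list(lev)
  pairs <- which(sig & upper.tri(sig), arr.ind = TRUE)
  for (r in seq_len(nrow(pairs))) {
    a <- lev[pairs[r, 1L]]; b <- lev[pairs[r, 2L]]
    new_sets <- list()
    for (s in sets) {
      if (a %in% s && b %in% s) {
        new_sets <- c(new_sets, list(setdiff(s, a)), list(setdiff(s, b)))
      } else {
        new_sets <- c(new_sets, list(s))
      }
    }
    # absorb: drop any set contained in another (duplicates keep first)
    keep <- rep(TRUE, length(new_sets))
    for (i in seq_along(new_sets)) {
      for (j in seq_along(new_sets)) {
        if (i == j || !keep[i] || !keep[j]) next
        if (all(new_sets[[i]] %in% new_sets[[j]]) &&
            (length(new_sets[[i]]) < length(new_sets[[j]]) || j < i)) {
          keep[i] <- FALSE
        }
      }
    }
    sets <- new_sets[keep]
  }
  out <- vapply(lev, function(gname) {
    paste(letters[which(vapply(sets, function(s) gname %in% s, logical(1)))],
          collapse = "")
  }, character(1))
  out
}

#' Principal coordinate analysis
#'
#' Gower double-centering of `-0.5 * D^2` followed by eigendecomposition;
#' coordinates are eigenvectors scaled by the square root of their
#' eigenvalues. Axes with negative eigenvalues are dropped by default and
#' reported.
#'
#' @param dissim Dissimilarity matrix (or `dist`).
#' @param n_axes Maximum number of positive axes returned.
#' @return List with `coordinates` (samples x axes), `eigenvalues` (all,
#'   including negatives), `negative_axes` (count dropped).
#' @export
pcoa <- function(dissim, n_axes = NULL) {
  m <- check_dist_matrix(dissim)
  n <- nrow(m)
  fit <- suppressWarnings(stats::cmdscale(stats::as.dist(m), k = n - 1L,
                                          eig = TRUE))
  eig <- fit$eig
  pos <- which(eig > 1e-12 * max(abs(eig)))
  if (!is.null(n_axes)) pos <- pos[seq_len(min(n_axes, length(pos)))]
  coords <- fit$points[, pos, drop = FALSE]
  colnames(coords) <- paste0("PCo", seq_along(pos))
  rownames(coords) <- rownames(m)
  list(coordinates = coords, eigenvalues = eig,
       negative_axes = sum(eig < -1e-12 * max(abs(eig))))
}

# sums of squares of a one-way PERMANOVA from squared dissimilarities
permanova_ss <- function(d2, labels) {
  N <- nrow(d2)
  ss_total <- sum(d2[upper.tri(d2)]) / N
  ss_within <- 0
  for (ix in split(seq_len(N), labels)) {
    if (length(ix) >= 2L) {
      sub <- d2[ix, ix]
      ss_within <- ss_within + sum(sub[upper.tri(sub)]) / length(ix)
    }
  }
  c(total = ss_total, within = ss_within, between = ss_total - ss_within)
}

#' PERMANOVA with distance-based redundancy analysis
#'
#' One-way permutational multivariate analysis of variance on a
#' dissimilarity matrix: `SS_total = (1/N) sum_{i<j} d_ij^2`, `SS_within`
#' summed per group, pseudo-F on `(k - 1, N - k)` degrees of freedom, and
#' permutation p-value `(1 + #{F_perm >= F_obs}) / (n_perm + 1)` (the
#' observed statistic counts itself, so p is floored at
#' `1 / (n_perm + 1)`). Constrained (dbRDA) axes and inertia fraction are
#' computed with `vegan::dbrda` on the same dissimilarities for plotting
#' parity.
#'
#' @param dissim Dissimilarity matrix (or `dist`).
#' @param labels Named group vector over the samples (>= 2 groups, each
#'   with >= 2 members).
#' @param n_perm Number of permutations (`"exact"` enumerates all distinct
#'   label arrangements; only sensible for tiny N).
#' @param seed Optional integer seed for the permutations.
#' @return Object of class `fab_permanova`: `F`, `R2` (PERMANOVA
#'   `SS_between / SS_total`), `p`, `n_perm`, the SS decomposition,
#'   `dbrda_R2` (constrained inertia fraction), `dbrda_eigenvalues`, and
#'   constrained site `scores`.
#' @export
permanova_dbrda <- function(dissim, labels, n_perm = 999, seed = NULL) {
  m <- check_dist_matrix(dissim)
  ids <- rownames(m)
  if (!all(ids %in% names(labels))) abort_fmt("labels must cover all samples")
  lab <- factor(labels[ids])
  k <- nlevels(lab)
  N <- nrow(m)
  if (k < 2L) abort_fmt("need >= 2 groups")
  if (any(table(lab) < 2L)) abort_fmt("every group needs >= 2 members")
  d2 <- m^2
  ss <- permanova_ss(d2, lab)
  df1 <- k - 1L; df2 <- N - k
  f_obs <- (ss["between"] / df1) / (ss["within"] / df2)

  f_of <- function(perm_lab) {
    s <- permanova_ss(d2, perm_lab)
    (s["between"] / df1) / (s["within"] / df2)
  }
  if (identical(n_perm, "exact")) {
    perms <- unique_label_permutations(lab)
    f_perm <- vapply(perms, f_of, numeric(1))
    p <- mean(f_perm >= f_obs - 1e-12)   # observed config is among perms
    n_perm_used <- length(perms)
  } else {
    f_perm <- with_seed(seed, vapply(seq_len(n_perm), function(i)
      f_of(sample(lab)), numeric(1)))
    p <- (1 + sum(f_perm >= f_obs - 1e-12)) / (n_perm + 1)
    n_perm_used <- n_perm
  }

  db <- vegan::dbrda(stats::as.dist(m) ~ grp,
                     data = data.frame(grp = lab))
  dbrda_R2 <- db$CCA$tot.chi / db$tot.chi
  sc <- tryCatch(vegan::scores(db, display = "sites"),
                 error = function(e) NULL)
  structure(list(F = unname(f_obs), R2 = unname(ss["between"] / ss["total"]),
                 p = p, n_perm = n_perm_used, ss = ss, df = c(df1, df2),
                 dbrda_R2 = dbrda_R2,
                 dbrda_eigenvalues = db$CCA$eig, scores = sc,
                 labels = lab), class = "fab_permanova")
}

# all distinct assignments of a label multiset (for exact tests, tiny N)
unique_label_permutations <- function(lab) {
  pool <- as.integer(lab)
  out <- list()
  recurse <- function(remaining, acc) {
    if (!length(remaining)) {
      out[[length(out) + 1L]] <<- factor(levels(lab)[acc],
                                         levels = levels(lab))
      return(invisible(NULL))
    }
    for (v in unique(remaining)) {
      at <- which(remaining == v)[1L]
      recurse(remaining[-at], c(acc, v))
    }
  }
  recurse(pool, integer(0))
  out
}

#' @export
print.fab_permanova <- function(x, ...) {
  cat("PERMANOVA on Bray-Curtis-type dissimilarities\n")
  cat(sprintf("  F = %.3f on (%d, %d) df;  R2 = %.4f;  p = %.4g (%d permutations)\n",
              x$F, x$df[1L], x$df[2L], x$R2, x$p, x$n_perm))
  cat(sprintf("  dbRDA constrained inertia fraction: %.4f\n", x$dbrda_R2))
  invisible(x)
}
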