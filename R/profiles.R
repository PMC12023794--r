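# Functional profiling: ABC-transporter-style pathway completeness and copy
# number with chi-squared habitat comparisons, and CAZyme consensus
# filtering, family collation, and substrate-level guild comparisons.

#' Copy number of a complete pathway in one genome
#'
#' A pathway counts only when complete (every required gene present); its
#' copy number is then the minimum copy count over required genes — the
#' number of fully stocked pathway instances. Monotone in every gene count
#' and zero iff the pathway is incomplete.
#'
#' @param genome_gene_counts Named non-negative counts for one genome.
#' @param pathway Character vector of required gene ids (non-empty);
#'   genes absent from the count vector count as 0.
#' @return Integer copy number.
#' @examples
#' pathway_copy_number(c(A = 2, B = 1, C = 3), c("A", "B", "C"))  # 1
#' @export
pathway_copy_number <- function(genome_gene_counts, pathway) {
  if (length(pathway) == 0L) abort_fmt("pathway has no required genes")
  cnt <- genome_gene_counts[pathway]
  cnt[is.na(cnt)] <- 0
  if (any(cnt < 0)) abort_fmt("negative gene counts")
  as.integer(min(cnt))
}

#' Pathway copy numbers for all genomes
#'
#' @param gene_counts Genes x genomes count matrix (pathway genes as rows).
#' @param pathway_defs Named list, pathway id -> required gene ids.
#' @return Genomes x pathways integer matrix of complete-pathway copy
#'   numbers.
#' @export
pathway_copy_table <- function(gene_counts, pathway_defs) {
  gene_counts <- as.matrix(gene_counts)
  out <- vapply(pathway_defs, function(genes) {
    m <- matrix(0, length(genes), ncol(gene_counts))
    hit <- genes %in% rownames(gene_counts)
    m[hit, ] <- gene_counts[genes[hit], , drop = FALSE]
    as.integer(apply(m, 2, min))
  }, integer(ncol(gene_counts)))
  rownames(out) <- colnames(gene_counts)
  out
}

#' Compare pathway copy-number frequencies across habitats
#'
#' Per pathway, bins genome copy numbers (default categories 0, 1, >= 2;
#' `mode = "presence"` collapses to absent/present) and tests the
#' category x habitat contingency table with Pearson's chi-squared (no
#' continuity correction by default), FDR-correcting across pathways.
#' Pathways whose copies occur in exactly one habitat are flagged
#' exclusive.
#'
#' @param copy_table Genomes x pathways matrix from [pathway_copy_table()].
#' @param habitats Named habitat vector over the genomes.
#' @param mode `"categories"` (0 / 1 / >= 2) or `"presence"` (0 / >= 1).
#' @param correct Apply Yates continuity correction (2x2 tables only).
#' @return Data frame: `pathway`, `chisq`, `df`, `p`, `q`, `exclusive`
#'   (habitat name or `NA`).
#' @export
pathway_habitat_comparison <- function(copy_table, habitats,
                                       mode = c("categories", "presence"),
                                       correct = FALSE) {
  mode <- match.arg(mode)
  copy_table <- as.matrix(copy_table)
  if (!all(rownames(copy_table) %in% names(habitats))) {
    abort_fmt("habitats must cover all genomes in copy_table")
  }
  hab <- factor(habitats[rownames(copy_table)])
  res <- lapply(colnames(copy_table), function(pw) {
    cn <- copy_table[, pw]
    cat <- if (mode == "presence") factor(cn >= 1, levels = c(FALSE, TRUE))
           else factor(pmin(cn, 2L), levels = 0:2)
    tab <- table(cat, hab)
    tab <- tab[rowSums(tab) > 0, , drop = FALSE]
    if (nrow(tab) < 2L || ncol(tab) < 2L) {
      chisq <- 0; df <- NA_integer_; p <- 1
    } else {
      ct <- suppressWarnings(stats::chisq.test(tab, correct = correct))
      chisq <- unname(ct$statistic); df <- unname(ct$parameter)
      p <- ct$p.value
    }
    present_habs <- unique(as.character(hab[cn > 0]))
    data.frame(pathway = pw, chisq = chisq, df = df, p = p,
               exclusive = if (length(present_habs) == 1L) present_habs
                           else NA_character_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$q <- bh_fdr(out$p)
  out[, c("pathway", "chisq", "df", "p", "q", "exclusive")]
}

# parse the comma-separated algorithm field into counts
n_algorithms <- function(algorithms) {
  lengths(strsplit(as.character(algorithms), ",", fixed = TRUE))
}

#' Consensus-filter CAZyme annotations
#'
#' Keeps hits supported by at least `min_algorithms` annotation
#' algorithms, preserving row order. Idempotent.
#'
#' @param annotations Data frame with columns `protein_id`, `genome_id`,
#'   `family`, `algorithms` (comma-separated algorithm names).
#' @param min_algorithms Minimum number of supporting algorithms.
#' @return Filtered data frame.
#' @export
cazy_consensus_filter <- function(annotations, min_algorithms = 2) {
  if (nrow(annotations) == 0L) return(annotations)
  annotations[n_algorithms(annotations$algorithms) >= min_algorithms, ,
              drop = FALSE]
}

#' Collate CAZyme annotations into a family x genome count table
#'
#' @param annotations (Filtered) annotation data frame.
#' @param genome_ids Optional genome universe (zero columns kept for
#'   genomes without hits).
#' @return Family x genome integer matrix.
#' @export
cazy_family_counts <- function(annotations, genome_ids = NULL) {
  if (is.null(genome_ids)) genome_ids <- sort(unique(annotations$genome_id))
  fams <- sort(unique(annotations$family))
  tab <- table(factor(annotations$family, levels = fams),
               factor(annotations$genome_id, levels = genome_ids))
  m <- matrix(as.integer(tab), nrow = length(fams),
              dimnames = list(fams, genome_ids))
  m
}

#' Substrate-level CAZyme profile and guild comparison
#'
#' Rolls family counts up to substrates (a family serving several
#' substrates contributes its full count to each), then compares
#' ectomycorrhizal- against saprotrophic-guild genomes per substrate with
#' a two-sided rank-sum test, FDR-corrected; substrates below the
#' threshold are starred.
#'
#' @param annotations CAZyme annotation data frame (consensus-filter it
#'   first with [cazy_consensus_filter()]).
#' @param substrate_map Named list, substrate -> CAZyme families.
#' @param genome_guilds Named guild vector (`"ectomycorrhizal"`,
#'   `"saprotrophic"`, other/`NA` ignored).
#' @param alpha Star threshold on q-values.
#' @return List with `substrate_counts` (substrate x genome matrix) and
#'   `comparison` (data frame: substrate, mean per guild, p, q, starred;
#'   substrates with no mapped family present are reported with `NA`
#'   statistics).
#' @export
substrate_profile <- function(annotations, substrate_map, genome_guilds,
                              alpha = 0.05) {
  guilds <- genome_guilds[!is.na(genome_guilds) &
                            genome_guilds %in% c("ectomycorrhizal",
                                                 "saprotrophic")]
  if (!length(guilds)) abort_fmt("no genomes with ectomycorrhizal/saprotrophic guild labels")
  fam <- cazy_family_counts(annotations, genome_ids = names(guilds))
  sub_counts <- t(vapply(substrate_map, function(fams) {
    hit <- intersect(fams, rownames(fam))
    if (!length(hit)) return(rep(NA_real_, ncol(fam)))
    colSums(fam[hit, , drop = FALSE])
  }, numeric(ncol(fam))))
  colnames(sub_counts) <- colnames(fam)
  ecto <- names(guilds)[guilds == "ectomycorrhizal"]
  sapro <- names(guilds)[guilds == "saprotrophic"]
  comp <- lapply(rownames(sub_counts), function(s) {
    x <- sub_counts[s, ecto]; y <- sub_counts[s, sapro]
    if (all(is.na(x)) || all(is.na(y))) {
      return(data.frame(substrate = s, mean_ecto = NA_real_,
                        mean_sapro = NA_real_, p = NA_real_,
                        stringsAsFactors = FALSE))
    }
    p <- suppressWarnings(stats::wilcox.test(x, y)$p.value)
    data.frame(substrate = s, mean_ecto = mean(x), mean_sapro = mean(y),
               p = p, stringsAsFactors = FALSE)
  })
  comp <- do.call(rbind, comp)
  comp$q <- NA_real_
  ok <- !is.na(comp$p)
  comp$q[ok] <- bh_fdr(comp$p[ok])
  comp$starred <- !is.na(comp$q) & comp$q < alpha
  list(substrate_counts = sub_counts, comparison = comp)
}
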