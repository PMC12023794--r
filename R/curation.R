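# Genome-set curation: five-rule quality filtering, per-species-and-habitat
# subsampling, and ANI-based dereplication. Thresholds follow the standard
# high-quality-genome reading: strictly-below-95% completeness, strictly-above
# -5% contamination, at least 90% of the 92 single-copy marker genes
# (ceiling: >= 83), at least 85% coding fraction, and strict ANI > 99.995%
# with alignment fraction > 90% for redundancy.

CURATION_RULES <- c("site", "completeness", "contamination",
                    "single_copy", "coding")

check_records <- function(records) {
  need <- c("genome_id", "habitat", "species", "isolation_site_known",
            "completeness", "contamination", "single_copy_hits",
            "coding_fraction")
  miss <- setdiff(need, names(records))
  if (length(miss)) abort_fmt("records missing columns: %s",
                              paste(miss, collapse = ", "))
  if (anyDuplicated(records$genome_id)) abort_fmt("duplicate genome ids in records")
  invisible(records)
}

#' Quality-filter genome records
#'
#' Applies the five quality rules in fixed order — known isolation site,
#' completeness >= 95, contamination <= 5, single-copy marker hits >= 83
#' (90% of 92, ceiling), coding fraction >= 85 — attributing each removal
#' to the first failing rule.
#'
#' @param records Genome metadata data frame (see [simulate_dataset()] for
#'   the column contract).
#' @param min_completeness,max_contamination,min_single_copy,min_coding
#'   Rule thresholds; records pass when `completeness >= min_completeness`,
#'   `contamination <= max_contamination`, `single_copy_hits >=
#'   min_single_copy`, `coding_fraction >= min_coding`.
#' @return List with `kept` (data frame of passing records) and `report`
#'   (a `curation_report`: per-rule removal counts, removed ids by rule).
#' @examples
#' ds <- simulate_dataset(sim_config(n_tips = 20, n_genes = 10,
#'                                   qc_fail_spec = list(completeness = 2)))
#' filter_quality(ds$records)$report
#' @export
filter_quality <- function(records, min_completeness = 95,
                           max_contamination = 5, min_single_copy = 83,
                           min_coding = 85) {
  check_records(records)
  if (nrow(records) == 0L) abort_fmt("records is empty")
  fails <- list(
    site = !records$isolation_site_known,
    completeness = records$completeness < min_completeness,
    contamination = records$contamination > max_contamination,
    single_copy = records$single_copy_hits < min_single_copy,
    coding = records$coding_fraction < min_coding)
  # first failing rule wins the attribution
  attributed <- rep(NA_character_, nrow(records))
  for (rule in CURATION_RULES) {
    hit <- fails[[rule]] & is.na(attributed)
    attributed[hit] <- rule
  }
  kept <- records[is.na(attributed), , drop = FALSE]
  removed <- lapply(stats::setNames(CURATION_RULES, CURATION_RULES),
                    function(r) records$genome_id[!is.na(attributed) &
                                                    attributed == r])
  report <- structure(list(
    n_input = nrow(records),
    removed_by_rule = vapply(removed, length, integer(1)),
    removed_ids = removed,
    kept_ids = kept$genome_id), class = "curation_report")
  list(kept = kept, report = report)
}

#' @export
print.curation_report <- function(x, ...) {
  cat("Genome curation report\n")
  cat(sprintf("  input: %d, kept: %d\n", x$n_input, length(x$kept_ids)))
  for (r in names(x$removed_by_rule)) {
    cat(sprintf("  removed by %-13s %d\n", paste0(r, ":"),
                x$removed_by_rule[[r]]))
  }
  if (!is.null(x$seed)) cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}

#' Subsample genomes per species and habitat
#'
#' Within each (species, habitat) group keeps at most `max_per` genomes,
#' chosen uniformly at random; smaller groups pass unchanged.
#'
#' @param records Genome metadata data frame.
#' @param max_per Maximum genomes retained per species x habitat group.
#' @param seed Optional integer seed.
#' @return Data frame of kept records (original order preserved).
#' @export
subsample_species <- function(records, max_per = 5, seed = NULL) {
  check_records(records)
  check_scalar_number(max_per, "max_per", min = 1)
  grp <- interaction(records$species, records$habitat, drop = TRUE)
  keep <- with_seed(seed, {
    sel <- logical(nrow(records))
    for (g in levels(grp)) {
      at <- which(grp == g)
      if (length(at) <= max_per) sel[at] <- TRUE
      else sel[sample(at, max_per)] <- TRUE
    }
    sel
  })
  records[keep, , drop = FALSE]
}

#' Dereplicate genomes by average nucleotide identity
#'
#' Marks a pair redundant when `ani > ani_thr` and `af > af_thr` (strict
#' inequalities), builds the redundancy graph, and keeps exactly one
#' randomly chosen representative per connected component, so chains of
#' near-identical genomes collapse deterministically given the seed.
#'
#' @param records Genome metadata data frame.
#' @param ani_pairs Data frame with columns `genome_a`, `genome_b`, `ani`,
#'   `af` (fractions in \[0, 1\]).
#' @param ani_thr,af_thr Redundancy thresholds (strict).
#' @param seed Optional integer seed.
#' @return List with `kept` (data frame), `removed_ids`, and
#'   `redundant_groups` (list of component memberships of size >= 2).
#' @export
deduplicate_ani <- function(records, ani_pairs, ani_thr = 0.99995,
                            af_thr = 0.90, seed = NULL) {
  check_records(records)
  need <- c("genome_a", "genome_b", "ani", "af")
  if (!all(need %in% names(ani_pairs))) {
    abort_fmt("ani_pairs must have columns %s", paste(need, collapse = ", "))
  }
  unknown <- setdiff(c(ani_pairs$genome_a, ani_pairs$genome_b),
                     records$genome_id)
  if (length(unknown)) {
    abort_fmt("ani_pairs references unknown genomes: %s",
              paste(utils::head(unknown, 3), collapse = ", "))
  }
  red <- ani_pairs[ani_pairs$ani > ani_thr & ani_pairs$af > af_thr, ,
                   drop = FALSE]
  if (nrow(red) == 0L) {
    return(list(kept = records, removed_ids = character(0),
                redundant_groups = list()))
  }
  g <- igraph::graph_from_data_frame(red[, c("genome_a", "genome_b")],
                                     directed = FALSE)
  comp <- igraph::components(g)
  groups <- split(names(comp$membership), comp$membership)
  reps <- with_seed(seed, vapply(groups, function(m) {
    if (length(m) == 1L) m else sample(m, 1L)
  }, character(1)))
  removed <- setdiff(unlist(groups), reps)
  list(kept = records[!(records$genome_id %in% removed), , drop = FALSE],
       removed_ids = removed,
       redundant_groups = unname(groups))
}

#' Run the full genome curation procedure
#'
#' Quality filtering, species subsampling, and ANI dereplication in the
#' fixed order of the selection protocol, with every removal attributed to
#' exactly one step.
#'
#' @inheritParams filter_quality
#' @inheritParams deduplicate_ani
#' @param max_per Species x habitat subsampling cap.
#' @param seed Integer seed driving subsampling and dedup representative
#'   choice.
#' @return List with `kept` and a `curation_report` whose counts reconcile
#'   with the input size.
#' @export
curate_genomes <- function(records, ani_pairs = NULL, min_completeness = 95,
                           max_contamination = 5, min_single_copy = 83,
                           min_coding = 85, max_per = 5, ani_thr = 0.99995,
                           af_thr = 0.90, seed = NULL) {
  fq <- filter_quality(records, min_completeness, max_contamination,
                       min_single_copy, min_coding)
  sub <- subsample_species(fq$kept, max_per = max_per, seed = seed)
  n_sub <- nrow(fq$kept) - nrow(sub)
  if (!is.null(ani_pairs)) {
    pairs_known <- ani_pairs[ani_pairs$genome_a %in% sub$genome_id &
                               ani_pairs$genome_b %in% sub$genome_id, ,
                             drop = FALSE]
    dd <- deduplicate_ani(sub, pairs_known, ani_thr, af_thr, seed = seed)
  } else {
    dd <- list(kept = sub, removed_ids = character(0),
               redundant_groups = list())
  }
  report <- structure(list(
    n_input = nrow(records),
    removed_by_rule = c(fq$report$removed_by_rule,
                        subsample = n_sub,
                        dedup = length(dd$removed_ids)),
    removed_ids = c(fq$report$removed_ids,
                    list(subsample = setdiff(fq$kept$genome_id,
                                             sub$genome_id),
                         dedup = dd$removed_ids)),
    kept_ids = dd$kept$genome_id,
    redundant_groups = dd$redundant_groups,
    seed = seed), class = "curation_report")
  stopifnot(length(report$kept_ids) + sum(report$removed_by_rule) ==
              report$n_input)
  list(kept = dd$kept, report = report)
}
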