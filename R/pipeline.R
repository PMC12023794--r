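# End-to-end pipeline driver: curation -> clustering -> enrichment ->
# association -> functional profiles -> ordination, each stage writing its
# outputs before the next starts, with a JSON run manifest recording
# checksums for reproducibility.

#' Pipeline configuration
#'
#' @param input_dir Directory with the dataset files (see [read_tables()]).
#' @param output_dir Directory for stage outputs and the manifest.
#' @param stages Character vector of stages to run, in fixed order; any of
#'   `"curate"`, `"cluster"`, `"enrich"`, `"associate"`, `"pathways"`,
#'   `"cazymes"`, `"ordinate"`.
#' @param seed Integer seed recorded in the manifest and used by every
#'   stochastic stage.
#' @param thresholds Named list overriding defaults: `min_completeness`,
#'   `max_contamination`, `min_single_copy`, `min_coding`, `max_per`,
#'   `ani_thr`, `af_thr`, `k_range`, `linkage`, `lambda`, `alpha`,
#'   `presence_min`, `min_algorithms`, `n_perm`.
#' @return Object of class `fab_pipeline_config`.
#' @export
pipeline_config <- function(input_dir, output_dir,
                            stages = c("curate", "cluster", "enrich",
                                       "associate", "pathways", "cazymes",
                                       "ordinate"),
                            seed = 1L, thresholds = list()) {
  known <- c("curate", "cluster", "enrich", "associate", "pathways",
             "cazymes", "ordinate")
  stages <- known[known %in% stages]
  defaults <- list(min_completeness = 95, max_contamination = 5,
                   min_single_copy = 83, min_coding = 85, max_per = 5,
                   ani_thr = 0.99995, af_thr = 0.90, k_range = c(2, 10),
                   linkage = "complete", lambda = "ml", alpha = 0.05,
                   presence_min = 1, min_algorithms = 2, n_perm = 999)
  defaults[names(thresholds)] <- thresholds
  structure(list(input_dir = input_dir, output_dir = output_dir,
                 stages = stages, seed = as.integer(seed),
                 thresholds = defaults), class = "fab_pipeline_config")
}

#' Run the comparative-genomics pipeline
#'
#' Executes the enabled stages in order on the curated genome set (or the
#' unfiltered set when curation is disabled, flagged in the manifest).
#' Every stage writes plain-text outputs before the next stage starts; the
#' manifest (JSON) is written last and records the configuration, per-file
#' MD5 checksums, timestamps, and warnings.
#'
#' @param config A [pipeline_config()].
#' @return The manifest, invisibly (also written to
#'   `output_dir/manifest.json`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "fab_pipeline_config"))
  thr <- config$thresholds
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  data <- read_tables(config$input_dir)
  manifest <- list(tool = "fabgenomics",
                   version = as.character(utils::packageVersion("fabgenomics")),
                   seed = config$seed, stages = list(), warnings = list(),
                   started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  outputs <- character(0)
  note <- function(stage, files) {
    manifest$stages[[stage]] <<- list(
      outputs = as.list(unname(files)),
      md5 = as.list(unname(tools::md5sum(files))),
      finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
    outputs <<- c(outputs, files)
  }
  op <- function(name) file.path(config$output_dir, name)
  habitats <- stats::setNames(data$records$habitat, data$records$genome_id)

  kept <- data$records
  if ("curate" %in% config$stages) {
    cur <- curate_genomes(data$records, data$ani_pairs,
                          min_completeness = thr$min_completeness,
                          max_contamination = thr$max_contamination,
                          min_single_copy = thr$min_single_copy,
                          min_coding = thr$min_coding,
                          max_per = thr$max_per, ani_thr = thr$ani_thr,
                          af_thr = thr$af_thr, seed = config$seed)
    kept <- cur$kept
    writeLines(kept$genome_id, op("kept_ids.txt"))
    jsonlite::write_json(
      list(n_input = cur$report$n_input,
           removed_by_rule = as.list(cur$report$removed_by_rule),
           kept = cur$report$kept_ids, seed = config$seed),
      op("curation_report.json"), auto_unbox = TRUE, digits = NA)
    note("curate", c(op("kept_ids.txt"), op("curation_report.json")))
  } else {
    manifest$warnings <- c(manifest$warnings,
                           "curation disabled: downstream stages use the unfiltered genome set")
  }
  ids <- kept$genome_id
  tree <- ape::keep.tip(data$tree, intersect(data$tree$tip.label, ids))
  counts <- data$counts[, intersect(colnames(data$counts), ids),
                        drop = FALSE]
  habitats <- habitats[ids]

  if ("cluster" %in% config$stages) {
    d <- cophenetic_distances(tree)
    sel <- select_k(d, k_min = thr$k_range[1L],
                    k_max = min(thr$k_range[2L], nrow(d) - 1L),
                    linkage = thr$linkage, seed = config$seed)
    write_tsv(data.frame(genome_id = names(sel$assignment$labels),
                         cluster = unname(sel$assignment$labels)),
              op("clusters.tsv"))
    jsonlite::write_json(list(k_best = sel$k_best,
                              silhouette = as.list(sel$silhouette),
                              gap = as.list(sel$gap)),
                         op("cluster_selection.json"), auto_unbox = TRUE,
                         digits = NA)
    note("cluster", c(op("clusters.tsv"), op("cluster_selection.json")))
  }

  if ("enrich" %in% config$stages) {
    enr <- enrich_all(counts, habitats, tree,
                      category_map = data$category_map,
                      lambda = thr$lambda)
    write_tsv(enr$genes, op("enrichment_genes.tsv"))
    write_tsv(enr$categories, op("enrichment_categories.tsv"))
    note("enrich", c(op("enrichment_genes.tsv"),
                     op("enrichment_categories.tsv")))
  }

  if ("associate" %in% config$stages) {
    assoc <- associate_genes(counts, habitats,
                             presence_min = thr$presence_min)
    called <- call_specific_genes(assoc, alpha = thr$alpha)
    write_tsv(called$specific, op("association.tsv"))
    note("associate", op("association.tsv"))
  }

  if ("pathways" %in% config$stages) {
    pc <- data$pathway_content[, intersect(colnames(data$pathway_content),
                                           ids), drop = FALSE]
    ct <- pathway_copy_table(pc, data$pathway_defs)
    cmp <- pathway_habitat_comparison(ct, habitats)
    write_tsv(data.frame(genome_id = rownames(ct), ct, check.names = FALSE),
              op("pathway_copies.tsv"))
    write_tsv(cmp, op("pathway_comparison.tsv"))
    note("pathways", c(op("pathway_copies.tsv"),
                       op("pathway_comparison.tsv")))
  }

  if ("cazymes" %in% config$stages) {
    caz <- data$cazyme[data$cazyme$genome_id %in% ids, , drop = FALSE]
    caz <- cazy_consensus_filter(caz, min_algorithms = thr$min_algorithms)
    guilds <- stats::setNames(kept$guild, kept$genome_id)
    if (any(!is.na(guilds) & guilds %in% c("ectomycorrhizal",
                                           "saprotrophic"))) {
      prof <- substrate_profile(caz, data$substrate_map, guilds,
                                alpha = thr$alpha)
      write_tsv(prof$comparison, op("substrate_comparison.tsv"))
      note("cazymes", op("substrate_comparison.tsv"))
    } else {
      manifest$warnings <- c(manifest$warnings,
                             "cazymes stage skipped: no guild labels")
    }
  }

  if ("ordinate" %in% config$stages) {
    d <- bray_curtis(counts)
    # PERMANOVA needs >= 2 genomes per habitat; drop and flag the rest
    sizes <- table(habitats)
    small <- names(sizes)[sizes < 2]
    ord_hab <- habitats[!(habitats %in% small)]
    if (length(small)) {
      manifest$warnings <- c(manifest$warnings,
                             sprintf("ordination excludes habitats with < 2 genomes: %s",
                                     paste(small, collapse = ", ")))
    }
    pv <- permanova_dbrda(d[names(ord_hab), names(ord_hab)], ord_hab,
                          n_perm = thr$n_perm, seed = config$seed)
    emb <- pcoa(d, n_axes = 2)
    write_tsv(data.frame(genome_id = rownames(emb$coordinates),
                         emb$coordinates, check.names = FALSE),
              op("pcoa_coordinates.tsv"))
    jsonlite::write_json(list(R2 = pv$R2, F = pv$F, p = pv$p,
                              n_perm = pv$n_perm, dbrda_R2 = pv$dbrda_R2,
                              seed = config$seed),
                         op("ordination_stats.json"), auto_unbox = TRUE,
                         digits = NA)
    note("ordinate", c(op("pcoa_coordinates.tsv"),
                       op("ordination_stats.json")))
  }

  manifest$finished <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  jsonlite::write_json(manifest, file.path(config$output_dir,
                                           "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
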