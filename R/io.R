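# Plain-text I/O: every intermediate is TSV (header line, '#' comments),
# newick, or JSON, so any stage can be re-run in isolation and inputs
# survive hand editing.

read_tsv_checked <- function(path, required, what) {
  if (!file.exists(path)) abort_fmt("%s file not found: %s", what, path)
  df <- tryCatch(
    utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                      check.names = FALSE),
    error = function(e) abort_fmt("malformed %s file %s: %s", what, path,
                                  conditionMessage(e)))
  miss <- setdiff(required, names(df))
  if (length(miss)) {
    abort_fmt("%s file %s lacks columns: %s", what, path,
              paste(miss, collapse = ", "))
  }
  df
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read genome metadata
#' @param path TSV with the [simulate_dataset()] record columns.
#' @return Data frame of genome records.
#' @export
read_genome_metadata <- function(path) {
  df <- read_tsv_checked(path, c("genome_id", "habitat", "species"),
                         "metadata")
  if (anyDuplicated(df$genome_id)) {
    abort_fmt("duplicate genome ids in %s", path)
  }
  if ("isolation_site_known" %in% names(df)) {
    df$isolation_site_known <- as.logical(df$isolation_site_known)
  }
  df
}

#' Read a gene count table (genes as rows, genomes as columns)
#' @param path TSV whose first column holds gene ids.
#' @return Integer matrix genes x genomes.
#' @export
read_gene_counts <- function(path) {
  df <- read_tsv_checked(path, character(0), "gene-count")
  if (anyDuplicated(names(df)[-1L])) {
    abort_fmt("duplicated genome column in %s: %s", path,
              names(df)[-1L][duplicated(names(df)[-1L])][1L])
  }
  if (anyDuplicated(df[[1L]])) abort_fmt("duplicated gene ids in %s", path)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  storage.mode(m) <- "double"
  m
}

#' Write a gene count table
#' @param counts Genes x genomes matrix. @param path Output TSV path.
#' @export
write_gene_counts <- function(counts, path) {
  df <- data.frame(gene = rownames(counts), counts, check.names = FALSE)
  write_tsv(df, path)
}

#' Read pairwise ANI/alignment-fraction values
#' @param path TSV with columns genome_a, genome_b, ani, af.
#' @return Data frame.
#' @export
read_ani_pairs <- function(path) {
  read_tsv_checked(path, c("genome_a", "genome_b", "ani", "af"), "ANI")
}

#' Read CAZyme annotations
#' @param path TSV with columns protein_id, genome_id, family, algorithms.
#' @return Data frame.
#' @export
read_cazyme_annotations <- function(path) {
  read_tsv_checked(path, c("protein_id", "genome_id", "family",
                           "algorithms"), "CAZyme")
}

#' Read pathway definitions
#' @param path Two-column TSV (pathway, gene).
#' @return Named list, pathway -> gene vector.
#' @export
read_pathway_defs <- function(path) {
  df <- read_tsv_checked(path, c("pathway", "gene"), "pathway-definition")
  lapply(split(df$gene, df$pathway), unique)
}

#' Read a substrate-to-family map
#' @param path Two-column TSV (substrate, family).
#' @return Named list, substrate -> family vector.
#' @export
read_substrate_map <- function(path) {
  df <- read_tsv_checked(path, c("substrate", "family"), "substrate-map")
  lapply(split(df$family, df$substrate), unique)
}

#' Write a synthetic dataset to plain-text files
#'
#' Serializes tree (newick), metadata, gene counts, ANI pairs, CAZyme
#' annotations, pathway content and definitions, substrate map, category
#' map, and the ground truth (JSON) into a directory.
#'
#' @param dataset A `fab_dataset` from [simulate_dataset()].
#' @param dir Output directory (created if missing).
#' @return Named character vector of written paths, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "fab_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    tree = file.path(dir, "tree.nwk"),
    metadata = file.path(dir, "metadata.tsv"),
    counts = file.path(dir, "gene_counts.tsv"),
    ani = file.path(dir, "ani_pairs.tsv"),
    cazyme = file.path(dir, "cazyme_annotations.tsv"),
    pathway_content = file.path(dir, "pathway_counts.tsv"),
    pathway_defs = file.path(dir, "pathway_defs.tsv"),
    substrate_map = file.path(dir, "substrate_map.tsv"),
    category_map = file.path(dir, "category_map.tsv"),
    truth = file.path(dir, "truth.json"))
  ape::write.tree(dataset$tree, paths["tree"])
  write_tsv(dataset$records, paths["metadata"])
  write_gene_counts(dataset$counts, paths["counts"])
  write_tsv(dataset$ani_pairs, paths["ani"])
  write_tsv(dataset$cazyme, paths["cazyme"])
  write_gene_counts(dataset$pathway_content, paths["pathway_content"])
  write_tsv(data.frame(
    pathway = rep(names(dataset$pathway_defs),
                  lengths(dataset$pathway_defs)),
    gene = unlist(dataset$pathway_defs, use.names = FALSE)),
    paths["pathway_defs"])
  write_tsv(data.frame(
    substrate = rep(names(dataset$substrate_map),
                    lengths(dataset$substrate_map)),
    family = unlist(dataset$substrate_map, use.names = FALSE)),
    paths["substrate_map"])
  write_tsv(dataset$category_map, paths["category_map"])
  truth <- dataset$truth
  truth$effects <- list(gene = rownames(truth$effects),
                        habitat = colnames(truth$effects),
                        matrix = unname(truth$effects))
  jsonlite::write_json(truth, paths["truth"], auto_unbox = TRUE,
                       digits = NA)
  invisible(paths)
}

#' Read and cross-validate a dataset directory
#'
#' Parses the files written by [write_dataset()] (or equivalently laid-out
#' external exports) and cross-validates the id sets: tree tips, metadata
#' genome ids, and count columns must agree; ANI pairs and CAZyme
#' annotations must reference known genomes.
#'
#' @param dir Directory holding the dataset files.
#' @return List with `tree`, `records`, `counts`, `ani_pairs`, `cazyme`,
#'   `pathway_content`, `pathway_defs`, `substrate_map`, `category_map`.
#' @export
read_tables <- function(dir) {
  tree_path <- file.path(dir, "tree.nwk")
  if (!file.exists(tree_path)) abort_fmt("tree file not found: %s", tree_path)
  tree <- tryCatch(ape::read.tree(tree_path), error = function(e)
    abort_fmt("malformed newick in %s: %s", tree_path, conditionMessage(e)))
  records <- read_genome_metadata(file.path(dir, "metadata.tsv"))
  counts <- read_gene_counts(file.path(dir, "gene_counts.tsv"))
  orphan_tips <- setdiff(tree$tip.label, records$genome_id)
  if (length(orphan_tips)) {
    abort_fmt("tree tips absent from metadata: %s",
              paste(utils::head(orphan_tips, 5), collapse = ", "))
  }
  orphan_cols <- setdiff(colnames(counts), records$genome_id)
  if (length(orphan_cols)) {
    abort_fmt("count columns absent from metadata: %s",
              paste(utils::head(orphan_cols, 5), collapse = ", "))
  }
  ani <- read_ani_pairs(file.path(dir, "ani_pairs.tsv"))
  bad <- setdiff(c(ani$genome_a, ani$genome_b), records$genome_id)
  if (length(bad)) {
    abort_fmt("ANI pairs reference unknown genomes: %s",
              paste(utils::head(bad, 5), collapse = ", "))
  }
  list(tree = tree, records = records, counts = counts, ani_pairs = ani,
       cazyme = read_cazyme_annotations(file.path(dir,
                                                  "cazyme_annotations.tsv")),
       pathway_content = read_gene_counts(file.path(dir,
                                                    "pathway_counts.tsv")),
       pathway_defs = read_pathway_defs(file.path(dir, "pathway_defs.tsv")),
       substrate_map = read_substrate_map(file.path(dir,
                                                    "substrate_map.tsv")),
       category_map = read_tsv_checked(file.path(dir, "category_map.tsv"),
                                       c("gene", "category"), "category-map"))
}
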