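# Bundled reference tables.

#' Per-habitat genome counts of the reference dataset
#'
#' The curated comparative dataset behind this package compares
#' fungus-associated bacteria against bacteria from plants, humans, soil,
#' and water; this table holds the number of genomes per habitat after
#' curation. Summing it reproduces the curated analysis-set size.
#'
#' @return Data frame with columns `habitat`, `n_genomes`.
#' @examples
#' sum(reference_habitat_counts()$n_genomes)
#' @export
reference_habitat_counts <- function() {
  path <- system.file("extdata", "habitat_genome_counts.tsv",
                      package = "fabgenomics", mustWork = TRUE)
  read_tsv_checked(path, c("habitat", "n_genomes"), "habitat-counts")
}
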