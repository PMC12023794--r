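# Synthetic-data generator: habitat-labelled genome collections with known
# ground truth, so every downstream stage (curation, clustering, enrichment,
# association, profiling, ordination) can be tested without external data.

FAB_HABITATS <- c("fungi", "plants", "humans", "soil", "water")
FAB_ALGORITHMS <- c("HMMER", "DIAMOND", "eCAMI")

# Sampling weights for random habitat assignment: proportional to the
# per-habitat genome counts of the reference comparative dataset
# (see inst/extdata/habitat_genome_counts.tsv).
FAB_HABITAT_WEIGHTS <- c(fungi = 163, plants = 316, humans = 212,
                         soil = 284, water = 236)

habitat_names <- function(n) {
  if (n <= length(FAB_HABITATS)) return(FAB_HABITATS[seq_len(n)])
  c(FAB_HABITATS, paste0("habitat", seq(length(FAB_HABITATS) + 1L, n)))
}

#' Simulation configuration
#'
#' Bundles and validates every knob of the synthetic-data generator. The
#' defaults describe the study conditions the package is designed around:
#' five habitats with sampling weights proportional to the reference
#' dataset's per-habitat genome counts, a Yule tree with unit birth rate,
#' baseline gene copy number 5 on the log link, and a Brownian-motion
#' genome effect of variance 0.05 per unit branch length (about 0.25 at
#' the tips for typical Yule tree heights, strong enough to confound naive
#' tests while keeping the count scale approximately log-linear).
#'
#' @param n_tips Number of genomes (tree tips).
#' @param birth_rate Per-lineage speciation rate of the Yule tree.
#' @param n_habitats Number of habitat labels.
#' @param habitat_mode `"random"` (labels exchangeable with respect to the
#'   tree) or `"clade_confounded"` (each habitat is one clade, obtained by
#'   cutting the tree at its deepest internal nodes).
#' @param n_genes Number of gene orthologs simulated.
#' @param baseline_log_mean Log expected copy number per gene (scalar or
#'   length-`n_genes` vector).
#' @param bm_sigma2 Brownian-motion variance per unit branch length of the
#'   per-gene genome effect (>= 0).
#' @param effect_table Planted habitat effects: a data frame with columns
#'   `gene` (index or name), `habitat`, `effect` (additive on the log link),
#'   or `NULL` for no planted signal.
#' @param n_duplicates Number of near-clone genomes injected (with ANI/AF
#'   above the dereplication thresholds against their source).
#' @param qc_fail_spec Named list giving counts of designed quality-control
#'   failures among `site`, `completeness`, `contamination`, `single_copy`,
#'   `coding`.
#' @param plant_substrate_boost Additive mean shift of plant-substrate CAZyme
#'   family counts in ectomycorrhizal-guild genomes (0 = no guild signal).
#' @param p_single_algorithm Probability that a CAZyme hit is supported by
#'   only one annotation algorithm (and so fails consensus filtering).
#' @param seed Integer seed; the whole dataset is a pure function of the
#'   configuration including this seed.
#' @return An object of class `fab_sim_config` (a validated list).
#' @export
sim_config <- function(n_tips = 1211, birth_rate = 1, n_habitats = 5,
                       habitat_mode = c("random", "clade_confounded"),
                       n_genes = 500, baseline_log_mean = log(5),
                       bm_sigma2 = 0.05, effect_table = NULL,
                       n_duplicates = 0, qc_fail_spec = list(),
                       plant_substrate_boost = 0,
                       p_single_algorithm = 0.2, seed = 1L) {
  habitat_mode <- match.arg(habitat_mode)
  check_scalar_number(n_tips, "n_tips", min = 2)
  check_scalar_number(n_genes, "n_genes", min = 0)
  check_scalar_number(n_habitats, "n_habitats", min = 2)
  check_scalar_number(birth_rate, "birth_rate", min = 0)
  check_scalar_number(bm_sigma2, "bm_sigma2", min = 0)
  check_scalar_number(n_duplicates, "n_duplicates", min = 0)
  if (!is.null(effect_table)) {
    stopifnot(is.data.frame(effect_table),
              all(c("gene", "habitat", "effect") %in% names(effect_table)))
    if (!all(effect_table$habitat %in% habitat_names(n_habitats))) {
      abort_fmt("effect_table refers to unknown habitats")
    }
  }
  known_qc <- c("site", "completeness", "contamination", "single_copy", "coding")
  if (length(qc_fail_spec) &&
      (is.null(names(qc_fail_spec)) || !all(names(qc_fail_spec) %in% known_qc))) {
    abort_fmt("qc_fail_spec names must be among: %s",
              paste(known_qc, collapse = ", "))
  }
  structure(list(
    n_tips = as.integer(n_tips), birth_rate = birth_rate,
    n_habitats = as.integer(n_habitats), habitat_mode = habitat_mode,
    n_genes = as.integer(n_genes), baseline_log_mean = baseline_log_mean,
    bm_sigma2 = bm_sigma2, effect_table = effect_table,
    n_duplicates = as.integer(n_duplicates), qc_fail_spec = qc_fail_spec,
    plant_substrate_boost = plant_substrate_boost,
    p_single_algorithm = p_single_algorithm, seed = as.integer(seed)
  ), class = "fab_sim_config")
}

#' Simulate an ultrametric Yule tree
#'
#' Pure-birth tree with `n_tips` labelled tips; identical seeds give
#' byte-identical newick strings.
#'
#' @param n_tips Number of tips (>= 1).
#' @param birth_rate Speciation rate.
#' @param seed Optional integer seed.
#' @return An `ape::phylo` tree, rooted and ultrametric, tips
#'   `g0001`, `g0002`, ...
#' @examples
#' tr <- simulate_tree(10, seed = 1)
#' @export
simulate_tree <- function(n_tips, birth_rate = 1, seed = NULL) {
  check_scalar_number(n_tips, "n_tips", min = 1)
  n_tips <- as.integer(n_tips)
  labels <- sprintf("g%04d", seq_len(n_tips))
  if (n_tips == 1L) {
    tr <- ape::read.tree(text = "(g0001:0);")
    return(tr)
  }
  tr <- with_seed(seed, ape::rphylo(n_tips, birth = birth_rate, death = 0))
  tr$tip.label <- labels
  tr
}

#' Simulate a tree of well-separated clades
#'
#' Builds `n_clades` Yule subtrees of height 1 and grafts them onto a star
#' backbone with stem length `separation - 1`, so the ratio of
#' between-clade (`2 * separation`) to maximal within-clade (2) cophenetic
#' distance equals `separation`. Used to test cluster-number recovery under planted
#' phylogenetic structure.
#'
#' @param n_clades Number of clades (>= 2).
#' @param tips_per_clade Tips in each clade (>= 2).
#' @param separation Between-to-within cophenetic distance ratio (> 1).
#' @param seed Optional integer seed.
#' @return An `ape::phylo` tree with `n_clades * tips_per_clade` tips; the
#'   attribute `"clade"` maps tip label to planted clade index.
#' @export
simulate_clustered_tree <- function(n_clades, tips_per_clade, separation = 5,
                                    seed = NULL) {
  check_scalar_number(n_clades, "n_clades", min = 2)
  check_scalar_number(tips_per_clade, "tips_per_clade", min = 2)
  check_scalar_number(separation, "separation", min = 1)
  with_seed(seed, {
    stem <- separation - 1
    parts <- vapply(seq_len(n_clades), function(i) {
      s <- ape::rphylo(tips_per_clade, birth = 1, death = 0)
      # rescale clade to height 1 so within-clade distance is at most 2
      s$edge.length <- s$edge.length / max(ape::node.depth.edgelength(s))
      s$tip.label <- sprintf("c%02d_t%03d", i, seq_len(tips_per_clade))
      paste0(sub(";$", "", ape::write.tree(s)), ":", format(stem))
    }, character(1))
    tr <- ape::read.tree(text = paste0("(", paste(parts, collapse = ","),
                                       ");"))
    clade <- rep(seq_len(n_clades), each = as.integer(tips_per_clade))
    names(clade) <- sprintf("c%02d_t%03d", clade,
                            rep(seq_len(tips_per_clade), n_clades))
    attr(tr, "clade") <- clade[tr$tip.label]
    tr
  })
}

#' Assign habitat labels to tree tips
#'
#' @param tree `ape::phylo` tree.
#' @param n_habitats Number of habitats (<= number of tips).
#' @param habitat_mode `"random"` draws labels independently of the tree
#'   (weights proportional to the reference dataset's habitat sizes);
#'   `"clade_confounded"` makes each habitat one clade by cutting the
#'   ultrametric tree at its `n_habitats - 1` deepest internal nodes, the
#'   worst case of phylogeny-habitat collinearity.
#' @param seed Optional integer seed.
#' @param weights Optional sampling weights for random mode (recycled over
#'   habitats); defaults to the reference dataset proportions.
#' @return Named character vector, tip label -> habitat.
#' @export
assign_habitats <- function(tree, n_habitats,
                            habitat_mode = c("random", "clade_confounded"),
                            seed = NULL, weights = NULL) {
  habitat_mode <- match.arg(habitat_mode)
  tips <- tree$tip.label
  n <- length(tips)
  check_scalar_number(n_habitats, "n_habitats", min = 1)
  if (n_habitats > n) abort_fmt("n_habitats (%d) exceeds number of tips (%d)",
                                n_habitats, n)
  habs <- habitat_names(n_habitats)
  if (n_habitats == 1L) {
    out <- rep(habs, n); names(out) <- tips
    return(out)
  }
  if (habitat_mode == "random") {
    if (is.null(weights)) {
      weights <- FAB_HABITAT_WEIGHTS[seq_len(min(n_habitats,
                                                 length(FAB_HABITAT_WEIGHTS)))]
      weights <- rep_len(unname(weights), n_habitats)
    }
    out <- with_seed(seed, {
      repeat {
        lab <- sample(habs, n, replace = TRUE, prob = weights)
        if (length(unique(lab)) == n_habitats) break
      }
      lab
    })
  } else {
    # cutting an ultrametric tree at its deepest nodes == cutting the
    # dendrogram reconstructed from cophenetic distances at k groups
    d <- stats::as.dist(ape::cophenetic.phylo(tree))
    hc <- stats::hclust(d, method = "average")
    grp <- stats::cutree(hc, k = n_habitats)
    out <- habs[grp]
  }
  names(out) <- tips
  out
}

# expand an effect_table into an n_genes x n_habitats matrix of log effects
effect_matrix <- function(effect_table, gene_ids, habs) {
  eff <- matrix(0, nrow = length(gene_ids), ncol = length(habs),
                dimnames = list(gene_ids, habs))
  if (is.null(effect_table) || nrow(effect_table) == 0L) return(eff)
  g <- effect_table$gene
  if (is.numeric(g)) {
    if (any(g < 1 | g > length(gene_ids))) abort_fmt("effect_table gene index out of range")
    g <- gene_ids[g]
  }
  if (!all(g %in% gene_ids)) abort_fmt("effect_table refers to unknown genes")
  if (!all(effect_table$habitat %in% habs)) {
    abort_fmt("effect_table refers to unknown habitats")
  }
  eff[cbind(g, effect_table$habitat)] <- effect_table$effect
  eff
}

#' Simulate gene ortholog counts on a tree
#'
#' For gene g and genome i, `count ~ Poisson(exp(mu_g + b_gi + e_g,h(i)))`
#' where `b_g` is an independent Brownian-motion realization on the tree
#' with variance `bm_sigma2` per unit branch length and `e` the planted
#' habitat effect. This gives per-gene counts carrying both phylogenetic
#' signal and habitat structure.
#'
#' @param tree `ape::phylo` tree.
#' @param habitats Named habitat vector covering all tips.
#' @param n_genes Number of genes.
#' @param baseline_log_mean Scalar or per-gene log baseline.
#' @param bm_sigma2 Brownian variance per unit branch length.
#' @param effect_table Planted effects (see [sim_config()]).
#' @param seed Optional integer seed.
#' @return List with `counts` (genes x genomes integer matrix) and `truth`
#'   (the expanded effect matrix plus the simulation parameters).
#' @export
simulate_gene_counts <- function(tree, habitats, n_genes,
                                 baseline_log_mean = log(5), bm_sigma2 = 0.05,
                                 effect_table = NULL, seed = NULL) {
  tips <- tree$tip.label
  if (!all(tips %in% names(habitats))) {
    abort_fmt("habitats does not cover all tree tips")
  }
  habitats <- habitats[tips]
  habs <- sort(unique(unname(habitats)))
  n <- length(tips)
  n_genes <- as.integer(n_genes)
  gene_ids <- sprintf("COG%04d", seq_len(n_genes))
  if (n_genes == 0L) {
    counts <- matrix(integer(0), nrow = 0, ncol = n,
                     dimnames = list(character(0), tips))
    return(list(counts = counts,
                truth = list(effects = effect_matrix(NULL, character(0), habs),
                             habitats = habitats,
                             baseline_log_mean = baseline_log_mean,
                             bm_sigma2 = bm_sigma2)))
  }
  mu <- rep_len(baseline_log_mean, n_genes)
  eff <- effect_matrix(effect_table, gene_ids, habs)
  counts <- with_seed(seed, {
    if (bm_sigma2 > 0 && n >= 2) {
      V <- ape::vcv(tree)
      R <- chol(V + diag(1e-10 * max(diag(V)), n))
      B <- sqrt(bm_sigma2) * crossprod(R, matrix(stats::rnorm(n * n_genes), n))
    } else {
      B <- matrix(0, n, n_genes)
    }
    eta <- matrix(mu, n_genes, n) + t(B) + eff[, habitats, drop = FALSE]
    m <- matrix(stats::rpois(n_genes * n, exp(eta)), n_genes, n)
    dimnames(m) <- list(gene_ids, tips)
    m
  })
  list(counts = counts,
       truth = list(effects = eff, habitats = habitats,
                    baseline_log_mean = baseline_log_mean,
                    bm_sigma2 = bm_sigma2))
}

#' Built-in CAZyme substrate map
#'
#' Maps metabolic substrates to the CAZyme families acting on them,
#' covering the fungal (chitin, trehalose) and plant (sucrose, cellulose,
#' hemicellulose, starch) substrates central to fungus-associated bacteria.
#' A family may serve several substrates.
#'
#' @return Named list, substrate -> character vector of families.
#' @export
fab_substrate_map <- function() {
  list(
    sucrose       = c("GH32"),
    trehalose     = c("GT4", "GT20", "GH37"),
    cellulose     = c("GH5", "GH6", "GH9"),
    hemicellulose = c("GH10", "GH11", "GH43"),
    chitin        = c("GH18", "GH19", "CE4"),
    starch        = c("GH13", "GH15")
  )
}

fab_plant_substrates <- c("sucrose", "cellulose", "hemicellulose", "starch")

#' Built-in ABC-transporter pathway definitions
#'
#' Small KO-style gene sets emulating ABC-transporter import systems
#' (substrate-binding protein, permease, ATPase), including the
#' galactofuranose-uptake system treated as fungus-habitat-exclusive by the
#' generator.
#'
#' @return Named list, pathway id -> character vector of required genes.
#' @export
fab_pathway_defs <- function() {
  list(
    abc_galactofuranose = c("gfuA", "gfuB", "gfuC"),
    abc_fe_hydroxamate  = c("fhuA", "fhuB", "fhuC", "fhuD"),
    abc_sugar           = c("ugpA", "ugpB", "ugpE"),
    abc_amino_acid      = c("livF", "livG", "livH", "livK")
  )
}

# per-habitat probability that a genome carries the complete pathway
fab_pathway_presence <- function(habs) {
  p <- list(
    abc_galactofuranose = ifelse(habs == "fungi", 0.8, 0),
    abc_fe_hydroxamate  = ifelse(habs == "fungi", 0.9, 0.4),
    abc_sugar           = rep(0.7, length(habs)),
    abc_amino_acid      = rep(0.6, length(habs))
  )
  lapply(p, stats::setNames, habs)
}

#' Simulate a complete synthetic dataset
#'
#' Orchestrates tree, habitat, and gene-count simulation, then injects
#' near-clone genomes (ANI > 99.995%, AF > 90% against their source, counts
#' perturbed in at most 0.1% of genes), designed quality-control failures,
#' CAZyme annotations with 1-3 supporting algorithms per hit, and pathway
#' gene content with planted complete/incomplete and habitat-exclusive
#' pathways. Everything is a pure function of the configuration.
#'
#' @param config A [sim_config()] object.
#' @return Object of class `fab_dataset`: list with `tree`, `records`
#'   (metadata data frame), `counts`, `ani_pairs`, `cazyme`,
#'   `pathway_content`, `pathway_defs`, `substrate_map`, `category_map`,
#'   `truth`, and the `config`.
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "fab_sim_config"))
  cfg <- config
  with_seed(cfg$seed, {
    tree <- simulate_tree(cfg$n_tips, cfg$birth_rate)
    habitats <- assign_habitats(tree, cfg$n_habitats, cfg$habitat_mode)
    sim <- simulate_gene_counts(tree, habitats, cfg$n_genes,
                                cfg$baseline_log_mean, cfg$bm_sigma2,
                                cfg$effect_table)
    counts <- sim$counts
    ids <- tree$tip.label

    # --- near-clone injection -------------------------------------------
    dup_truth <- data.frame(source = character(0), clone = character(0))
    ani_pairs <- data.frame(genome_a = character(0), genome_b = character(0),
                            ani = numeric(0), af = numeric(0))
    if (cfg$n_duplicates > 0) {
      src <- sample(ids, cfg$n_duplicates)
      clones <- paste0(src, "_dup")
      for (j in seq_along(src)) {
        tree <- phytools::bind.tip(tree, clones[j], edge.length = 1e-8,
                                   where = which(tree$tip.label == src[j]),
                                   position = 1e-8)
        col <- counts[, src[j]]
        n_pert <- floor(0.001 * length(col))
        if (n_pert > 0) {
          at <- sample(length(col), n_pert)
          col[at] <- col[at] + 1L
        }
        counts <- cbind(counts, col)
        colnames(counts)[ncol(counts)] <- clones[j]
      }
      habitats <- c(habitats, stats::setNames(habitats[src], clones))
      dup_truth <- data.frame(source = src, clone = clones)
      ani_pairs <- data.frame(
        genome_a = src, genome_b = clones,
        ani = stats::runif(length(src), 0.999956, 0.99999),
        af = stats::runif(length(src), 0.92, 0.99))
    }
    ids <- tree$tip.label
    counts <- counts[, ids, drop = FALSE]
    habitats <- habitats[ids]
    n <- length(ids)

    # background (non-redundant) ANI pairs
    if (n >= 4) {
      nbg <- min(200L, n)
      a <- sample(ids, nbg, replace = TRUE)
      b <- sample(ids, nbg, replace = TRUE)
      keep <- a != b & !(paste(a, b) %in%
                           paste(dup_truth$source, dup_truth$clone))
      bg <- data.frame(genome_a = a[keep], genome_b = b[keep],
                       ani = stats::runif(sum(keep), 0.75, 0.97),
                       af = stats::runif(sum(keep), 0.2, 0.85))
      ani_pairs <- rbind(ani_pairs, bg)
    }

    # --- metadata records ------------------------------------------------
    size_mean <- c(fungi = 5.5e6, plants = 6.5e6, humans = 4.5e6,
                   soil = 5.5e6, water = 4.0e6)
    gc_mean <- c(fungi = 60, plants = 60, humans = 60, soil = 52, water = 52)
    sm <- ifelse(habitats %in% names(size_mean), size_mean[habitats], 5e6)
    gm <- ifelse(habitats %in% names(gc_mean), gc_mean[habitats], 55)
    guild <- rep(NA_character_, n)
    is_fungi <- habitats == "fungi"
    guild[is_fungi] <- sample(c("ectomycorrhizal", "saprotrophic"),
                              sum(is_fungi), replace = TRUE)
    records <- data.frame(
      genome_id = ids,
      habitat = unname(habitats),
      host_type = ifelse(habitats %in% c("fungi", "plants", "humans"),
                         "host_associated", "environmental"),
      species = paste0("sp_", ids),
      isolation_site_known = TRUE,
      completeness = stats::runif(n, 97, 100),
      contamination = stats::runif(n, 0, 2),
      single_copy_hits = sample(88:92, n, replace = TRUE),
      coding_fraction = stats::runif(n, 88, 95),
      genome_size = round(stats::rnorm(n, sm, 4e5)),
      gc_content = stats::rnorm(n, gm, 2.5),
      guild = guild,
      stringsAsFactors = FALSE)
    # clones inherit their source species so dedup, not subsampling, must
    # remove them
    if (nrow(dup_truth)) {
      records$species[match(dup_truth$clone, records$genome_id)] <-
        records$species[match(dup_truth$source, records$genome_id)]
    }

    # designed QC failures, one field per chosen genome
    qc_truth <- list()
    qc_values <- list(
      site = function(df, i) { df$isolation_site_known[i] <- FALSE; df },
      completeness = function(df, i) { df$completeness[i] <- 94.9; df },
      contamination = function(df, i) { df$contamination[i] <- 5.1; df },
      single_copy = function(df, i) { df$single_copy_hits[i] <- 82L; df },
      coding = function(df, i) { df$coding_fraction[i] <- 84.9; df })
    clean <- setdiff(ids, dup_truth$clone)
    avail <- sample(clean)
    for (rule in names(cfg$qc_fail_spec)) {
      k <- cfg$qc_fail_spec[[rule]]
      if (k < 1) next
      if (k > length(avail)) abort_fmt("qc_fail_spec requests more failures than genomes")
      pick <- avail[seq_len(k)]
      avail <- setdiff(avail, pick)
      records <- qc_values[[rule]](records, match(pick, records$genome_id))
      qc_truth[[rule]] <- pick
    }

    # --- CAZyme annotations ---------------------------------------------
    smap <- fab_substrate_map()
    families <- unique(unlist(smap))
    plant_fams <- unique(unlist(smap[fab_plant_substrates]))
    lam <- matrix(1, n, length(families), dimnames = list(ids, families))
    if (cfg$plant_substrate_boost != 0) {
      ecto <- records$genome_id[!is.na(records$guild) &
                                  records$guild == "ectomycorrhizal"]
      lam[ecto, plant_fams] <- lam[ecto, plant_fams] + cfg$plant_substrate_boost
    }
    fam_counts <- matrix(stats::rpois(length(lam), lam), n,
                         dimnames = dimnames(lam))
    idx <- which(fam_counts > 0, arr.ind = TRUE)
    caz_rows <- rep(seq_len(nrow(idx)), fam_counts[idx])
    n_hits <- length(caz_rows)
    n_alg <- ifelse(stats::runif(n_hits) < cfg$p_single_algorithm, 1L,
                    sample(2:3, n_hits, replace = TRUE))
    algs <- vapply(n_alg, function(k)
      paste(sort(sample(FAB_ALGORITHMS, k)), collapse = ","), character(1))
    cazyme <- data.frame(
      protein_id = sprintf("prot%06d", seq_len(n_hits)),
      genome_id = ids[idx[caz_rows, 1L]],
      family = families[idx[caz_rows, 2L]],
      algorithms = algs,
      stringsAsFactors = FALSE)

    # --- pathway gene content -------------------------------------------
    pdefs <- fab_pathway_defs()
    presence <- fab_pathway_presence(habitats)
    pgenes <- unlist(pdefs, use.names = FALSE)
    pathway_content <- matrix(0L, length(pgenes), n,
                              dimnames = list(pgenes, ids))
    for (pw in names(pdefs)) {
      genes <- pdefs[[pw]]
      complete <- stats::runif(n) < presence[[pw]]
      base <- matrix(1L + stats::rpois(length(genes) * n, 0.5),
                     length(genes), n)
      base[, !complete] <- 0L
      # a fraction of incomplete genomes carry a partial (broken) pathway
      partial <- !complete & stats::runif(n) < 0.3
      if (any(partial)) {
        part <- matrix(stats::rpois(length(genes) * sum(partial), 0.7),
                       length(genes), sum(partial))
        drop_gene <- sample(length(genes), sum(partial), replace = TRUE)
        part[cbind(drop_gene, seq_len(sum(partial)))] <- 0L
        base[, partial] <- part
      }
      pathway_content[genes, ] <- base
    }

    # COG functional category map (letters drawn from the standard alphabet)
    cats <- c("C", "E", "G", "J", "K", "L", "M", "N", "P", "T", "R", "S")
    category_map <- data.frame(
      gene = rownames(counts),
      category = sample(cats, nrow(counts), replace = TRUE),
      stringsAsFactors = FALSE)

    structure(list(
      tree = tree, records = records, counts = counts,
      ani_pairs = ani_pairs, cazyme = cazyme,
      pathway_content = pathway_content, pathway_defs = pdefs,
      substrate_map = smap, category_map = category_map,
      truth = list(effects = sim$truth$effects, habitats = habitats,
                   duplicates = dup_truth, qc_failures = qc_truth,
                   pathway_presence = presence),
      config = cfg), class = "fab_dataset")
  })
}

#' @export
print.fab_dataset <- function(x, ...) {
  cat("Synthetic comparative-genomics dataset\n")
  cat(sprintf("  genomes: %d (%d injected near-clones)\n",
              nrow(x$records), nrow(x$truth$duplicates)))
  cat(sprintf("  genes:   %d; habitats: %s\n", nrow(x$counts),
              paste(sort(unique(x$records$habitat)), collapse = ", ")))
  cat(sprintf("  CAZyme hits: %d; pathway genes: %d; ANI pairs: %d\n",
              nrow(x$cazyme), nrow(x$pathway_content), nrow(x$ani_pairs)))
  invisible(x)
}
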