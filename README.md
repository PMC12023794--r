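# fabgenomics

Comparative genomics of habitat-classified bacteria, built around the
question of what distinguishes fungus-associated bacteria (FaB — bacteria
isolated from fruiting bodies, mycelia, and mycorrhizal root tips) from
bacteria of plants, humans, soil, and water.

Given a genome collection with habitat metadata, a phylogeny, per-genome
gene-ortholog (COG) counts, pairwise ANI/alignment-fraction values, and
CAZyme/pathway annotations, the package runs the full analysis chain:

1. **Curation** — five quality rules (isolation site known,
   completeness ≥ 95%, contamination ≤ 5%, ≥ 83 of 92 single-copy
   markers, coding fraction ≥ 85%), per-species×habitat subsampling
   (≤ 5), and ANI dereplication (ANI > 99.995% ∧ AF > 90%, resolved by
   connected components).
2. **Clustering** — cophenetic distances, agglomerative clustering, and
   silhouette/gap selection of the number of taxa.
3. **Phylogeny-aware enrichment** — per-gene generalized least squares
   of standardized copy numbers on one-vs-rest habitat indicators with
   residual covariance σ²·(λV + (1−λ)·diag V), V the Brownian-motion
   covariance of the tree and λ Pagel's lambda (grid ML); BH-FDR within
   each contrast; category-level median effects.
4. **Association** — upper-tail hypergeometric tests
   (score = −log₁₀ p), odds ratios with one-sided Fisher p, CPT
   (counts per thousand genomes) normalization, and habitat-specific gene
   calls by the either-test disjunction rule.
5. **Profiles** — complete-pathway copy numbers (min over required
   genes), chi-squared habitat comparisons, CAZyme two-algorithm
   consensus filtering, and substrate-level ectomycorrhizal versus
   saprotrophic guild comparisons.
6. **Ordination** — Bray–Curtis dissimilarities, PCoA, one-way PERMANOVA
   with permutation p (floored at 1/(n_perm+1)) and dbRDA, plus
   ANOVA/Tukey group summaries with compact-letter displays.

A synthetic-data generator (`sim_config()` / `simulate_dataset()`)
produces complete datasets — Yule tree, habitat labels (exchangeable or
clade-confounded), Poisson gene counts with Brownian phylogenetic signal
and planted habitat effects, injected near-clone genomes, designed QC
failures, CAZyme and pathway content — with the ground truth recorded, so
every downstream claim is testable without external data. See
`vignette("fabgenomics-methods")` for the models, conventions, and design
choices.

## Worked example

Simulate a 150-genome collection in which ten genes carry a +1.5 log-link
enrichment in the fungi habitat, three near-clone genomes and two
designed completeness failures are planted, then curate and analyze:

```r
library(fabgenomics)

cfg <- sim_config(n_tips = 150, n_genes = 120, n_duplicates = 3,
                  qc_fail_spec = list(completeness = 2),
                  effect_table = data.frame(gene = 1:10, habitat = "fungi",
                                            effect = 1.5),
                  seed = 20)
ds  <- simulate_dataset(cfg)
cur <- curate_genomes(ds$records, ds$ani_pairs, seed = 20)
cur$report
#> Genome curation report
#>   input: 153, kept: 148
#>   removed by site:         0
#>   removed by completeness: 2
#>   removed by contamination: 0
#>   removed by single_copy:  0
#>   removed by coding:       0
#>   removed by subsample:    0
#>   removed by dedup:        3
#>   seed: 20
```

Both designed completeness failures and all three injected clones are
removed, each attributed to the right rule. Enrichment on the curated
set:

```r
ids    <- cur$kept$genome_id
tree   <- ape::keep.tip(ds$tree, ids)
counts <- ds$counts[, ids]
hab    <- setNames(cur$kept$habitat, ids)

enr <- enrich_all(counts, hab, tree, ds$category_map)
enr
#> Gene enrichment: 600 gene x habitat fits (ml lambda), 12 categories
#>   genes enriched at q < 0.05: 10

fung <- enr$genes[enr$genes$habitat == "fungi", ]
head(fung[order(fung$q), c("gene", "beta", "t", "q", "lambda")], 5)
#>      gene beta    t        q lambda
#> 1 COG0001 2.46 25.2 6.59e-53   0.75
#> 3 COG0003 2.45 21.6 1.99e-45   0.35
#> 4 COG0004 2.47 20.2 1.77e-42   0.35
#> 7 COG0007 2.27 19.7 2.20e-41   0.55
#> 6 COG0006 2.37 18.6 5.54e-39   0.30
```

The ten genes flagged at q < 0.05 are exactly the ten planted ones
(`COG0001`–`COG0010`): positive effects (`beta`) on the standardized
scale, with Pagel's λ estimated per gene. Habitat structure in overall
gene content:

```r
d <- bray_curtis(counts)
permanova_dbrda(d, hab, n_perm = 999, seed = 20)
#> PERMANOVA on Bray-Curtis-type dissimilarities
#>   F = 4.830 on (4, 143) df;  R2 = 0.1190;  p = 0.001 (999 permutations)
#>   dbRDA constrained inertia fraction: 0.1190
```

Habitat explains ~12% of gene-content inertia here and the permutation p
sits at its floor of 1/(999+1). `run_pipeline(pipeline_config(...))`
chains all stages on files (TSV/newick/JSON) and writes a manifest with
per-output checksums.

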