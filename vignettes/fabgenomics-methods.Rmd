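---
title: "Methods: comparative genomics of habitat-classified bacteria"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative genomics of habitat-classified bacteria}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fabgenomics)
```

# The problem

Bacteria isolated from fungal fruiting bodies, mycelia, and mycorrhizal
root tips (fungus-associated bacteria, FaB) are expected to carry genomic
signatures of their habitat: enrichment of carbohydrate-metabolism and
motility genes, habitat-specific gene orthologs, complete nutrient-uptake
pathways, and carbohydrate-active enzyme (CAZyme) repertoires tuned to
fungal and plant substrates. Detecting such signatures from a collection
of genomes labelled by habitat (fungi, plants, humans, soil, water) is a
comparative-genomics exercise with two well-known traps:

1. **Shared ancestry.** Related genomes resemble each other regardless of
   habitat; when habitats are phylogenetically clustered, naive per-gene
   tests massively over-report habitat effects.
2. **Redundant and low-quality genomes.** Near-identical genome
   deposits and incomplete or contaminated assemblies distort every
   downstream count.

`fabgenomics` implements the full analysis chain — genome curation,
genome clustering, phylogeny-aware gene enrichment, habitat-association
scoring, pathway and CAZyme profiling, and ordination — together with a
synthetic-data generator that produces datasets with known ground truth,
so each claim the pipeline makes can be checked against planted signals.

# Genome curation

`curate_genomes()` applies, in fixed order:

1. unknown/ambiguous isolation site → removed;
2. completeness < 95% → removed;
3. contamination > 5% → removed;
4. fewer than 83 of the 92 single-copy marker genes (90%, rounded up —
   marker hits are integers, so the ceiling is the conservative reading)
   → removed;
5. protein-coding fraction < 85% → removed;
6. within each species × habitat group, at most 5 genomes are kept
   (uniform random subsample under the run seed);
7. genome pairs with ANI > 99.995% **and** alignment fraction > 90% are
   redundant; redundancy is closed transitively (connected components of
   the pair graph) and one random representative per component survives.

Boundary semantics follow the rule wording literally: "less than 95%"
removes strictly below, "more than 5%" strictly above, and the ANI/AF
thresholds are strict inequalities (a pair sitting exactly at a threshold
is kept); every threshold is an argument, so an inclusive convention is
one flag away. Removals are attributed to the *first* failing rule, which
makes the per-rule counts in the `curation_report` reconcile exactly with
the input size. Resolving redundancy per connected component, rather than
pair by pair, is deliberate: random pairwise removal over chains
(A–B, B–C redundant, A–C unlisted) is order-dependent, while components
give a deterministic contract — exactly one survivor per group.

# Clustering genomes into taxa

`cophenetic_distances()` converts the phylogeny into patristic distances;
`hierarchical_cluster()` applies agglomerative clustering (complete
linkage by default — the conventional default of the underlying
`hclust`; average and single linkage are available) and
`select_k()` picks the number of clusters maximizing the mean silhouette
width, with a gap statistic reported as a secondary diagnostic.
Conventions: silhouette width of a singleton cluster is 0 (the standard
convention, avoiding a 0/0); the gap reference is drawn uniformly from
the bounding box of a principal-coordinate embedding, since a
distance-only input has no native coordinate space to resample.

# Phylogeny-aware gene enrichment

The central model is a per-gene phylogenetic linear regression
(`phylo_lm()`): for a standardized gene copy number $z$,

$$ z = X\beta + \varepsilon, \qquad
   \varepsilon \sim \mathcal N\!\big(0,\; \sigma^2 V(\lambda)\big), \qquad
   V(\lambda) = \lambda V + (1 - \lambda)\,\mathrm{diag}(V), $$

where $V$ is the Brownian-motion covariance of the tree
($V_{ij}$ = depth of the most recent common ancestor of tips $i, j$) and
$\lambda \in [0, 1]$ is Pagel's lambda, interpolating between star-tree
independence and full Brownian covariance. The design is an intercept
plus a one-vs-rest habitat indicator, fitted separately per habitat:
per-habitat enrichment/depletion cells are the natural output of
one-vs-rest coding, and each contrast remains interpretable on its own.
The system is solved by Cholesky whitening ($V(\lambda) = R^\top R$;
regress $R^{-\top} z$ on $R^{-\top} X$ by QR), never by explicit matrix
inversion. With `lambda = "ml"` the likelihood is profiled on a 21-point
grid over $[0, 1]$; `lambda = "fixed"` (default 1 in `phylo_lm()`) is
pure Brownian motion. `enrich_all()` profiles λ by default: ortholog
counts carry non-phylogenetic sampling noise on top of the heritable
signal, and assuming a pure Brownian residual when an independent noise
component is present misweights every contrast — on generator data with
planted effects, the fixed-BM fit floods the gene list with false
positives that the λ-ML fit removes entirely. Inference uses Student-t with $n - p$ degrees of freedom,
Benjamini–Hochberg correction across genes within each habitat contrast,
and category summaries take the median per-gene effect per
(category, habitat) cell — empty cells are reported as missing, never as
zero.

Standardization uses the population (divisor-$n$) standard deviation, a
fixed convention exposed as a flag; constant genes are excluded and
reported.

# Habitat association and habitat-specific genes

A gene is *present* in a genome when its copy number is at least 1
(configurable). For habitat $h$ with $n_h$ genomes, $k_h$ of which carry
a gene found in $K$ of all $N$ genomes, `hypergeom_test()` computes the
upper tail $P(X \ge k_h)$, $X \sim \mathrm{Hypergeometric}(N, K, n_h)$,
in log-space, and reports the association score $-\log_{10} p$ (larger =
more associated). `odds_ratio_test()` forms the 2×2 presence table and
reports the sample odds ratio — with the Haldane–Anscombe +0.5 correction
applied only when a cell is zero — and the one-sided Fisher exact p,
which on these margins equals the hypergeometric tail (an identity the
test suite checks). Both p-value families are FDR-corrected within each
habitat across genes; a gene is called habitat-specific when *either*
corrected test falls below the threshold. Counts are normalized across
habitats of different sizes as counts per thousand genomes
(`cpt_transform()`, $1000 \cdot \text{count} / n_h$).

# Pathway and CAZyme profiles

A pathway (e.g. an ABC-transporter import system) counts only when
*complete* — every required gene present in the genome — and its copy
number is the minimum copy count over required genes: the number of fully
stocked pathway instances. This min rule is monotone in every gene count
and reduces to presence/absence at threshold 1. Copy numbers are binned
(0 / 1 / ≥2 by default; presence mode collapses to 0 / ≥1 — both modes
exist because either binning is defensible) and compared across habitats
by Pearson chi-squared without continuity correction (tables are usually
larger than 2×2; Yates is available for 2×2). Pathways whose copies occur
in exactly one habitat are flagged exclusive.

CAZyme annotations carry the set of supporting algorithms per hit;
`cazy_consensus_filter()` keeps hits supported by at least two, after
which family × genome counts roll up to substrates via a configurable
substrate map — a family serving several substrates contributes its full
count to each. Ectomycorrhizal- versus saprotrophic-guild genomes are
compared per substrate with a two-sided Wilcoxon rank-sum test
(normal approximation with tie correction), FDR-corrected.

# Ordination and group summaries

Gene-content dissimilarity is Bray–Curtis,
$\mathrm{BC}(u, v) = \sum|u_i - v_i| / \sum(u_i + v_i)$. PCoA applies
Gower double-centering to $-\tfrac12 D^2$; axes with negative eigenvalues
(Bray–Curtis is non-Euclidean) are dropped and their number reported —
dropping is the common default, and a correction would only matter if the
negative inertia were large, which the report makes visible. The one-way
PERMANOVA uses

$$ SS_\text{total} = \tfrac1N \textstyle\sum_{i<j} d_{ij}^2, \quad
   SS_\text{within} = \sum_g \tfrac1{n_g} \sum_{i<j \in g} d_{ij}^2, \quad
   F = \frac{SS_\text{between}/(k-1)}{SS_\text{within}/(N-k)}, $$

with permutation p-value $(1 + \#\{F^{perm} \ge F^{obs}\})/(n_{perm}+1)$:
counting the observed statistic keeps p valid and floors it at
$1/(n_{perm}+1)$ (0.001 at 999 permutations). On tiny inputs
`n_perm = "exact"` enumerates all distinct label arrangements. dbRDA axes
and the constrained-inertia fraction are computed on the same
dissimilarities; both the PERMANOVA $R^2$ and the dbRDA fraction are
reported, since either can be meant by an "explained variance" figure.
Genome size, GC content, and ortholog richness are compared by ANOVA with
Tukey HSD (Tukey–Kramer for unbalanced groups), FDR-corrected, and
summarized as a compact-letter display built by insert-and-absorb: two
groups share a letter exactly when their corrected pairwise q-value is
not significant.

# The synthetic-data generator

`simulate_dataset()` produces a complete dataset from a validated
configuration (`sim_config()`), and everything is a pure function of the
configuration including its seed:

* **Tree** — ultrametric Yule (pure-birth) tree, unit birth rate.
* **Habitats** — `random` mode draws labels independently of the tree
  with weights proportional to the reference dataset's habitat sizes
  (163 : 316 : 212 : 284 : 236 for fungi, plants, humans, soil, water);
  `clade_confounded` mode cuts the tree at its deepest internal nodes so
  each habitat is one clade — maximal phylogeny–habitat collinearity, the
  designed stress test for type-I error control.
* **Gene counts** — for gene $g$ and genome $i$,
  $c_{gi} \sim \mathrm{Poisson}\!\big(\exp(\mu_g + b_{gi} + e_{g,h(i)})\big)$
  with $b_g$ an independent Brownian realization on the tree and $e$ the
  planted effect table. This is the simplest generative model carrying
  both phylogenetic signal and habitat effects on count data; no claim is
  made that real ortholog counts arise this way, and the choice is a
  documented stand-in.
* **Near-clones** — injected duplicates graft onto the tree at tiny
  branch length, copy the source's counts with at most 0.1% of genes
  perturbed, and receive ANI/AF draws above the dereplication
  thresholds: clones are statistically indistinguishable downstream, so
  dereplication is the only defense.
* **QC failures** — designed failures set exactly one field each to just
  beyond its threshold (e.g. completeness 94.9).
* **CAZymes and pathways** — per-family Poisson counts (with an optional
  guild boost on plant substrates), 1–3 supporting algorithms per hit, and
  pathway gene content with planted complete, partial, and
  fungi-exclusive pathways.

Default noise levels were fixed once, from a model-adequacy argument:
baseline mean copy number 5 and Brownian variance 0.05 per unit branch
length. A Yule tree of a few hundred tips has height near $\ln n$, so the
tip-level latent variance is ≈ 0.25 — strong enough that naive OLS on
clade-confounded labels inflates grossly, yet mild enough that the
exponential link stays near-linear and standardized copy numbers retain
the covariance structure ($\lambda V + (1-\lambda)\,\mathrm{diag}\,V$)
the regression assumes. At much larger Brownian variance the count scale
becomes heavily lognormal and *no* linear method — phylogenetic or not —
is correctly specified; the generator is meant to emulate the structure
the analysis assumes, not to break it by construction.

What the generator does **not** emulate: real COG fractional category
assignments (categories are drawn uniformly), genome-size-correlated gene
counts, annotation error, horizontal transfer (which violates the
tree-shaped covariance), or sequence-level artifacts — the pipeline
starts at annotation tables. Passing tests therefore demonstrate
correctness of the statistical machinery under the stated model, not that
real data satisfy that model.

# Validation studies and problem sizes

The package ships its own benchmark functions, used by both the test
suite and `scripts/acceptance.R`:

* `calibration_study()` — 200 genomes, 500 genes, clade-confounded null:
  rejection rate of the λ-ML phylogenetic fit at α = 0.05 versus naive
  OLS. The phylogenetic rate is required to sit inside the 99% binomial
  band around 0.05 while OLS exceeds 0.15.
* `effect_recovery_study()` — 100 independent simulations of a planted
  +2 log-link effect at 200 genomes; the raw-count habitat contrast is
  compared with the closed-form implied mean difference
  $e^{\mu + \sigma^2 H/2}(e^{2} - 1)$.
* `dedup_study()` — 50 datasets with 4 planted clone groups each; success
  means exactly one survivor per group.
* `permanova_calibration_study()` — 500 null-label replicates (mean p
  should be near 0.5) plus one strongly separated pair of habitats (p
  must reach the 1/1000 floor).
* `cluster_recovery_study()` — 100 trees of 4 planted clades at 5:1
  between-to-within separation; silhouette selection must recover k = 4.
* `hypergeom_enumeration_check()` — every margin with N ≤ 12 against
  full subset enumeration.

These sizes keep each study in seconds on a single core while leaving the
binomial error bars tight enough for the stated bounds to be meaningful.

# Numerical and degenerate-input conventions

* GLS is solved via Cholesky whitening and QR; non-positive-definite
  covariances and rank-deficient designs raise immediately with the
  offending quantity named.
* The Brownian covariance of duplicated tips is singular; a relative
  ridge of 1e-10 is added only inside the *generator's* latent draw
  (where clones are intended), never in the fitting path.
* Agglomeration ties follow `hclust`'s deterministic ordering, so
  clustering is invariant to input row order.
* Constant genes, empty categories, all-zero genomes, zero-genome
  habitats, and substrates with no mapped family present are each either
  excluded-and-reported or returned as missing — never silently coerced
  to zero.

# Limitations

* One-vs-rest contrasts ignore correlations between habitat labels; a
  single multi-level-factor fit is a straightforward extension.
* Pagel's λ on a 21-point grid resolves λ to 0.05; finer resolution costs
  linearly more Cholesky factorizations.
* The PERMANOVA is one-way; multi-factor designs (habitat + host type)
  require the constrained-ordination route.
* The generator's ground truth is expressed on the log link; comparisons
  of fitted effects against truth are therefore done either on raw counts
  (closed-form mean difference) or as sign/ranking statements on the
  standardized scale.
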