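---
title: "Methods: integrating host expression with gut microbial composition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: integrating host expression with gut microbial composition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(homico)
```

homico mines associations between host gene expression and gut microbial
composition in paired case/control cohorts. The analysis has four stages:
overall concordance testing, group-level association by sparse canonical
correlation analysis (CCA), feature-level association by gene-wise penalized
regression with debiased inference and stability selection, and pathway and
cross-cohort summaries. Cases and controls are always analysed separately and
compared only at the end, and cohorts are combined only at the final
cross-cohort step, so batch structure between cohorts never enters a fitted
model. This vignette records the statistical choices, defaults, and known
limitations.

## Input preprocessing

Expression side. Counts are restricted to an optional coding-gene list,
genes must be expressed (count > 0) in at least half the samples, and the
matrix is transformed by per-sample median-of-ratios size factors followed by
`log2(x/s + 1)`. This transform is monotone, removes depth differences, and
tames the count-variance relationship; it is *not* the regularized
variance-stabilizing transform of differential-expression packages, and we
document it as an approximation (the size factors themselves match
`DESeq2::estimateSizeFactorsForMatrix` exactly, which a unit test checks).
Genes below the 25% variance quantile (linear-interpolation convention,
boundary kept) are then dropped.

Microbiome side. After removing blocklisted contaminant lineages, the OTU
table is summarized at every available rank (phylum through species; OTUs
unlabelled at a rank are excluded from that rank only), each rank table is
filtered to taxa at relative abundance >= 0.001 in at least
`ceiling(0.10 n)` samples (both boundaries inclusive), and the rank tables
are concatenated before a single centered log-ratio (CLR) transform with a
pseudocount of 1. Transforming the combined matrix rather than each rank
separately keeps a single compositional geometry across ranks;
`compare_clr_strategies()` reports how similar the two orderings are on any
dataset. Combining ranks multi-counts reads, so the combined matrix contains
strongly correlated (sometimes identical) columns; the association machinery
is designed to tolerate this (below). Cohorts with repeated timepoints are
collapsed to one profile per subject by arithmetic means on the count scale
before any transform; the rule generalizes beyond two timepoints as a plain
mean. Subjects with conflicting group labels are an error.

## Concordance testing

Aitchison distance (Euclidean on CLR, or on an already-transformed
standardized expression matrix) and Bray-Curtis dissimilarity feed a
symmetric Procrustes test and a Mantel test. The Procrustes embedding is
classical MDS keeping all positive-eigenvalue axes; with both configurations
centred and scaled to unit sum of squares, the statistic is
`m2 = 1 - (sum of singular values of X'Y)^2` and significance comes from row
permutations, `p = (1 + #{perm cor >= observed}) / (n_perm + 1)` (9999
permutations by default, so the smallest attainable p is 1e-4). The
statistic equals `vegan::protest`'s exactly (tested); the permutation loop is
compiled so calibration studies with hundreds of replicates stay cheap. The
Mantel test is `vegan::mantel` (Pearson on upper triangles).

## Sparse CCA

With standardized taxa matrix X (samples x taxa, CLR) and expression matrix
Y (samples x genes), sparse CCA maximizes `u'X'Yv` subject to
`||u||2 <= 1, ||v||2 <= 1, ||u||1 <= c1, ||v||1 <= c2` — the
diagonal-covariance penalized matrix decomposition; the printed constraint
`u'X'Xu <= 1` of classical CCA is deliberately replaced by the unit ball, as
in the standard implementation of this estimator. Penalties are expressed as
fractions `lambda` of the maximal bound, `c = lambda * sqrt(dim)`, floored
at 1 because an l1 bound below 1 is infeasible for a unit-l2 vector.

Numerics: the rank-1 solver initializes v at the leading right singular
vector, alternates `u <- S(Cv, d1)/||.||2` and `v <- S(C'u, d2)/||.||2` with
each threshold found by 60 bisection steps, and stops when the largest
loading change is below 1e-6 (cap 100 iterations, warning on
non-convergence). When k columns tie exactly at the maximum — which happens
systematically because rank-combined taxa duplicate columns — every feasible
point has `||u||1 >= sqrt(k)` and the bisection would collapse to zero; the
solver falls back to the sparsest vertex (all weight on the first maximal
coordinate), a deterministic tie-break. Components are oriented so the
largest-|v| entry is positive. Later components deflate the cross-product,
`C <- C - d u v'`. K defaults to 10 and is truncated to `min(dim)` with a
warning.

Penalty tuning is a two-dimensional grid search under leave-one-out CV: for
each cell the first component is refitted without each sample, held-out
scores `X_i u_{-i}`, `Y_i v_{-i}` are collected, and the objective is their
Pearson correlation; ties go to the sparser pair, taxa penalty first. The
default grid spans 0.05–0.5 in steps of 0.05 on both axes.

Component significance repeats the leave-one-out refit for all K components
(`mode = "full"`; a `"fast"` mode refits only component k against the
full-data deflations and is flagged approximate), tests each component's
held-out score pairs with a two-sided Pearson correlation test, and adjusts
the K p-values by Benjamini-Hochberg within the run; components with
q < 0.1 are called significant.

**Known limitation.** Under a global null the held-out score pairs are not
independent across folds — every sample's loadings are trained on all other
samples — and the empirical spread of the held-out correlation is about
twice the `1/sqrt(n)` the correlation test assumes (measured at n = 60 with
200 genes and 50 taxa, across penalties 0.1–0.4). The per-component
p-values are therefore anti-conservative: in null simulations roughly half
of runs show at least one q < 0.1 component at K = 5. A calibrated
alternative would refit the whole leave-one-out procedure under row
permutations (roughly a hundredfold cost) or use sample splitting; we keep
the held-out correlation test as the stage's standard procedure and report
its measured null behaviour in the validation outputs. Significant
components should be read as a ranking device feeding enrichment, not as
calibrated hypothesis tests.

## Gene-wise lasso with debiased inference and stability selection

For each gene, expression (centred) is regressed on the standardized
predictor matrix of CLR taxa plus 0/1 covariates (sex; disease subtype where
it varies), with covariates penalized like taxa. The lasso path uses the
glmnet objective over 100 log-spaced penalties from `lambda_max = max|X'y|/n`
down to `1e-3 lambda_max`; `lambda_best` minimizes the leave-one-out mean
squared error (CV minimum, not the 1-SE rule). The solver is a
coordinate-descent path with warm starts working on covariance statistics
(`X'X/n`, `X'y/n`), active-set inner loops, a glmnet-style scaled
convergence measure, and a deviance-saturation stop for the p > n tail;
unit tests pin it to glmnet on well-posed designs and to the soft-threshold
closed form on orthonormal designs.

Debiased inference uses nodewise-regression projections: each column is
regressed on the others with a 10-fold-CV lasso (the response model is LOO;
nodewise LOO would be computationally disproportionate), giving residuals
`Z_j` and `b_j = beta_j + Z_j'(y - X beta)/(Z_j'X_j)` with
`SE_j = sigma ||Z_j||/|Z_j'X_j|` and `sigma^2 = RSS/(n - #nonzero)`. The
projections depend only on the design, so they are computed once per
cohort-group and reused by every gene model. Three finite-sample refinements
were adopted after measuring the far tail of null p-values (the region a
pooled BH correction over ~10^4 tests actually uses):

1. p-values and confidence intervals use a Student-t reference with
   `n - #nonzero` degrees of freedom rather than the asymptotic normal;
   with sigma estimated, the normal tail is severalfold too small at
   n = 60–80.
2. The nodewise penalty is raised above its CV minimum until the projection
   leaves at least 5% of the column's variance unexplained (a restricted
   projection). The CLR closure makes every taxon an exact linear
   combination of the others, so the CV-minimal projection can vanish and
   the debiasing remainder term explodes — we measured per-column z-score
   spreads up to 4.7 before the floor and at most 1.15 after.
3. The standard error is the maximum of the classical formula and a
   df-corrected sandwich estimate `sqrt(sum_i Z_ij^2 r_i^2 * n/df)/|Z_j'X_j|`,
   guarding the far tail against the heteroscedastic log-count residuals.

Columns that are exact duplicates of another column (absolute correlation
numerically 1, e.g. a singleton lineage repeated across ranks) have no
identifiable individual coefficient; they are flagged and reported with
infinite SE and p = 1 (an `on_collinear = "error"` mode aborts instead).

Stability selection runs K = 100 rounds, each fitting the lasso on a random
`floor(n/2)`-subsample at a penalty drawn uniformly from
`[0.8, 1.2] * lambda_best`, and records selection frequencies; predictors
with frequency >= 0.6 are stable. Per-gene seeds are derived from the gene
*name*, so results are identical whatever the execution order — the
serial/parallel contract is a property of the seeding, not of a scheduler.

The final table applies one BH correction across the cohort-group and keeps
records with q < 0.1, stability frequency >= 0.6 and predictor kind taxon,
with the Spearman correlation between raw expression and CLR abundance
attached as the effect's sign and weight. The BH family is the gene-taxon
tests; covariate tests are corrected separately. Pooling the covariate tests
into the same family would let their (frequently real) effects raise the BH
threshold for everyone, licensing on the order of one false taxon discovery
per dataset even with perfectly calibrated p-values — we measured exactly
that on null simulations — so the nuisance family is kept apart.

Case-specificity removes any (gene, taxon) pair present in the control
group's *pre-threshold* stability-selected set — no p or FDR cut enters the
overlap — so the case-only designation is robust to the significance
threshold.

## Enrichment and differential enrichment

Fisher's exact test (one-sided, enrichment direction) scores pathways after
intersecting each set with the background and applying size filters: for
sparse CCA interest sets, pathways with 25–300 genes; for lasso gene sets,
10–85 genes; both require an overlap of at least 5. BH correction runs
across surviving pathways within a cohort run; for multi-component sources
every significant component's rows enter one pooled correction and each
pathway is tagged with its most significant component. The reported odds
ratio is the sample odds ratio with a Haldane +0.5 on all cells of any table
containing a zero.

Differential enrichment compares arms through
`z = log(OR)/SE, SE = sqrt(1/n1 + 1/n2 + 1/n3 + 1/n4)` and
`z_diff = (log OR_case - log OR_ctrl)/sqrt(SE_case^2 + SE_ctrl^2)` — the
quadrature sum is the standard comparison of independent log odds ratios —
with two-sided normal p-values and BH across tested pathways. Case-specific
pathways are the union of (1) pathways enriched only in cases (q < 0.1) and
(2) pathways enriched in both arms and differentially enriched at
q_diff < 0.2.

## Cross-cohort mining

Set similarity is the overlap coefficient `|A n B| / min(|A|, |B|)`.
Pathway redundancy pruning takes the top 15 most significant pathways, links
pairs with coefficient > 0.5, computes connected components, and keeps the
largest gene set per component (ties: lexicographically smallest ID).
Shared-taxon networks are built per Venn region (all cohorts; each
pair-only region, excluding taxa present in the remaining cohort): edges are
picked round-robin by taxon in ascending q, at most 10 per cohort per
region. Shared-gene networks rank genes lexicographically by their best q
per member cohort (cohort order as supplied), keep the top 10, and then at
most the top 10 edges per cohort. Exports are GraphML plus a TSV edge list
whose round trip reconstructs the network exactly; edge weight is |Spearman
rho| with the sign carried as a separate attribute.

## The synthetic-data generator

The generator emulates the data model the analysis assumes. Taxa: per-sample
log abundances are a baseline (sd 1.5 across taxa) plus latent-factor
loadings on planted taxon supports plus log-normal noise (sd 1, chosen so
CLR features have roughly unit scale, as mucosal 16S profiles do), closed to
the simplex and sampled multinomially at Poisson depth (default 20,000
reads). Genes: negative-binomial counts (dispersion 0.1) around a log-mean
with baseline `N(6, 1)` (median count a few hundred, as genes passing
expression filters do), the same latent factors on planted gene supports,
planted direct taxon effects acting through the true CLR abundances,
a sex effect of magnitude 1 on 5% of genes, a per-sample size factor
(sd 0.2), and Gaussian noise (sd 0.5). Case-only (or control-only) regimes
multiply planted effects by the group indicator. Lineages come from random
nested partitions with about a quarter of species labels missing; gene sets
are uniform decoys plus planted sets drawing at least 80% of their members
(capped by the support size) from a designated support. Everything is a pure
function of the configuration seed.

What the generator does *not* emulate: batch effects between cohorts
(deliberately, since the pipeline never pools cohorts in a fitted model),
primer or region biases, phylogenetically structured effects (taxon supports
are random, not clades), zero-inflation beyond what the multinomial induces,
and gene-gene coexpression beyond the planted factors. Passing recovery
tests therefore show the machinery works under the assumed model, not that
real mucosal data satisfy the model.

## Validation studies and problem sizes

The studies behind `scripts/acceptance.R` and the heavier tests use sizes
chosen to finish in minutes on one core while keeping Monte-Carlo error
small relative to the margins checked: the PMD–SVD oracle on 100 random
20x15 and 20x10 instances; sparse CCA recovery and power on 50 cohorts of
n = 60 with 200 genes / 50 taxa, 10% active supports, effect 1.5, K = 5
components at penalty 0.3; the null type-I study on 100 Gaussian datasets of
the same shape; debiased CI coverage on 200 null coefficients (4 designs of
n = 100, p = 50); association recovery on 10 cohorts of n = 80 with 10
planted pairs of effect 1.5 (plus 10 null cohorts); the Fisher oracle on 500
random tables with totals up to 200; concordance calibration on 500 null
replicates at n = 20 with 999 permutations; and the end-to-end determinism
check on three cohorts of n = 40 run twice. K = 5 components (rather than
the pipeline default of 10) keeps the leave-one-out significance refits
proportionate in the repeated-simulation setting; the conclusions do not
depend on K.

## Known limitations

- The held-out significance test for sparse CCA components is
  anti-conservative under the null (see above); its output ranks components
  rather than testing them.
- The log size-factor transform approximates, and is not, a regularized
  variance-stabilizing transform; very low counts remain noisier than the
  transform pretends.
- Near-duplicate taxa columns from rank combination receive no individual
  debiased significance (infinite SE by design when exactly duplicated);
  the stability-selection step tends to pick one representative of a
  correlated clade, and which one is data-dependent.
- Debiased p-values are calibrated under the generator's model; heavy
  contamination, strong zero-inflation, or outlier samples beyond what the
  sandwich guard absorbs can still inflate the far tail.
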