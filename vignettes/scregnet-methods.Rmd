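---
title: "Methods: from single-cell counts to master regulators"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from single-cell counts to master regulators}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`scregnet` implements a complete analysis chain for deep, plate-based
single-cell RNA-seq of disease and isogenic-control neurons: subtype
classification, negative-binomial differential expression, k-NN smoothing,
signed coexpression modules, mutual-information regulatory networks, and
two-tailed master-regulator analysis with concordance filtering. This
vignette explains the model behind each stage, the parameters that matter,
the numerical choices, and what the bundled synthetic generator does and does
not emulate.

## Count model and normalisation

All stages assume negative-binomial raw counts with cell-specific library
sizes — the standard model for full-length, plate-based single-cell
protocols, where zeros arise from sampling at low means rather than from a
separate dropout process. Library-size normalisation is counts-per-10k;
log1p of that is used wherever distances or correlations across cells are
computed (classification, smoothing neighbourhoods). Differential expression
works on raw counts with size factors; module and network inference work on
smoothed normalised counts.

## Quality control and classification

Cells are kept when `detected_genes >= 1000`, `total_counts >= 50000` and
`mito_fraction <= 0.5`. The thresholds suit deep plate-based data (hundreds
of thousands of reads per cell); the generous mitochondrial cutoff reflects
the high mitochondrial content expected of cultured neurons. All three are
config fields.

Classification proceeds in five steps:

1. **Marker scoring.** Each cell is scored against each marker panel as the
   mean of gene-wise z-scored log-normalised expression over the panel's
   genes; the argmax panel gives a provisional class.
2. **Classifier gene set.** Every gene is tested across provisional classes
   with a Kruskal–Wallis test; the classifier set is the union, over
   classes, of the `n_top = 150` genes with smallest BH-adjusted p among
   genes whose mean is highest in that class. A rank test is used because
   log-normalised single-cell expression is zero-inflated and heteroskedastic;
   per-class top lists keep the set balanced when one class dominates the
   signal.
3. **Clustering.** PCA (30 PCs) of the scaled classifier-gene matrix, a
   k-nearest-neighbour graph (k = 15, Euclidean in PC space), and Leiden
   modularity communities. The default *calibrates the resolution by
   bisection to 8 clusters*: deliberate over-clustering relative to the
   ~3 expected classes. Partition analysis can only flag a mixed
   sub-population if clustering first isolates it; with a resolution tuned
   to the class count, a small hybrid population is simply absorbed into its
   nearest class. Splitting a pure class into two clusters is harmless —
   both halves receive the same marker label.
4. **Labelling and partition analysis.** Clusters are labelled by the argmax
   of per-cluster median panel scores (exact ties stay `unassigned`).
   Cluster centroids over the classifier genes are correlated and
   average-linkage clustered into `k_super = 3` superclusters. A cluster is
   **mixed** when its marker label differs from the cell-count-weighted
   plurality label of its supercluster. The plurality is cell-weighted
   because "majority of clusters" is undefined when a supercluster holds one
   cluster of each label; an exact weighted tie flags nothing and warns.
   Mixed clusters are excluded from differential expression.
5. **HOX code.** For any supplied gene list the pipeline reports the percent
   of cells per genotype with a nonzero count; genes absent from the matrix
   are reported as missing rather than zero.

## Differential expression

Disease vs control within one cell class (default MN), design
`~ batch + genotype`, fitted by DESeq2 with the settings appropriate for
single-cell counts: Wald test, `sfType = "poscounts"`,
`minReplicatesForReplace = Inf` (no outlier replacement), `useT = TRUE`
(t-distributed Wald statistic with residual degrees of freedom) and
`minmu = 1e-6`. Results are extracted without independent filtering or
Cook's cutoff, so the BH correction runs over all genes with any counts;
all-zero genes are dropped before fitting. `estimate_size_factors_poscounts()`
re-implements the poscounts reference (geometric mean over positive counts,
log-sum divided by the total cell count) and is cross-checked against DESeq2
in the tests. The **signature** is exact thresholding: adjusted p < 0.01 and
|log2 FC| > 1, split into up and down sets, plus the full ranking by signed
Wald statistic (ties broken by gene id for determinism).

## Smoothing

Genes expressed in at least 20 cells are retained. Each cell's normalised
profile is replaced by the unweighted mean over itself and its `k = 10`
nearest neighbours, found by Euclidean distance in the top 30 PCs of the
log-normalised matrix; distance ties break by cell index. A plain mean (no
diffusion, no weighting) is the smallest intervention that raises the
signal-to-noise of gene–gene correlations; it keeps constant genes fixed and
bounds every smoothed value by the gene's observed range. Smoothing runs on
the non-mixed neuronal cells (default classes MN and IN), which are also the
cells used for modules and networks.

## Coexpression modules

The signed-hybrid adjacency is `a_ij = cor(i,j)^6` for positive Pearson
correlations and 0 otherwise — power 6 is the conventional signed-hybrid
default and is kept fixed; negative correlations are excluded from module
formation by construction. Topological overlap
`TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i,k_j) + 1 - a_ij)` counts
shared neighbours, and `1 - TOM` is clustered by average linkage.

**Branch cutting** is a static height scan. Merge heights at or above 99% of
the tree top are excluded (those merges glue unrelated background genes into
giant branches); among the remaining heights the cut maximising the number
of branches with ≥ 50 genes wins, and ties resolve to the *middle* of the
tied height range — the lowest tied height leaves branches truncated, the
highest begins absorbing background, and the midpoint takes branches at
their natural completion (verified on planted-block toys). Leftover genes
are rescued into the module whose eigengene they correlate with above 0.3,
otherwise they stay unassigned. Modules whose eigengenes correlate ≥ 0.75
merge (transitively, via clustering the eigengenes at height 0.25),
iterating to a fixed point.

The **eigengene** is the first principal component of the standardized
cell × gene submatrix, unit variance, sign-aligned with the module's mean
profile. **Trait association** is the Pearson correlation of an eigengene
with a binary contrast indicator, BH-corrected across modules within a
contrast, significant at adjusted p < 0.01 and |r| > 0.4. **Stability** is
bootstrap-based: cells are resampled with replacement `B` times, modules are
recut from scratch, and a module scores 100 × the mean best Jaccard index
against any resampled module. The bootstrap recut skips the eigengene
rescue: single-gene rescue decisions are noise-driven under resampling, and
the score should measure branch reproducibility. The score's ceiling of 100
matches its use as a percentage-like index.

## Regulatory network and master-regulator analysis

Genes with coefficient of variation below 0.05 on the smoothed matrix are
dropped. Mutual information between every TF and every remaining gene uses
equal-frequency binning on ranks (`ceiling(n^(1/3))` bins per axis), the
plug-in histogram estimator with Miller–Madow bias correction, floored at
zero. Rank binning makes the estimate invariant to monotone transforms of
the smoothed counts; the estimator's contract is calibration, verified
against the bivariate-Gaussian closed form `-0.5 log(1 - rho^2)` and a
permutation null in the tests. The edge threshold is the `(1 - alpha)`
quantile (alpha = 0.05) of a pooled null built from permuted TF–gene pairs,
so on pure noise about alpha of pairs survive. The data-processing
inequality then removes, in every triangle, the weakest edge when
`MI_weak < min(MI_other) * (1 - tolerance)` with tolerance 0.1; removals are
decided simultaneously on the original values, so edge order is irrelevant.

Surviving TF edges become regulons, signed by Spearman correlation (positive
regulon: activated targets; negative: repressed). MRA tests each TF twice:
the *activation* overlap counts positive-regulon genes in the up-signature
plus negative-regulon genes in the down-signature; the *inhibition* overlap
swaps directions. Both are upper-tail hypergeometric tests over the genes
present in both the network and the DE table; BH runs over the per-TF
stronger tail and a call requires FDR < 0.01. A hypergeometric overlap (not
a running-sum enrichment) is used because the signature is a fixed gene set,
not a ranking. The **core set** applies the concordance filter: the TF must
itself be differentially expressed (adjusted p < 0.01, |log2 FC| > 1) in the
direction of its call. Core TFs are clustered on `1 - MI/max(MI)` (average
linkage), and their regulon halves are tested against modules by
hypergeometric overlap with BH across the whole table.

## One-way GSEA

The enrichment score is the classic weighted Kolmogorov–Smirnov running sum
(hit steps proportional to `|score|^p`, p = 1 by default; miss steps
uniform), with the signed extreme deviation reported. The permutation null
draws random gene sets of the same size, and the p-value is the **one-way
upper tail** `P(ES_null >= ES_obs)` with the add-one rule. A tail chosen
from the sign of the observed score would concentrate p-values below 0.5
under the null; the fixed upper tail keeps them uniform, which is the
property the calibration tests assert. Depletion is queried by reversing the
ranking (the ES sign flips exactly).

## The synthetic generator

`simulate_regulatory_counts()` draws NB counts whose log-mean adds a gene
baseline (log-normal relative abundances, including `MT-` genes holding
~15% of the library), the cell's class program (three classes at effect
log 6), module latents, signed TF-activity effects, a per-gene batch offset
(sd 0.1), and the log library size (log-normal around 3×10⁵). Disease cells
have the three perturbed TFs' activities shifted by ±2 (log scale) and the
first module's latent shifted by +2. TF activity also drives the TF's own
mRNA (loading 1), so TF and regulon are concordant by construction;
`decouple_tfs = TRUE` severs that link to exercise the concordance filter's
rejection path. A planted *hybrid* population (10% of cells) expresses the
MN marker panel at MN level on a full IN background with attenuated IN
markers: its marker label (MN) conflicts with its global profile (IN),
which is exactly the situation the mixed-cluster flag exists to catch. Ten
cells with ~2,000-read libraries are planted to exercise QC. Module
loadings are drawn from U(0.5, 0.8), giving within-module correlations of
roughly 0.4–0.7 after smoothing — the regime reported coexpression modules
occupy; regulon weights are U(0.4, 0.8) with 70% positive targets.

The generator emulates: NB overdispersion, library-size variation, zeros by
sampling, batch structure, marker-driven classes, coexpression modules, a
disease module, signed regulons and perturbed master TFs. It does **not**
emulate: UMI duplication, doublets, isoform structure, gradient-like
(trajectory) populations, cross-talk between modules and regulons (their
gene pools are disjoint), or realistic gene–gene correlation beyond the
planted structure. Passing the recovery tests therefore shows the pipeline
is correct and well-calibrated under its own model assumptions, not that it
is robust to everything real data can do.

## Problem sizes and determinism

The default fixture is ~300 cells (150 per genotype, plus 10 low-quality),
2,000 genes, 50 TFs with 30 targets each, 5 modules of 60 genes, and 3
perturbed TFs — big enough for every stage to operate in its intended regime
while the full pipeline runs in about a minute. Tests use a reduced fixture
(120 cells, 400 genes) where the full scale is not needed; calibration
checks use 2,000 null genes at 40+40 cells (Wald type-I error), n = 5,000
for the Gaussian MI check, and n = 1,000 for the MI permutation null.
Bootstrap stability defaults to 20 replicates; acceptance runs use 10.

All randomness flows from the single `rng_seed` through named per-stage
substreams, so a stage rerun in isolation reproduces its in-pipeline result
and a repeated full run writes byte-identical tables. Ties are broken
deterministically throughout (cell index in neighbour search, gene id in
rankings, simultaneous edge marking in DPI).

## Known limitations

- The static branch cut is simpler than the dynamic hybrid algorithm of the
  WGCNA tradition; it recovers well-separated modules exactly but will not
  resolve nested or strongly overlapping module structure.
- The MI estimator's Miller–Madow correction leaves a small negative bias at
  high dependence (visible as ~0.02–0.03 nats at rho = 0.8); edge ranking is
  unaffected because the bias is monotone in dependence strength.
- Regulons inferred from smoothed data are large: neighbour averaging
  inflates all correlations, and the permutation null (built from the same
  smoothed data) compensates only partially. The MRA is robust to this
  because both the regulon and the null model share the inflation, but the
  absolute regulon sizes should not be over-interpreted.
- Module and regulon gene pools are disjoint in the generator, so the
  regulon–module overlap table is exercised by constructed cases in the
  tests rather than by the fixture.
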