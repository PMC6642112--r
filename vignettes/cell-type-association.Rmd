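---
title: "Mapping GWAS signal onto cell types: the model and the workflow"
author: "scTypeAssoc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping GWAS signal onto cell types}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scTypeAssoc)
```

## The problem

A well-powered GWAS yields, after gene-based aggregation, a Z-score per
gene summarizing how strongly the gene's region associates with the
trait. Single-cell RNA-seq yields, per dataset, an expression profile
for each annotated cell type. If trait risk is mediated by a particular
cell type, genes expressed *specifically* in that cell type should carry
more association signal. The difficulty is that "specific" is only
defined relative to the other cell types measured in the same dataset,
and that the dozens of public scRNA-seq datasets one would like to use
cannot be merged: protocols, species, tissue sampling and cell-type
taxonomies differ, producing batch effects that dominate naive joint
analyses. This package tests cell types dataset by dataset and then
reconciles the results *across* datasets by conditional analysis,
without ever merging expression values.

## The regression model

For one dataset, the per-cell-type profile is

$$E_c = \frac{1}{n}\sum_{i=1}^{n} \log_2(e_i + 1), \qquad
  A = \frac{1}{N}\sum_{j \in C} E_j,$$

the mean log expression of each gene over the \(n\) cells of cell type
\(c\) (log first, then average), and \(A\) the per-gene mean of the
\(N\) cell-type columns. The association test is the gene-property
regression

$$Z = \beta_0 + E_c\,\beta_E + A\,\beta_A + B\,\beta_B + \varepsilon,$$

with \(B\) technical confounders (gene length and log gene length when
available) and a **one-sided** test of \(\beta_E > 0\): association
should increase with cell-type-specific expression, not merely with
expression. Conditioning on \(A\) is what turns "expressed here" into
"expressed here *more than elsewhere in this dataset*"; it also defines
the hypothesis. Subsetting the profile (`subsetProfile()`) recomputes
\(A\) over the kept cell types and thereby changes the question --
e.g. a neuron tested against a brain-wide average answers a different
question than the same neuron tested against a whole-body average.

Why not binned specificity scores? A gene's S score (its expression in
one cell type divided by its summed expression across cell types),
binned into equal-count bins, correlates positively with overall
expression whenever zeros or mean-coupled specificity are present, so a
model built on binned S alone inherits a general-expression confound.
`makeConfoundedFixture()` reproduces this mechanism and the test suite
verifies that the \(A\)-conditioned regression stays calibrated on the
same data (see `sScore()`, `binEqualCount()`).

One-sided P-values use the Student-t distribution with
\(df = n_\text{genes} - n_\text{terms}\) rather than the normal: exact
finite-sample behaviour matters at desk-scale gene counts. When a
gene-gene correlation matrix (LD-induced) is supplied, the whole system
is whitened by the inverse Cholesky factor of the (ridge-stabilized,
\(\varepsilon = 10^{-6}\), applied only when plain Cholesky fails)
correlation, which makes ordinary least squares on the whitened system
exactly generalized least squares. This is an approximation to full
LD-aware gene-based machinery, not a replication of it.

## The three-step workflow

**Step 1 (marginal scan).** The marginal model is fitted for every cell
type of every dataset; significance is Bonferroni-corrected across
*all* dataset-cell-type combinations (with 2,679 tests and
\(\alpha = 0.05\) the threshold is \(1.87\times 10^{-5}\)).

**Step 2 (within-dataset conditioning).** Cell types within one dataset
are often near-duplicates. For a significant pair \((a, b)\) with
\(p_a \le p_b\), a joint fit yields conditional P-values, and the
proportional significance
\(\mathrm{PS}_{a,b} = \log_{10} p_{a,b} / \log_{10} p_a\) measures how
much of \(a\)'s signal survives conditioning on \(b\). The decision
table is:

| scenario | condition | action |
|---|---|---|
| 1 independent | \(\mathrm{PS}_{a,b} \ge 0.8\) and \(\mathrm{PS}_{b,a} \ge 0.8\) | retain both |
| 2 partially joint | \(\mathrm{PS}_{a,b} \ge 0.5\) and \(\mathrm{PS}_{b,a} \ge 0.5\) | retain both |
| 3 jointly explained | \(\mathrm{PS}_{a,b} < 0.2\) and \(\mathrm{PS}_{b,a} < 0.2\) | retain a |
| 4 a drives b, residual signal | \(\mathrm{PS}_{a,b} > 0.8\), \(\mathrm{PS}_{b,a} < 0.5\), \(p_{b,a} < 0.05\) | retain a |
| 5 a fully drives b | \(\mathrm{PS}_{a,b} \ge 0.5\) and \(p_{b,a} \ge 0.05\) | retain a |
| 6, 7 | mirrors of 4, 5 after the flip rule | retain b |
| 8 ambiguous | anything else | retain a (stronger marginal), flagged |

The *flip rule* runs first: when \(\mathrm{PS}_{a,b} < 0.2\) while
\(\mathrm{PS}_{b,a} \ge 0.2\), the nominally weaker cell type explains
the stronger one, and the roles are swapped before classification.
Scenario 8 covers combinations the rules above leave gapped (e.g.
\(\mathrm{PS}_{a,b} = \mathrm{PS}_{b,a} = 0.3\)); it conservatively
retains the stronger marginal and is flagged for audit. Forward
selection proceeds per dataset from the most significant cell type; a
candidate is kept only if every pairwise classification against the
already-retained set retains it. Conditioning is pairwise, not one
joint model over all retained cell types: the pairwise PS rules are
what the decision table is defined on, and a full joint model with many
correlated expression columns would routinely trip the collinearity
guard. Pairs whose residualized expression columns correlate above
0.999 are flagged `colinear` and their P-values withheld.

**Step 3 (cross-dataset conditioning).** For retained cell types
\(c_1, c_2\) from datasets 1 and 2, three models are fitted, all
containing *both* dataset averages:

$$Z = \beta_0 + E_{c1}\beta_{E_{c1}} + A_1\beta_{A_1} + A_2\beta_{A_2} + B\beta_B + \varepsilon$$
$$Z = \beta_0 + E_{c2}\beta_{E_{c2}} + A_1\beta_{A_1} + A_2\beta_{A_2} + B\beta_B + \varepsilon$$
$$Z = \beta_0 + E_{c1}\beta_{E_{c1}} + E_{c2}\beta_{E_{c2}} + A_1\beta_{A_1} + A_2\beta_{A_2} + B\beta_B + \varepsilon$$

giving the cross-dataset (CD) marginal and conditional P-values and the
CD proportional significance per cell type. Two cell types are mutually
independent when both CD PS values exceed 0.5. Forward selection over
all retained cell types (ordered by step-1 marginal P; ties broken by
dataset id, then cell-type name) builds clusters: a cell type founds a
new cluster iff it is independent of **every existing founder**, and
otherwise joins the first founder that explains it. Conditioning on
founders only (rather than all previously placed cell types) matches
the "mostly independent" summary semantics; the alternative would only
re-partition non-founders. Within-dataset pairs reuse the step-2 joint
fits. Each cross-dataset pair also records whether adding the other
dataset's average alone already removes half of a cell type's marginal
association (`avg_explained`); for comparability this recomputes the
step-1 marginal on the pair's shared gene set, since the three CD fits
use the intersection of genes present in the statistics and both
profiles. Beyond step 1 no further multiple-testing correction is
applied: the nominal 0.05 inside the PS rules is part of the decision
table itself.

## Specificity scores, binning and dataset comparison

Cross-dataset comparisons never use raw expression: each vector is
rank-binned into equal-count bins (`binEqualCount()`), which absorbs
scale and distributional batch differences. Genes with expression zero
are kept as bin 0, so 100 bins yield 101 possible values and the
40-bin S-score construction yields 41. Ties receive their average rank
before the ceiling -- deterministic and permutation-invariant; the
binning is invariant to strictly monotone transforms. For *residual
specificity* (each cell type's expression column regressed on intercept
plus dataset average, residuals kept), the zero carve-out is not
applied: a residual of zero has no special meaning, so residual vectors
are rank-binned over all genes. Dataset-level similarity is the
Spearman correlation of 100-binned average-expression vectors over
shared genes; cell-type-level similarity the same on binned residual
specificity. Group contrasts (e.g. within- versus between-species
correlations) use the two-sided Mann-Whitney U test, exact when both
groups have at most 20 values and no ties. The 2-D embedding runs
t-SNE (perplexity 30) `restarts` times from sub-seeds derived from one
master seed and keeps the run with minimal Kullback-Leibler divergence;
whether the embedded features are binned residual-specificity vectors
(the default in the command-line `embed`) or raw averages is the
caller's choice, as either reading is defensible.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `alpha` | 0.05 | family-wise error of step 1 (Bonferroni over all tests) |
| `ps_joint` | 0.2 | below: conditional signal essentially gone |
| `ps_driver` | 0.5 | driver / partial-joint boundary; also step-3 independence |
| `ps_strong` | 0.8 | independence / strong-driver boundary |
| `p_nominal` | 0.05 | nominal conditional significance inside the rules |
| `collinearity` | 0.999 | residualized-correlation limit before flagging a pair |
| `minGenes` | 50 | smallest gene intersection a fit will accept |
| `nBins` | 100 / 40 | rank bins for comparison / S-score binning |
| winsorization | 50 | TPM cap before log for tissue profiles |

All PS thresholds live in `psConfig()` and flow through the whole
workflow.

## The synthetic generator

`fixtureSpec()` + `simulateProfiles()` + `simulateGeneStats()` generate
complete inputs with known ground truth. Per gene, a log-normal
baseline mean (meanlog 1, sdlog 1) shared by all datasets; per dataset,
a gene-wise log-normal batch factor (sd 0.4 on the natural-log scale)
-- without it, dataset averages would be nearly identical and the
cross-dataset models could read planted programs straight out of
average-expression differences, which no real pair of independently
generated datasets allows. Planted programs are sparse gene sets (5% of
genes) over-expressed by +3 log2 units (about 8-fold, marker-gene
scale) in their member cell types; cells add multiplicative log-normal
noise (sd 0.3) and optional uniform zero inflation. Gene statistics are
built generatively: \(z = \sum \text{effect} \times
\text{standardized loading} + \mathcal{N}(0, 1)\), plus log-normal
gene-length confounders with optional leakage. The Z-noise sd is a
separate field from the expression noise sd so that noise-free
expression fixtures still produce non-degenerate statistics. Cells per
type default to 40-50 in the validation fixtures; 1,200-2,000 genes and
3-5 datasets of 4-5 cell types are the problem sizes the test suite
exercises end to end.

What the generator does *not* emulate: droplet chemistry, library-size
variation, doublets, cell-type abundance imbalance and taxonomy
mismatches across datasets. Passing tests demonstrate that the
machinery recovers planted rank/covariance structure under realistic
batch separation -- not that any particular biological claim about real
traits is reproduced.

`makeConfoundedFixture()` is separate: it couples a gene's specificity
for the first cell type to the gene's overall mean with a chosen
coefficient, and its dropout is deliberately mean-*dependent* (low
expression drops out more), because that is the mechanism that makes
binned S scores correlate with average expression in real data.

## Numerical choices and degenerate inputs

* Fits column-equilibrate the design before the qr decomposition so
  rank detection is insensitive to covariate scale (gene length is
  ~1e4 x larger than log expression).
* Exact rank deficiency raises a structured `collinearityError` naming
  the dependent columns -- e.g. a one-cell-type dataset, where
  \(E_c \equiv A\), or supplying the same dataset twice to a
  cross-dataset fit (\(A_1 \equiv A_2\)). Near-collinearity between the
  two *tested* expression columns is flagged, not raised.
* P-values are floored at 1e-300 before logs; `zFromP()` clips at
  1e-300 and 1 - 1e-16 with a warning and the PS of a marginal P of 1
  is an error (undefined).
* Equal-count binning of an all-zero vector warns and returns all
  bin 0. Ties at the top-decile boundary break by gene id ascending.
* Gene mappings drop unmapped genes, and when two source genes map to
  one target both are dropped (duplicated target ids are excluded);
  one-to-one ortholog tables must be unique in both columns.
* All fits use the intersection of genes present in every input of that
  fit and report `nGenesUsed`, so PS values comparing fits on different
  gene sets can be audited.

## Known limitations

* The gene-property engine approximates, and does not replicate, the
  full LD-aware gene-analysis stack: computing gene-based statistics
  from SNP-level summary data, and reference-panel LD estimation, are
  out of scope. Any additional shrinkage or weighting a dedicated
  implementation applies beyond the stated covariates is not
  reproduced.
* Cell QC, clustering of cells into types, doublet/ambient correction
  and the choice among multiple label resolutions are the caller's
  responsibility; the package consumes one label column per run.
* Conditional analysis measures shared association signal, not
  cell-type identity: two cell types explaining each other's signal
  need not be the same cell type.
* The `ambiguous` scenario is a reconstruction choice for combinations
  the PS rules leave gapped; it is configurable and logged, and
  downstream counts should be read with those flags in mind.
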