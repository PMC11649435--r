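---
title: "Differential proportion analysis of single-cell cluster compositions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Differential proportion analysis of single-cell cluster compositions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cellprop)
library(dplyr)
```

## The problem

Single-cell RNA-seq cohorts are routinely summarised as *compositions*: for
each condition (say, normal kidney versus chronic kidney disease), what share
of the cells falls into each cluster or cell type? When a subpopulation such
as CD16+ NK cells occupies 10% of control cells but only 2% of case cells,
the question is whether that shift is larger than chance given the number of
cells sampled. cellprop implements a permutation answer to that question —
differential proportion analysis (DPA) — together with the quality-control
filtering and clinical stratification that surround it in practice, and a
synthetic cohort generator providing planted ground truth for every stage.

Cluster labels are an *input* here: upstream integration, graph clustering
and annotation are out of scope, as are doublet removal and batch
correction.

## The test

Each cell carries a group label $G$ (one of two conditions) and a cluster
label $L$. For cluster $c$ the statistic is the pooled proportion difference

$$T_c = \frac{n_{c,\text{test}}}{n_\text{test}} -
        \frac{n_{c,\text{ref}}}{n_\text{ref}},$$

so $\sum_c T_c = 0$ identically. The null distribution is generated by
*partial label shuffling*: in each of $B$ iterations, $\lceil wN \rceil$
cells are drawn uniformly without replacement from the pooled dataset and
their cluster labels are shuffled uniformly among the chosen subset; group
labels are never touched, and the global multiset of cluster labels is
preserved exactly. With fraction $w = 1$ this is the classical full
label-shuffle null, under which the per-cluster count in the test group is
hypergeometric. The defaults follow the published procedure: $w = 0.1$ and
$B = 100{,}000$ iterations.

Empirical p-values use the add-one estimator
$p_c = \bigl(1 + \#\{b: |T^*_c(b)| \ge |T_c|\}\bigr)/(B+1)$, so no reported
p is ever zero and the smallest attainable value is $1/(B+1)$. Ties count as
exceedances. A Bonferroni correction $\min(1, K p_c)$ over the $K$ clusters
tested in the comparison at hand is applied, with significance declared at
adjusted $p < 0.05$.

### Design choices in the permutation scheme

The phrase "permuting cluster labels for a fraction of cells" admits two
readings. The default here shuffles labels *within* the random subset, which
preserves the label multiset, keeps the null exactly enumerable, and is
conservative about global composition. The alternative — resampling the
subset's labels from the global label frequencies — is available via
`mode = "resample"` but is not the default, because it perturbs the global
composition and has no finite exact null.

Other conventions, chosen where the procedure's description is silent:

* **Sidedness.** Two-sided by default, since both contractions and
  expansions are of interest. A one-sided `"greater"` mode exists.
* **Subset size.** $\lceil wN \rceil$ (ceiling). At $w \to 0^+$ the subset
  has one cell and a one-element shuffle is the identity, so the null
  degenerates at the observed statistic.
* **Small clusters.** Clusters with fewer than 5 cells in total are reported
  but flagged `reliable = FALSE` rather than dropped.
* **Calibration.** A partial shuffle ($w < 1$) is not an exchangeable null:
  the permuted statistic stays within $O(w)$ of the observed one, so the
  test's level at $w = 0.1$ is characterised empirically rather than
  asserted to equal the nominal level. At $w = 1$ the implementation is
  validated two ways: against an exact enumeration oracle
  (`exact_null_distribution()`, which averages over every subset choice and
  every shuffle on small instances), and by a calibration experiment on an
  independent multinomial null, where the rejection rate of the per-cluster
  tests at raw $p \le 0.05$ falls in a narrow band around the nominal level
  (slightly below it, as expected from inclusive tie counting and the
  add-one estimator on a discrete statistic).

## Quality control

Per-cell metrics are computed from the raw counts: `n_counts` (total
counts), `n_features` (genes detected) and `pct_mito` (percentage of counts
on `MT-` genes; defined as 0 for empty cells, which fail the feature floor
regardless). A cell is retained iff

```
n_features > 200  AND  n_counts < 12000  AND  pct_mito < 30
```

with *strict* inequalities — boundary cells are removed. Thresholds are
configurable through `qc_thresholds()`. Gene categories follow human
nomenclature: mitochondrial `MT-*`, cytosolic ribosomal `RPL*`/`RPS*` (both
case-insensitive); mitochondrial-ribosomal `MRP*` genes are deliberately not
treated as ribosomal. Ribosomal genes can be dropped with
`remove_ribosomal_genes()` *after* metric computation, so metrics always
reflect the raw matrix; the opposite order is defensible but changes
`n_counts`/`n_features` slightly, and computing metrics first keeps them
comparable across analyses that do and do not strip ribosomal genes.

The expressed-gene background rule used for downstream interaction analyses
is provided as `expressed_genes()`: a gene is expressed in a cell group if
it is non-zero in at least 10% of the group's cells (inclusive threshold).

## Clinical stratification

`stratify()` maps per-sample covariates to comparison groups and propagates
them to cells. Built-in rules: serum creatinine splits at 140 uM
("impaired" above), eGFR at 60 mL/min/1.73m^2 ("impaired" below), age into
young (< 30), adult (30–60) and elderly (> 60), and sex as given. The
sources leave values exactly at a threshold unassigned, so each threshold
carries an explicit boundary convention: equality joins the *upper* stratum
for creatinine (140 is "impaired") and eGFR (60 is "normal"), and the age
boundaries 30 and 60 both fall in "adult". All conventions are configurable
via `stratification_rule()`.

## The synthetic cohort generator

The generator emulates the statistical structure the analysis assumes, so
that every stage can be tested against planted truth:

* **Compositions.** A baseline simplex over clusters; per-condition effect
  multipliers (renormalised) plant contractions and expansions; each sample
  draws its composition from a Dirichlet centred on its condition's
  composition with concentration $a$ (default 200, moderate between-sample
  overdispersion: per-sample cluster proportions have variance
  $(n + a)/(1 + a)$ times the multinomial variance at $n$ cells); cells draw
  labels multinomially. The default cohort is 42 control and 23 case
  samples. As $a \to \infty$ the hierarchy collapses to independent
  multinomial sampling, which the tests verify against the closed form.
* **Counts.** Negative binomial per-cell totals, multinomially allocated to
  genes with fixed lognormal gene weights; the mitochondrial share of each
  cell's total is binomially thinned to its class's target fraction. A
  planted `low_quality` class (default 10% of cells, expected total 60
  counts, 40% mitochondrial) sits below the 200-feature floor, giving QC a
  ground truth. The class of every cell is kept in the returned object.
* **Clinical covariates.** Lognormal creatinine (control median 80 uM, case
  250 uM), truncated-normal eGFR (control mean 90, case 35, floor 0), a
  shared age distribution and even sex probabilities. These defaults are
  deliberately arbitrary: they are chosen only to straddle the 140 uM and
  60 mL/min/1.73m^2 decision thresholds so that stratified analyses have
  signal, and are not estimates of any real cohort.

What the generator does *not* emulate: batch effects, doublet expression
profiles, gene–gene correlation, embeddings or spatial structure. Passing
tests therefore demonstrate the correctness and calibration of the
statistical machinery on data satisfying its assumptions, not robustness to
the artefacts real atlases contain.

All randomness flows from one master seed; stages use child seeds derived by
fixed offsets (`child_seed()`), so end-to-end runs are byte-reproducible and
stages are individually re-runnable.

## A worked run

```{r example}
spec <- composition_spec(
  cluster_names = c("NK_CD16", "Tnaive_CD4", "Tmem", "Treg", "NK_CD56"),
  baseline_proportions = c(0.10, 0.10, 0.30, 0.25, 0.25),
  effect_multipliers = c(0.2, 2.2, 1, 1, 1),
  n_samples_per_condition = c(42, 23),
  cells_per_sample = 150,
  seed = 1
)
cells <- simulate_cell_table(spec)
res <- dpa_test(cells, w = 0.1, iterations = 5000, seed = 1)
tidy(res)
glance(res)
```

The planted contraction (`NK_CD16`) and expansion (`Tnaive_CD4`) are the
significant rows; unshifted clusters are not flagged.

```{r plot, fig.width = 6, fig.height = 4}
autoplot(res)
```

## Numerical and scale choices

* Proportion tables are exact rational counts divided by column totals;
  column sums are checked to 1e-12 and $\sum_c T_c$ to 1e-12.
* Exceedance comparisons use a 1e-12 tolerance so that exact ties of the
  discrete statistic, computed by the same arithmetic, are counted
  inclusively regardless of floating-point representation.
* The exact oracle enumerates $\binom{N}{m} \, m!$ outcomes and refuses
  instances beyond $10^6$ outcomes.
* The validation experiments shipped with the package run at reduced but
  statistically meaningful sizes chosen to keep a complete check of the
  pipeline in the minutes range: oracle comparison at $B = 50{,}000$ on an
  8-cell instance, null calibration with 1,000 replicates of 2,000 cells at
  $B = 1{,}000$, and power analysis with 100 replicates of 6,000 cells at
  $B = 2{,}000$. The acceptance script runs the headline cohort analysis at
  the full $B = 100{,}000$.

## Limitations

* The partial-shuffle null at $w < 1$ is a procedural convention, not an
  exchangeable null; its level is characterised empirically at $w = 1$ only.
* Pooled proportions ignore the sample hierarchy; per-sample proportion
  tables are provided for diagnostics, but no mixed-model or
  Dirichlet-multinomial regression alternative is implemented.
* Bonferroni is the only multiplicity correction offered, matching the
  analysis this package operationalises.
* eGFR is taken as a given covariate, never estimated from creatinine.
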