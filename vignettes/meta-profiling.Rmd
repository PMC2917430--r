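---
title: "Coexpression-signature meta-profiling: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coexpression-signature meta-profiling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coexsig)
```

# The analysis

coexsig asks a simple question about a gene of interest — call it the
*reference gene*, the canonical example being the stress enzyme heme
oxygenase-1 (HMOX1/HO-1): do the genes that respond to this gene in a
controlled two-condition cell-line experiment also track its expression
across a large, heterogeneous collection of tumors? The answer is assembled
from four pieces:

1. **Differential expression.** A two-condition experiment (e.g. a control
   line versus a knockdown line, a few replicate arrays each) is tested
   gene by gene with an empirical-Bayes *moderated t-statistic*. On log2
   intensities, the per-gene pooled variance $s^2_g$ (residual df
   $d = n_1 + n_2 - 2$) is shrunk toward a prior,
   $\tilde s^2_g = (d_0 s_0^2 + d\, s^2_g)/(d_0 + d)$, and
   $t_g = \Delta_g / \sqrt{\tilde s^2_g (1/n_1 + 1/n_2)}$ is referred to a
   t distribution on $d_0 + d$ df. Benjamini–Hochberg adjustment controls
   the FDR. The *signature* is the set of genes expressed at least 2-fold
   higher in the reference condition at adjusted p < 0.05 — the genes that
   need the reference gene to be fully expressed.
2. **Neighbor ranking.** In the tumor compendium, every gene is scored by
   its *Pearson distance* $1 - r$ to the reference gene's profile and
   ranked ascending, so rank 1 is the most tightly coexpressed gene.
3. **Positional enrichment.** Walking the ranked list, a running sum gains
   $+1/k$ at each signature gene and $-1/(n-k)$ elsewhere; the *KS score*
   is its maximal prefix value (at least 0, at most 1). A front-loaded
   signature — coexpressed with the reference across tumors — scores near
   1.
4. **Permutation null.** The observed KS score is compared with the scores
   of random same-size gene sets drawn uniformly from the filtered gene
   universe; the fraction of random sets scoring at least as high is the
   empirical p-value.

# Parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| `iqr_min` | 0.5 | log2 intensity | variation filter: minimum interquartile range |
| `intensity_min` | 100 | relative units | variation filter: at least one sample must exceed it |
| `low`, `high` | 50, 15000 | relative units | compendium filter intensity window |
| `majority` | 0.5 | fraction | how many samples must violate the window (strict) |
| `comp_fold_min`, `comp_diff_min` | 2, 50 | fold / relative units | compendium dynamic-range rules |
| `p_adj_max`, `fold_min` | 0.05, 2 | — | signature selection |
| `k_select` | 14 | genes | nearest signature genes to report |
| `n_perm` | 100000 | draws | permutation budget |

The filter thresholds are the standard array-era conventions for data on a
positive "relative units" scale with saturation around 15,000; they are
exposed rather than hard-coded so the pipeline can be recalibrated for
other platforms.

# Numerical and convention choices

Several choices were genuinely open and are fixed here as package
conventions:

* **IQR scale.** The variation filter's interquartile range is computed on
  log2 intensities (values floored at 1 first), with type-7 (linearly
  interpolated) quantiles. On the raw scale a threshold of 0.5 relative
  units would be vacuous; the log2 scale makes it a meaningful
  dispersion bar. A `log2_scale = FALSE` escape hatch exists.
* **"More than half"** is a strict majority: a gene below the floor in
  exactly half of the arrays survives.
* **Fold-spread denominator** is clamped at 1 (`max / max(min, 1)`) so
  near-zero minima cannot manufacture huge folds.
* **Pearson distance** is $1-r$ with range $[0,2]$, computed on raw
  filtered intensities; a `log2_scale` flag offers the alternative. Ties
  in distance are broken by lexicographic gene id so rankings are
  deterministic. Constant genes have no defined correlation and are
  excluded with a warning rather than assigned a pseudo-distance.
* **KS statistic form** is the one-sided positive deviation (the classical
  $D^+$ in running-sum form): "high score = clustered near the top", and
  the permutation p is its upper tail. The two-sided form would also
  reward signatures *anti*-correlated with the reference, which is not
  the scientific question.
* **Permutation universe.** Random sets are drawn from the post-filter
  ranked universe (which excludes the reference gene itself), matching
  what the observed signature was located in. Observed-vs-permutation
  comparison uses `>=` with a 1e-12 absolute tolerance so float ordering
  cannot flip a count.
* **Two p-values.** The plain frequency `count_ge / n_perm` — which can
  legitimately be 0 — is reported as `p_empirical`; the add-one
  `(count_ge + 1) / (n_perm + 1)` is reported alongside as
  `p_conservative` and is the one to use for calibration claims.
* **Signed fold change** follows the array-era convention ($r$ if
  $r \ge 1$, else $-1/r$, from raw-scale group means), while the
  t-statistic works on log2 means; both are reported per gene.
* **Prior estimation** moment-matches $\log s^2$ under the
  scaled-inverse-$\chi^2$ model via the digamma/trigamma relations. When
  the spread of $\log s^2$ does not exceed its theoretical minimum the
  prior df estimate diverges; it is then capped at `d0_cap` (default
  `10 * d`) and flagged, with $s_0^2$ set to the geometric mean of the
  positive variances (for identical variances, that common value). An
  infinite-`d0` prior is also accepted and means full shrinkage.
* **`k_select` applies to the mapped signature**, not the raw one: the
  reported "top k" are the k nearest signature genes that exist in the
  compendium after identifier mapping (duplicate symbols collapse to the
  probe with maximal mean intensity by default).

# What the synthetic data emulates — and what it does not

The generators produce desk-scale surrogates with the statistical
structure the analysis assumes, plus a ground-truth record for recovery
tests.

* `simulate_two_group_experiment()`: log2-normal background intensities
  (baseline mean 8, sd 1.5 on the log2 scale — a positive, heavy-right-
  tailed intensity scale), triplicate arrays per condition, replicate
  noise sd 0.35 (log2), and planted genes whose reference-condition mean
  is shifted by `log2(fold)` with folds drawn log-uniformly in 2–8,
  matching the spread of fold changes such experiments report.
* `simulate_tumor_compendium()`: 190 specimens over 14 decorative tumor-
  type labels; a reference gene with a broad log-normal profile; a module
  of genes built on the standardized scale as
  $\rho z_{\mathrm{ref}} + \sqrt{1-\rho^2}\,\varepsilon$ and affinely
  mapped into the positive range (so the target Pearson $\rho$ is exact
  in expectation and unaffected by the mapping); background genes
  independent of the reference (log2 means uniform in 8–11.5, replicate
  sd 0.8, saturating at 15,000); and deliberate violators of each filter
  rule (mostly-below-50, mostly-above-15,000, flat). An optional per-type
  mean shift can stress the ranking; by default type labels carry no
  signal, since the ranking ignores them.

Not emulated: probe-level effects, RMA normalization, batch structure,
inter-gene correlation beyond the planted module, or realistic tumor-type
covariance. Passing recovery tests therefore shows the *pipeline logic*
is sound — filters remove what they claim, planted structure is found at
the planted strength, null inputs give uniform p-values — not that any
particular biological dataset would yield any particular signature.

One interaction worth knowing: with triplicate arrays and replicate noise
0.35, a null gene's log2 IQR sits just below the 0.5 filter bar, so the
variation filter is stringent on undifferentiated genes (roughly a
fifth of the background survives) while genes with real between-group
shifts pass easily. That mirrors the filter's purpose — selecting
informative genes — and leaves recovery statistics unaffected.

All generators take explicit integer seeds and use R's Mersenne-Twister
with fixed normal/sample kinds, so identical configs are byte-identical
across platforms.

# Problem sizes used in the checks

The package's own acceptance checks run at the study's scale where that
is cheap, and at reduced scale where exhaustive enumeration is the point:
KS-score equivalence is enumerated over *every* subset of lists up to
length 8; exact permutation arithmetic on the worked 4-choose-2 case;
null calibration with 2,000 replicates at list length 500, query size 14,
2,000 permutations each (the sampled-mode inner loop is implemented in
C++, so this takes seconds); and planted-signature recovery over 10 seeds
of a 2,000-gene, 190-specimen compendium with a 20-gene module at
$\rho = 0.8$ and 10,000 permutations.

# Worked example

```{r example, eval = FALSE}
comp <- simulate_tumor_compendium(
  compendium_sim_config(n_genes = 2000, module_size = 20, rho = 0.8,
                        seed = 7))
cell <- simulate_two_group_experiment(
  two_group_sim_config(
    n_genes = 2000, gene_ids = rownames(comp$matrix),
    de_up_ids = c(comp$truth$module_genes, comp$truth$reference_gene),
    n_de_down = 50, fixed_fold = 4, seed = 8))

res <- run_meta_profiling(
  cell$matrix, cell$classes, comp$matrix, "HMOX1",
  params = pipeline_params(n_perm = 100000, k_select = 14, seed = 42))

glance(res)
autoplot(res$enrichment)
```

# Known limitations

* Two-group designs only; no general design matrices, array weights or
  duplicate-correlation structure.
* Identifier mapping is case-insensitive symbol intersection; no
  annotation databases are consulted, so cross-platform recovery depends
  on shared symbols.
* The enrichment statistic is unweighted; score-weighted variants and
  normalized enrichment scores are intentionally out of scope.
* Exhaustive permutation mode is capped (default $10^6$ subsets); beyond
  that, sampled mode with a seed is the supported path.
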