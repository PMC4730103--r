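---
title: "Expression-weighted cell-type enrichment: model, parameters, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Expression-weighted cell-type enrichment: model, parameters, and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(ewcer)
library(dplyr)
```

## The question the method answers

Given a list of genes — disease susceptibility genes from human genetics, or
the most differentially expressed genes of a post-mortem cohort — which cell
type expresses them most? A marker-gene approach answers this only for genes
that are strong, exclusive markers. The expression-weighted approach instead
uses *every* gene's quantitative expression profile across cell types, so a
list of genes that are each only mildly biased toward, say, microglia can
still produce decisive evidence when the bias is consistent across the list.

## The specificity matrix

The reference is an annotated single-cell RNA-seq dataset: a genes-by-cells
matrix of non-negative expression values $r_{g,i}$, each cell carrying a
fine-grained sub-cell-type label, and each sub-cell type belonging to a
broader cell type. For gene $g$ and sub-cell type $c$ with $N_c$ cells, the
mean expression is $\bar r_{g,c} = \sum_{i : l_i = c} r_{g,i} / N_c$, and the
**specificity** of $g$ for $c$ is the proportion

$$ e_{g,c} = \frac{\bar r_{g,c}}{\sum_{r} \bar r_{g,r}}, $$

so each gene's row sums to 1 and is independent of the gene's overall
expression level. That independence is also why a low-expression filter is
required: a gene seen in a handful of reads in one cell would look like a
perfect marker. A gene is kept only if its mean expression **strictly
exceeds 0.2** (in the units of the input counts) in at least one sub-cell
type; the threshold is configurable (`drop_low_expression_genes()`), the
comparison deliberately strict so a gene sitting exactly on the boundary is
dropped.

Cell-type-level specificity is the sum of the sub-cell-type specificities
within each parent, $p_{g,e} = \sum_{c : m_c = e} e_{g,c}$ — the sum of
proportions, not the proportion of pooled means, so row sums are conserved
exactly. Note the two are not interchangeable: pooling cells before
normalising would weight sub-cell types by their cell counts.

No per-cell library-size normalisation is applied by default; the method is
defined on the distributed count matrix as-is. A user who wants
pre-normalised input can pass any matrix of non-negative values.

## The bootstrap test

For a target list $X$ of $n$ genes, the test statistic per group $c$ is the
summed specificity $\gamma(X,c) = \sum_{g \in X} e_{g,c}$. Its null
distribution is estimated by drawing `reps` random lists $D_j$ of the same
length, without replacement, uniformly from a **background** gene universe
$B$ (all genes surviving the expression filter; in transcriptome mode,
additionally restricted to genes detected in the disease study). Then

* $p(c) = \left(\#\{j : \gamma(D_j,c) \ge \gamma(X,c)\} + 1\right)/(\mathrm{reps}+1)$,
* fold enrichment $\phi(c) = \gamma(X,c) / \overline{\gamma(D,c)}$,
* z-score $d(c) = (\gamma(X,c) - \overline{\gamma(D,c)}) / \mathrm{sd}_j\,\gamma(D_j,c)$.

Numerical conventions, all of which matter at the margins:

* Ties count **against** the target ($\ge$), the conservative direction.
* The $+1/(\mathrm{reps}+1)$ correction prevents a finite bootstrap from
  reporting $p = 0$; `p_method = "raw"` gives the plain fraction
  $k/\mathrm{reps}$, where 0 should be read as "below $1/\mathrm{reps}$".
* The z-score uses the sample standard deviation (denominator
  $\mathrm{reps}-1$); at the default 100,000 replicates the distinction is
  far below reporting precision. A zero-spread null yields `z = NA` while
  `p` and `fold` remain valid.
* The default replicate count is 100,000. At that depth the Monte-Carlo
  standard error of a p-value near 0.05 is about 0.0007.

Multiple-testing correction (`correct_pvalues()`, via `stats::p.adjust`) is
Bonferroni by default for gene-list scans; transcriptome mode applies
Benjamini–Hochberg across both directions and all groups as a single family.
The family is always exactly what is passed in one call — nothing is
corrected implicitly across calls.

## Property-controlled sampling

Gene lists that come out of genetic studies are biased toward long genes
(more sequence in which to find associations) and genes of atypical GC
content. If transcript length also co-varies with cell-type specificity,
the uniform bootstrap null is wrong and the test anticonservative. The
controlled mode removes this bias structurally:

1. Over the background, compute empirical deciles of mean transcript length
   and of GC fraction (`build_decile_grid()`); the two axes define a 10×10
   grid and each gene falls in one cell.
2. For every replicate, the gene at position $i$ is drawn from the **same
   grid cell** as target gene $i$.

Convention details: decile boundaries are type-7 empirical quantiles; bins
are right-closed (a gene sitting exactly on a boundary belongs to the lower
bin); boundaries equal to the axis maximum are discarded so the top bin is
never empty; tied axes collapse to fewer bins with a warning. Within one
replicate all genes are distinct whenever feasible — since grid cells are
disjoint, drawing without replacement within each cell guarantees this; a
cell asked for more genes than it holds falls back to with-replacement
draws for those positions and says so once. Genes lacking properties are
excluded from controlled analyses with a warning rather than imputed.

Ortholog handling is part of the same universe-construction step: human
lists are mapped onto the (typically mouse) reference through a file-based
table reduced to strict 1:1 pairs. Many-to-many relations are dropped with
a report rather than silently collapsed — specificity is a per-gene
quantity and an ambiguous mapping would double-count expression. The
mapping direction is the user's choice of table orientation.

## Transcriptome mode

For a differential-expression study the inputs are per-probe t-statistics.
The up-regulated set is the 250 probes with the largest positive t, the
down-regulated set the 250 most negative; duplicate gene symbols within a
selected set are collapsed after selection, keeping the most extreme probe,
and the null lists are drawn at the resulting (possibly shorter) length.
Boundary ties are broken by stable input order and noted. The background is
restricted to genes detected in the study, which makes the null equivalent
to re-ranking the detected genes at random. Both directions reuse the same
bootstrap seed, so negating every t-statistic swaps the up and down results
exactly — a useful end-to-end integrity check. Differential expression
itself is out of scope here: the interface starts at the ranked table.

Controlled sampling is available in this mode behind a flag but is off by
default; the length/GC bias argument applies to how genetic associations
are discovered, not to how a ranked expression contrast is thresholded.

## Merging independent studies

When several cohorts measure the same contrast, their evidence is pooled by
summing: consensus null matrix $= \sum_s \Gamma^{(s)}$ element-wise over
aligned replicates, consensus target $= \sum_s \gamma^{(s)}(X)$, and $p$,
$\phi$, $d$ recomputed from the sums exactly as for one study
(`merge_bootstrap()`). This makes two invariants exact by construction:
merging a study with itself reproduces its single-study $p$ and $\phi$
(indicators and ratios are invariant to doubling), and merging with an
all-zero degenerate study changes nothing. Studies must share the group
set and replicate count; mismatches are refused rather than resampled,
since index-aligned summation presumes equal-shaped matrices. Saved null
matrices (`write_null()`/`read_null()`) are the exchange format, so merging
is pure post-processing.

## What the synthetic generator emulates — and what it does not

`simulate_sct()` plants known structure: each sub-cell type owns a disjoint
marker set whose mean expression is elevated `marker_effect`-fold in that
sub-cell type; counts are negative binomial with dispersion 0.5 by default
(UMI-like overdispersion) or Poisson for closed-form checks. Under Poisson
noise with $k$ sub-cell types, a marker's expected specificity in its own
group is approximately $\mathrm{effect}/(\mathrm{effect} + k - 1)$, which
the test suite verifies at `marker_effect = 50`. With `marker_effect = 1`
genes are exchangeable and the whole pipeline must be calibrated.

The generator deliberately does **not** model dropout/zero inflation beyond
the NB, doublets, batch effects, or realistic library-size variation.
Passing tests therefore demonstrate the statistical machinery is correct
under its stated assumptions, not that any particular biological reference
is adequate for a given disease question.

The property simulator (`simulate_gene_properties()`) draws log-normal
transcript lengths (median ≈ 2.5 kb, log-sd 0.9) and beta GC fractions
(mean ≈ 0.47), the broad shape of mammalian annotation. With
`correlation > 0` it skews the length percentile of one group's markers
upward ($u \mapsto u^{1/(1+4\rho)}$), creating the confound the controlled
bootstrap exists to fix. `simulate_biased_list()` then draws lists with
probability proportional to the length-decile index raised to a power.
Because that bias is a function of the decile index alone, inclusion is
uniform *within* every grid cell, so the decile-grid bootstrap is exactly
calibrated for such lists while the uniform bootstrap is not — the cleanest
possible demonstration of what the control does and why it works.

## Validation and the problem sizes used

The test suite and `scripts/acceptance.R` validate, at sizes chosen to keep
a full run within a few minutes on one core:

* **Oracle agreement**: on a hand-built 6-gene, 3-group matrix with lists
  of 2, exhaustive enumeration of all 15 pairs gives the exact p per group;
  the bootstrap at 100,000 replicates agrees within three binomial standard
  errors.
* **Null calibration**: an exchangeable reference (800 genes, 5 sub-cell
  types × 20 cells), 1,000 random 20-gene lists against a shared
  5,000-replicate null: p-values pass Kolmogorov–Smirnov uniformity at
  α = 0.01 and the empirical type-I error at nominal 0.05 lies in
  [0.03, 0.07].
* **Power**: marker_effect 10, purity-1 lists of 20, 200 draws: the planted
  group is detected (p < 0.05) in ≥ 95% of runs and has the smallest p in
  ≥ 99%.
* **Confound correction**: with subtype-1 markers made long
  (correlation 1) and lists drawn with a decile³ length bias, the
  uncontrolled bootstrap's type-I error exceeds 0.10 by a wide margin while
  the controlled bootstrap stays within [0.03, 0.07], over 500 lists at
  2,000 replicates each.
* **Exact invariants**: row-stochasticity at both levels (±1e-9), per-gene
  scale invariance, the strict 0.2 filter boundary, self-merge identity,
  t-negation antisymmetry, duplicate-probe list-length bookkeeping, and
  byte-identical outputs under identical seeds.

## Known limitations

* The test is one-sided for enrichment; depletion shows up only as
  $p \to 1$ (or through the z-score's sign).
* Closely related cell types share most of their transcriptome, so a list
  genuinely specific to one neuronal class will usually also enrich its
  relatives; the method ranks, it does not deconfound correlated groups.
* Sub-cell types sequenced at low depth (few cells) carry noisy mean
  estimates; nothing in the statistic down-weights them.
* The controlled mode conditions on length and GC deciles only; other gene
  properties (e.g. brain-expression breadth) are not controlled.
* Merging weights studies equally per replicate; there is no meta-analytic
  weighting by cohort size.
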