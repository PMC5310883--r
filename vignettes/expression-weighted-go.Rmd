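---
title: "Expression-weighted GO enrichment across ordered samples: methods"
author: "ewGO"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Expression-weighted GO enrichment: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ewGO)
options(ewGO.logLevel = "WARN")
```

## The problem and the model

Classical GO over-representation analysis (ORA) tests a short list of
differentially expressed genes against a background with a Fisher-exact or
hypergeometric test. Two things are lost in that design: the actual
expression level of each gene (every listed gene counts equally), and the
ability to follow more than two conditions at once. ewGO implements a
hypothesis-unbiased alternative in which *every* expressed gene
contributes to GO enrichment, weighted by its mRNA level, across an
ordered series of K samples (time points, disease stages, strains ordered
by phenotype, ...).

For genes $g_1 \ldots g_N$ and samples $s = 1 \ldots K$, the enrichment
score of term $t$ in sample $s$ is

$$ES_{t,s} = \sum_{i=1}^{N} \log_2\!\left(e(i,s) + 1\right) \cdot I(i,t)$$

when $e(i,s)$ is a non-negative abundance (RPKM/FPKM), or

$$ES_{t,s} = \sum_{i=1}^{N} \log_2\!\left(2^{e(i,s)} + 1\right) \cdot I(i,t)$$

when $e(i,s)$ is a microarray log2 fold change. $I(i,t)$ is the indicator
that gene $i$ is annotated to term $t$. The indicator is applied in both
modes; without it every term would receive the same score, so we read the
second form as carrying the same annotation indicator as the first. The
$+1$ inside the logarithm keeps unexpressed genes ($e = 0$) at zero weight
in abundance mode and gives a zero-change gene one unit of weight in
log-fold-change mode; both weights are monotone increasing in expression,
which is what lets lowly expressed genes participate through cumulative
effects rather than being discarded by a significance cutoff.

Cross-sample behaviour of a term is summarized by the stepwise fold
changes $F_{t,s} = ES_{t,s+1} / ES_{t,s}$ and their geometric mean

$$F_t = \left(\prod_{s=1}^{K-1} F_{t,s}\right)^{1/(K-1)},
\qquad
\log_2 F_t = \frac{1}{K-1} \sum_{s=1}^{K-1} \log_2 F_{t,s}.$$

The product telescopes, so $F_t = (ES_{t,K}/ES_{t,1})^{1/(K-1)}$: the
average is driven by the first and last samples, while the stepwise values
retain the full order sensitivity (reversing the sample order negates
$\log_2 F_t$; permuting interior samples changes the steps but not the
average). Both forms are reported because published fold values are quoted
sometimes on the linear and sometimes on the log2 scale.

Two derived views complete the per-term summary. The enrichment proportion
$EP_{t,s} = ES_{t,s} / \sum_{t'} ES_{t',s}$ normalizes scores within a
sample (proportions over the chosen term set sum to 1; this is the
pie-chart view, computed per GO level by the pipeline). Monotone trend
flags mark terms whose scores never decrease, or never increase, between
consecutive samples; the inequalities are non-strict, so a constant
trajectory carries both flags.

## Outlier detection over GO levels

The interesting terms are the ones whose average fold change is extreme
relative to their peers. Peers are defined by GO level: the level of a
term is the length of the shortest path to its namespace root over the
`is_a` and `part_of` relations (roots at level 0). Shortest-path depth is
the convention of mainstream GO browsers; it also makes the "deepest
level" well defined as the maximum level over annotated terms. The three
namespaces are analysed independently and cross-namespace edges are
ignored.

The search starts at the deepest annotated level, applies a two-sided
Grubbs test to the $\log_2 F_t$ values of the included terms at exactly
that level, and ascends one level at a time until some level yields at
least one outlier or level 1 has been visited. The Grubbs statistic is
$G = \max_i |x_i - \bar{x}| / s$ with critical value
$\frac{n-1}{\sqrt{n}} \sqrt{t^2 / (n - 2 + t^2)}$, $t$ the upper
$\alpha/(2n)$ quantile of Student's t on $n-2$ degrees of freedom. Levels
with fewer than three eligible terms, or with zero spread, cannot be
tested and are recorded as skipped.

Choices that the method description leaves open, and what this package
does about them:

* **Sidedness, iteration, alpha.** Default two-sided, $\alpha = 0.05$,
  with iterative removal (a flagged term is removed and the test repeated)
  so that several terms can be reported per namespace, which matches how
  results of this kind are usually presented. Ties at the maximal
  deviation are flagged together. Both iteration and alpha are arguments.
* **Stopping rule.** The search stops at the first level with any outlier
  rather than accumulating across levels; deeper hits are more specific
  and therefore more informative.
* **Multiple testing across levels.** None by default; an optional
  Bonferroni correction over the testable levels sits behind
  `bonferroni = TRUE`.
* **Annotation propagation.** Whether scores should be computed over
  direct annotations or over the true-path closure (gene annotated to a
  term is annotated to all its ancestors) is a genuine modelling choice.
  Propagation is the default (`propagateAnnotations()`), because without
  it most mid-level terms score zero and the level search has nothing to
  test; `usePropagated = FALSE` switches it off. With propagation, a
  parent's score dominates each child's score in every sample, since its
  annotated gene set is a superset.

**Zero scores.** A term with $ES_{t,s} = 0$ in any sample admits neither a
ratio nor a logarithm. Such terms are excluded from the fold and outlier
statistics, flagged (`included = FALSE`), and listed in a separate
zero-score report. A pseudocount would have manufactured fold changes the
model never defines, so none is used. Excluded terms carry `NA` averages,
never silent zeros.

## Comparing two whole distributions

With exactly two samples one can ask whether overall enrichment differs
at all. GO terms act as bins. The chi-square variant uses each sample's
scores directly - unrounded - as the bin counts of a 2 x m homogeneity
table (df = m - 1). Because real-valued scores stand in for counts, the
statistic scales with sequencing depth (doubling all scores doubles it);
this caveat is documented rather than "fixed", and cells with expected
value below 5 are counted and reported as a warning. The
Kolmogorov-Smirnov variant treats each sample's per-term scores as one
empirical distribution and reports $D = \sup |ECDF_a - ECDF_b|$ with the
asymptotic p-value; KS is not a paired test, so the term pairing survives
only in the report's bin listing. Both are computed through the standard
`stats` implementations.

## The synthetic-data generator

`scenarioSpec()` / `simulateScenario()` build a complete, deterministic
test bed: a single-namespace layered DAG (one root, a configurable number
of terms per level, each non-root term with one round-robin parent in the
level above plus occasionally a second), with each deepest-level term
directly annotating its own block of genes, and an abundance matrix whose
shape mimics a genes-by-ordered-samples RPKM table.

Baseline abundances are log-normal with median 10 and log-sd 1.5, a
dynamic range typical of RPKM data; both parameters are arguments. From
sample to sample the matrix evolves on the $\log_2(e+1)$ scale - the scale
on which genes enter the score - by adding Gaussian noise with sd
`noiseSd` per gene and step, and, for the genes of the planted term,
multiplying $\log_2(e+1)$ by `plantedFold`. Planting on this scale is what
makes the ground truth closed-form: the planted term's score is scaled by
exactly `plantedFold` per step, so its theoretical $F_t$ *equals*
`plantedFold`, with no approximation, in the noiseless limit, and every
untouched term sits exactly at 1. (Multiplying raw $e+1$ instead would
shift scores additively and leave no closed-form fold target.) Negative
log-abundances produced by noise are clipped to zero and counted.

Defaults - 9 deepest terms, 20 genes per term, K = 3, fold 4, noise sd
0.1 - are the conditions under which the validation suite measures
recovery. What the generator does *not* emulate: correlated expression
between genes, annotation noise, multi-namespace ontologies, shared genes
between sibling terms, or read-level sequencing artefacts. Passing the
planted-recovery tests therefore demonstrates correctness of the
statistical machinery, not robustness to everything real data can do.
Note also that planting multiplies log-abundances per step, so large
`K` x `plantedFold` combinations produce astronomically large abundances;
at the default K = 3 this is harmless.

## Numerical choices

* Identity checks (telescoping, $2^{\log_2 F} = F$, EP column sums) hold
  to relative 1e-9 in the validation suite; in practice they sit at
  machine precision.
* Report TSVs serialize numbers with 12 significant digits and fully
  specified row ordering (level descending, $|\log_2 F_t|$ descending,
  accession), so reruns are byte-identical.
* Duplicated gene identifiers in an expression table are a fatal
  validation error - aggregating silently would make $e(i,s)$ ambiguous.
* Genes present in the expression matrix but absent from the annotations
  simply contribute to no term; their count is logged. Genes annotated
  but not measured contribute nothing.
* Grubbs needs at least 3 values and positive spread; constant data is a
  degenerate-statistics error, not a silent pass.
* Obsolete terms are excluded from levels, scoring and reports;
  annotations pointing at them are remapped via `replaced_by`/`alt_id`
  when possible, otherwise dropped and counted.

## Validation problem sizes

The shipped test and validation suites use: 1000 random score tables for
the algebraic identities; 100 random fixtures for propagation
monotonicity; the full n = 3..50 sweep against a numerical-integration
t-quantile oracle plus a 10,000-replicate Monte-Carlo type-I calibration
for the Grubbs test; and 100 seeded noisy scenarios (9 deepest terms,
20 genes/term, noise 0.1) for exact planted-term recovery, alongside the
noiseless exactness check. These sizes give stable statistics while
keeping a full run in the low minutes on one core.

## Limitations

* Case-study-scale inputs (tens of thousands of genes against a full GO
  release) depend on the annotation snapshot used; numbers quoted against
  one GO release will not reproduce exactly against another. Record the
  ontology and annotation versions next to any result (the run manifest
  stores input checksums for this reason).
* The chi-square comparison inherits the scores-as-counts scale
  dependence described above; compare samples at comparable depth, or
  prefer the KS variant.
* Grubbs assumes an approximately normal null for the per-level fold
  values; heavy-tailed nulls will inflate discoveries. The Monte-Carlo
  calibration covers the normal case only.
* Abundance inputs are assumed already normalized (RPKM/FPKM);
  the package does not normalize raw counts.
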