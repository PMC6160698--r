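---
title: "Methods: coexpression-based functional annotation of metabolism-associated lncRNAs"
author: "lncmetnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: coexpression-based functional annotation of metabolism-associated lncRNAs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lncmetnet)
```

## Overview

`lncmetnet` implements a workflow for characterizing metabolism-associated
long noncoding RNAs (lncRNAs) from a small paired tumor/normal expression
microarray:

1. **Differential expression** — quantile normalization, a presence filter,
   and volcano-style selection (fold change > 1.5 and p < 0.05) of lncRNAs
   and protein-coding genes, optionally intersected with an external
   direction-labeled differential list.
2. **Coexpression network inference** — all-pairs Pearson correlation,
   Fisher z-transform asymptotic p-values, Benjamini–Hochberg FDR edge
   selection at adjusted p < 0.05, and multi-dataset consensus by minimum
   support.
3. **Guilt-by-association annotation** — lncRNA hubs (more than 3 directly
   coexpressed protein-coding genes) inherit the GO biological-process terms
   over-represented in their neighborhoods (hypergeometric upper-tail test,
   BH-adjusted p < 0.05).
4. **Network integration** — coexpression links, protein–protein
   interactions and miRNA–target regulations (kept only when the miRNA is
   differentially expressed in the direction opposite to its target) are
   merged into one typed multigraph with a link-type/overlap summary.
5. **qPCR verification statistics** — relative expression by the
   comparative threshold-cycle method (2^−ΔΔCq), a paired tumor-vs-normal
   t-test, and a clinicopathological association table (two-sample t-test
   for two categories, one-way ANOVA for three or more).

Every stage is driven by a synthetic-data generator with planted ground
truth, so the statistical machinery is testable end-to-end without any
downloads.

## Statistical model and procedures

### Differential expression

Intensities are analyzed on the log2 scale. Quantile normalization forces
every sample column onto the per-rank mean distribution of all columns; ties
within a column receive the mean of the reference values over their tied
ranks, which makes the operator deterministic and idempotent. The presence
filter retains probes flagged as expressed in at least `min_present`
samples (default 3 of 6); flags normally come from the vendor's detection
calls, with an above-column-median fallback when no calls exist. The
fallback is deliberately crude — it discards consistently low-intensity
probes — and vendor calls should be preferred whenever available.

Per-probe testing uses a two-sided t-test on log2 values. The default is
Welch's unpaired two-sample test; `paired = TRUE` switches to a paired test
on within-pair differences. Both are exact algebra plus the t distribution,
vectorized across 10⁴-row matrices, and are cross-checked against
`stats::t.test` in the unit tests. At very small group sizes (3 vs 3)
Welch's test is noticeably conservative (empirical type-I error ≈ 0.035 at
nominal 0.05) because the Satterthwaite degrees of freedom are estimated
from two variances of two degrees of freedom each; the paired test is
exactly calibrated under normality and is the better choice for a paired
design. Both behaviors are measured in the test suite.

Selection uses strict inequalities: up means fold change > 1.5 **and**
p < 0.05; down means fold change < 1/1.5 and p < 0.05. A fold change of
exactly 1.5 is excluded. Fold change is oriented tumor/normal, so "up"
means higher in tumor.

### Coexpression and the Fisher asymptotic p-value

For gene pair profiles of length $n$, the correlation $r$ is converted to a
p-value by the Fisher z-transform:
$$z = \tfrac{1}{2}\ln\frac{1+r}{1-r}, \qquad z\sqrt{n-3} \sim N(0,1)
\text{ under } H_0,$$
with $p = 2\Phi(-|z|\sqrt{n-3})$. This is the normal-approximation dialect
used by WGCNA-style pipelines; the Student-t alternative
$t = r\sqrt{n-2}/\sqrt{1-r^2}$ is available via `method = "t"`. $|r| = 1$
maps to $p = 0$; $n < 4$ is rejected because $\sqrt{n-3}$ degenerates. The
test suite verifies calibration against a permutation null and a 10,000
replicate true-null simulation at $n = 20$ (rejection rate 0.05 ± 0.007).

The BH family for edge selection is the full batch of $g(g-1)/2$ tested
pairs (not per-gene). Constant genes are dropped with a message before
correlation. Edges are stored as canonical (lexicographically ordered)
pairs with the sign of $r$; the network object also records `genes_tested`,
the gene space it was built over, which downstream enrichment uses as its
universe.

Multi-dataset consensus keeps an edge detected in at least `min_support`
input networks (default 50, for collections of public coexpression
datasets). Edge identity is the unordered node pair; sign disagreement
across datasets is ignored by default (`strict_sign = TRUE` requires
consistency), because a detection-based consensus rule is agnostic to sign.

### Guilt-by-association GO annotation

Only lncRNA *hubs* — strictly more than `min_neighbors` (default 3, i.e. at
least 4) directly coexpressed protein-coding genes — are annotated, both
edge signs counting. For each hub, every GO term with at least one
annotated neighbor is scored by the hypergeometric upper tail
$$p = \sum_{k=x}^{\min(n,K)} \frac{\binom{K}{k}\binom{N-K}{n-k}}{\binom{N}{n}},$$
where $N$ is the universe size, $K$ the universe genes annotated to the
term, $n$ the hub's annotated neighbors, and $x$ the overlap. Evaluation is
log-space-stable (`stats::phyper`); the tests verify it against exhaustive
enumeration of all draws for $N \le 12$ and against one-sided Fisher exact
p-values.

Two genuinely open choices were resolved as follows:

* **Universe.** $N$ = genes of the gene-set collection intersected with the
  *gene space the network was built over* (all genes tested for
  coexpression), not merely the genes that happen to have significant
  edges. Restricting to edge endpoints collapses $N$ toward $K$ for exactly
  the terms one hopes to detect and destroys the contrast between signature
  and background terms; using the assayed gene space matches standard
  over-representation practice, where the background is what was measured.
  An explicit `universe` argument overrides this.
* **Adjustment family.** BH is applied per lncRNA over its own tested
  terms, since each lncRNA's annotation is a separate question; a global
  family across all lncRNA–term pairs is available via
  `family = "global"`.

Ties in the top-k ranking are broken by larger overlap $x$, then term id,
so output is deterministic.

### Network integration

The integrated network is a typed multigraph: one node pair may
simultaneously carry `ppi` and `coexpr_pos`/`coexpr_neg` edges.
miRNA–target edges are directed miRNA → target; coexpression and PPI edges
are undirected and stored canonically. Structural invariants are enforced
at construction: no self-loops, every miRNA–target edge has exactly one
miRNA endpoint, coexpression edges never touch miRNA nodes. The
opposite-direction filter keeps a (miRNA, target) pair only when the two
differential directions differ; pairs with unknown direction on either side
are dropped with a logged count. PPI/coexpression overlap is keyed on the
unordered pair, with the sign taken from the coexpression edge; a pair
overlapping both signs is counted once, as positive. GraphML (via igraph)
and TSV exports round-trip nodes, typed edges and attributes exactly; SIF
carries edges only.

### qPCR quantification

ΔCq = Cq(target) − Cq(reference gene) per sample, and relative expression
between paired tissues is $2^{-\Delta\Delta C_q}$ with
ΔΔCq = ΔCq(tumor) − ΔCq(normal). The package follows the standard Cq
semantics throughout: **lower ΔCq means higher expression** (fewer cycles
to threshold when more template is present), so a positive ΔΔCq means the
gene is *down* in tumor. Published figure legends occasionally state the
opposite convention; users comparing against such sources should check the
orientation before interpreting signs. Technical replicates are expected to
be averaged per sample before analysis. Two-category association rows use
the classic equal-variance two-sample t-test (the historical SPSS default;
`welch = TRUE` switches), making the two-category ANOVA identity F = t²
hold exactly — the tests verify agreement to 1e-10. Categories with fewer
than 2 patients are excluded with a warning. The returned table keeps
p-values at full precision; rounding to 3 decimals is a presentation
concern handled when writing the TSV.

## The synthetic-data generator

`simulate_expression()` emulates a metabolism-pathway lncRNA array: 965
lncRNA and 458 protein-coding probes on 3 tumor/normal pairs by default.
Expression is simulated directly on the log2 scale with Gaussian residuals
(`noise_sd`, default 0.5 log2 units) around per-gene baselines drawn
uniformly from 6–12; the pipeline consumes log2 intensities, so
intensity-scale realism (scanner saturation, background, dye effects) is
deliberately not modeled. Planted structure:

* **Differential genes** — a `de_fraction` (default 10%) of genes, split
  evenly up/down, receive a ±`log2_effect` (default 2) shift in tumor
  columns before noise, so the expected tumor-minus-normal difference
  equals the planted effect exactly.
* **Coexpression modules** — each module shares a per-sample latent factor.
  With target correlation ρ, the loading is √ρ and the residual sd
  √(1−ρ) on the total-variance scale (both multiplied by `noise_sd`), so
  the expected pairwise within-module correlation equals ρ analytically.
  Each module is lncRNA-centered: its first member is a dedicated lncRNA
  hub when one is available, mirroring the ceRNA neighborhoods such arrays
  are designed around, and guaranteeing the annotation stage has a hub to
  annotate. Differential genes are drawn disjointly from module genes by
  default so ground-truth contingencies stay unambiguous
  (`de_module_overlap = TRUE` lifts this).
* **GO structure** — the first `n_modules` of `n_go_terms` terms are module
  signature terms annotating ≥80% of one module's members; the rest
  annotate each gene independently at `go_background_rate` (default 0.05).
* **miRNA regulation** — `mirna_count` planted (miRNA, target) pairs whose
  miRNA direction opposes the target's, plus an equal number of
  same-direction decoys flagged in the truth, so the direction filter's
  sensitivity and specificity are both checkable.
* **Cohort reuse** — passing a previous run's `truth` into
  `simulate_expression()` re-measures the same planted biology with fresh
  noise, which is how the multi-dataset consensus analyses build their
  replicate cohorts.

`simulate_cq()` generates per-patient Cq values for a target and a
reference gene in both tissues, with a planted tumor ΔCq shift and optional
covariate effects added to the later category of a clinicopathological
column (age, sex, invasion, metastasis, differentiation). The reference
gene carries no group effect. Amplification-efficiency artifacts and
realistic Cq curves are out of scope.

What passing tests on this generator do **not** show: robustness to probe
level artifacts, heavy-tailed intensity distributions, batch effects,
unbalanced designs, or annotation incompleteness in real GO. The generator
validates the statistical machinery, not array physics.

## Numerical choices and degenerate inputs

* Correlations are clipped to [−1, 1] against floating-point rounding;
  constant vectors raise errors rather than returning NaN.
* Rows with zero variance *and* zero mean difference get p = 1 with a
  warning in `differential_test()`; zero variance with a nonzero
  difference gives p = 0 (infinite t).
* `bh_adjust()` validates inputs and delegates to
  `stats::p.adjust(method = "BH")`; the test suite holds it equal to an
  independent O(m²) step-up implementation.
* Gene symbols are upper-cased at every file boundary so joins across
  sources are case-insensitive.
* All tabular outputs are sorted deterministically (by gene pair, then
  type) so reruns diff cleanly; `stats::hclust` with average linkage on
  1 − Pearson r resolves merge ties by original index, giving
  deterministic leaf orders.

## Default thresholds

| Parameter | Default | Where used |
|---|---|---|
| `fc_threshold` | 1.5 | volcano selection (strict >) |
| `alpha_de` | 0.05 | volcano selection |
| `alpha_edge` | 0.05 | FDR-adjusted edge selection |
| `alpha_enrich` | 0.05 | adjusted enrichment assignment |
| `min_neighbors` | 3 | hub rule (strictly more than) |
| `min_support` | 50 | multi-dataset consensus |
| `min_present` | 3 | presence filter |

`default_config()` carries exactly these values and serializes them to
YAML for reproducible runs; `run_pipeline()` executes the stages in order
and writes a JSON manifest with input checksums and per-stage counts.

## Problem sizes used in the tests

The packaged tests run the calibration checks at 10,000 replicates
(Fisher-z null, paired-t null), the planted-recovery check on a 100-pair
cohort (1,423 genes), the guilt-by-association recovery on 100 replicate
50-gene cohorts of 15 pairs each, and the exhaustive hypergeometric oracle
up to N = 12. These sizes give Monte-Carlo error well inside the asserted
bands while keeping a full test run under a minute on one core.

## Known limitations

* The coexpression scope question (all array genes vs differential genes
  only) is left to the `genes` argument of `build_network()`; at 6 samples
  an FDR-controlled network over all pairs is extremely sparse, which is a
  property of the design, not the implementation.
* Welch's test at 3 vs 3 is conservative (see above); the paired test is
  preferred for paired designs.
* No GO-graph propagation: terms are tested as given in the GMT. Ancestor
  inflation, semantic reduction, and KEGG-specific handling are out of
  scope (a KEGG-formatted GMT works unchanged).
* The pipeline is symbol-keyed; genomic coordinates and strand are never
  consulted.
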