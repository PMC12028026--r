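---
title: "Methods: gene-set-based comorbidity scoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gene-set-based comorbidity scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gscomod)
```

## The model

`gscomod` rests on one assumption: if two diseases arise from the same
biological processes, then their gene lists — even when disjoint — should
be over-represented in the *same* functional gene sets, and the two
vectors of over-representation p-values should co-vary.

For a disease gene list $L$ and a collection of $n$ functional gene sets
$S_1,\dots,S_n$ over a universe $U$, the *semantic profiling vector* is
$(p_1,\dots,p_n)$ where $p_i$ is the one-sided Fisher exact
(hypergeometric upper-tail) p-value

$$p_i = P(X \ge k_i), \qquad X \sim \mathrm{Hypergeom}(|U|,\,|S_i|,\,|L|),
\qquad k_i = |L \cap S_i|.$$

The comorbidity score of a pair $(A, B)$ is the Pearson correlation of
the two transformed profiles:

$$\mathrm{GS.sim}(A,B) =
\frac{\sum_i (P_{A,i}-\bar P_A)(P_{B,i}-\bar P_B)}
     {\sqrt{\sum_i (P_{A,i}-\bar P_A)^2}\,\sqrt{\sum_i (P_{B,i}-\bar P_B)^2}}.$$

### Why one-sided

The question is over-representation only. A two-sided test would also
reward significant *depletion* of a gene set, which carries no evidence
of shared biology; a list with zero overlap with a set therefore gets
$p = 1$, never a small p-value.

### The transform

The score correlates *transformed* p-values, and three conventions are
implemented: elementwise $\exp(p)$ (the default), the identity, and
$-\log_{10} p$. The conventions are not interchangeable in value —
$\exp(p)$ compresses p-values into $[1, e]$ and weights the profile
bulk, while $-\log_{10}p$ stretches the significant tail — but all three
are strictly monotone, so the rank order of any single profile is
transform-invariant. Rather than silently committing to one convention,
every output records its transform tag, and `transform` is an explicit
argument throughout. For inputs whose p-values span hundreds of orders of
magnitude (deep profiles against large collections), `neglog10` is the
numerically sensible scale and is the default for the core-subset CLI.

### Numerical conventions

* P-values are computed in log space (`phyper(..., log.p = TRUE)`) and
  floored at $10^{-320}$, so no profile entry is ever exactly zero.
* No multiple-testing correction is applied inside profiles: the score
  consumes raw p-values. Bonferroni correction appears only where a
  family-wise decision is made — gold-standard gating and core-set
  significance labels — as $\alpha/m$ over the $m$ tests actually
  performed.
* If a transformed profile is constant (zero variance), the correlation
  is undefined; the score is then *defined* as 0 and flagged
  `zero_variance`. A constant profile carries no similarity evidence,
  and a pipeline ranking thousands of pairs needs a number, not an NA.
* Gene identity is case-insensitive; every symbol is uppercased at
  ingest, since symbol-case mismatches between resources are the dominant
  matching failure in practice.
* The default ORA universe is the union of the collection's member genes;
  an explicit universe (e.g. all HGNC genes) can be supplied. Disease
  genes outside the universe cannot enter a Fisher table and are dropped
  with a warning.

## Benchmark measures

The Jaccard index $|A\cap B|/|A\cup B|$ and overlap coefficient
$|A\cap B|/\min(|A|,|B|)$ are the overlap-based baselines; both are zero
exactly when the gene lists are disjoint.

The network separation score on a protein–protein interaction graph is

$$S_{AB} = d_{AB} - \frac{d_{AA} + d_{BB}}{2}$$

with these conventions (the literature states the formula more tersely
than it states the conventions, so they are spelled out here and recorded
in the result object):

* $d_{AB}$ is the mean, over every mapped gene of both sets, of the
  shortest-path hop distance to the *nearest* mapped gene of the other
  set; a gene belonging to both diseases contributes distance 0.
* $d_{AA}$ (and $d_{BB}$) is the mean distance from each gene to its
  nearest *other* gene of the same set; a singleton set has
  within-distance 0 by convention.
* Genes absent from the network, or with no finite distance to any
  counterpart (different connected components), are dropped from the
  relevant mean and counted in `n_dropped_*`, rather than contributing
  infinity. This keeps the score finite on fragmented networks and
  matches the common practice of working on the interactome's giant
  component.

Negative $S_{AB}$ means the two disease modules overlap topologically.

## Core gene sets by mixture regression

For a comorbid pair, some functional sets' paired p-values track each
other closely while the rest do not. To separate them, the paired
transformed profiles $(x_i, y_i)$ are modelled as a two-component mixture
of Gaussian linear regressions
$y \sim N(\beta_{0k} + \beta_{1k} x,\ \sigma_k^2)$, $k \in \{1,2\}$,
fit by EM:

* **E-step** — posterior responsibilities from the component densities
  weighted by the mixing proportions (log-space softmax).
* **M-step** — responsibility-weighted least squares per component,
  weighted residual variance, mixing weights = mean responsibility.
* **Initialisation** — responsibilities drawn uniformly per observation
  (symmetric Dirichlet), seeded; 5 restarts, best log-likelihood kept.
  EM on mixture regressions is multimodal and restarts are cheap.
* **Convergence** — $|\Delta \log L| < 10^{-6}$ or 500 iterations; the
  log-likelihood trace is stored and is non-decreasing within a run.
* **Variance floor** — $\sigma_k^2 \ge 10^{-10}$ prevents a component
  collapsing onto a few exactly-fitted points.
* **Degeneracy** — if a single line already fits all points to machine
  precision, a second component has nothing to explain; the fit falls
  back to one component holding everything, flagged
  `degenerate_single_line`.

The *core* is the hard-assigned component with the larger within-component
GS.sim; by construction its similarity is at least the complement's. Two
edge rules: a component with fewer than 3 members cannot anchor a
correlation, so the other component is declared core (flagged); under the
single-line fallback everything is core and the complement's score is
reported as missing. Each core member is labelled significant when either
disease's raw p-value passes $\alpha/n$.

Orientation matters: regressing $y$ on $x$ is not the same model as $x$
on $y$, and swap-invariance is not guaranteed. The convention here is
disease A on the x-axis, recorded in the CLI metadata; fits are invariant
to observation order up to component relabelling.

## The simulation study

The validity check for the score is constructive: genes of a *single*
disease split into two pseudo-diseases must look comorbid, and random
genes split the same way must not.

* Split ratios default to $\{0.30, 0.35, 0.40, 0.45, 0.50\}$ — five
  ratios from a 3:7 split to an equal split; the end points are the
  canonical cases, the intermediate values are this package's choice and
  are configurable.
* Each real replicate partitions the disease's genes uniformly at random
  at the given ratio and scores the two parts with GS.sim; the matched
  null replicate samples the same total number of genes from the universe
  and splits identically.
* Real and null replicates are paired by index within ratio (they are
  generated in matched pairs from one seeded stream), and a two-sided
  paired t-test over all matched replicates summarises the separation.
* Small gene sets get no special casing: degenerate profile flags
  propagate into the replicate table.

## The evaluation framework

The gold standard for "actually comorbid" comes from a cohort diagnosis
matrix: for each disease pair the 2×2 table of the binary indicators
gives the relative risk $RR = P(B\mid A{=}1)/P(B\mid A{=}0)$ with the
Wald confidence interval
$\exp(\ln RR \pm 1.96\sqrt{1/n_{11} - 1/n_{1\cdot} + 1/n_{01} - 1/n_{0\cdot}})$
and a Pearson chi-square p-value without continuity correction. A zero
outcome count in either arm triggers a 0.5 continuity correction on all
cells, flagged. A pair is labelled comorbid at threshold
$t \in \{1, 5, 10\}$ iff its p-value passes the Bonferroni threshold
$\alpha/M$ over the $M$ tested pairs (non-strict $\le$; the boundary is
measure-zero) *and* $RR > t$.

Measures are compared by rank-based AUC (Mann–Whitney with half-credit
ties — an all-equal score vector scores exactly 0.5), and by logistic
regression combining several measures: unregularised maximum-likelihood
fits per requested measure subset, scored by *in-sample* AUC of the
fitted probabilities, best subset by AUC. In-sample evaluation is the
default deliberately — the model search is part of the measured pipeline
— and a single-measure logistic model reproduces that measure's raw AUC
exactly, since the logistic transform is monotone. Perfect separation is
detected by a vanishing residual deviance and flagged, with the AUC still
reported from the separating direction.

## The synthetic generator

The generator emulates the *statistical shape* of curated disease-gene
resources and claims-database diagnosis data:

* a gene universe (default 2000 genes) with a collection of functional
  sets (default 50 sets of 20–60 genes, sampled without replacement);
* diseases built from a handful of driver sets (default 5) plus a
  background fraction (default 10%) of off-pathway genes; disease sizes
  default to 30–300 genes, the spread seen in curated disease gene lists;
* three pair designs: shared drivers with overlapping genes, shared
  drivers with *strictly disjoint* gene lists (the
  comorbid-without-overlap scenario), and independent drivers;
* cohorts with planted relative risk: disease A is Bernoulli at
  prevalence $p_A$; disease B uses
  $P(B\mid A{=}1) = rq$, $P(B\mid A{=}0) = q$ with
  $q = p_B / (p_A r + 1 - p_A)$, which plants $RR = r$ while preserving
  B's marginal prevalence — so the Bonferroni/RR gates face realistic
  base rates regardless of the planted effect. Requested combinations
  with $rq > 1$ are rejected as infeasible.

The benchmark used for evaluation generates 60 gene-disjoint pairs, 20
comorbid (shared drivers) and 40 independent, with disjointness enforced
on the negatives as well; overlap measures are identically zero on every
pair, so their AUC is exactly 0.5 while the profile score still separates
the classes. Benchmark diseases use 30–50 genes so that two disjoint
samples always fit inside a five-driver gene pool.

What the generator does *not* emulate: GO's DAG structure and gene-set
nesting, per-gene annotation bias, literature-driven correlation between
disease-gene counts and study intensity, and longitudinal structure in
diagnoses. Passing tests on these fixtures therefore demonstrate the
machinery's correctness and the score's qualitative behaviour
(direction, blindness of overlap measures, planted-RR recovery), not
real-data effect sizes.

## Problem sizes and reproducibility

The test suite and acceptance script run everything at desk scale, chosen
to make the checked properties decisive yet quick: simulations at 20
replicates per ratio over 5 ratios; mixture-regression recovery on 200
points over 20 seeds; RR coverage on 50,000-sample cohorts over 20
seeds; oracle equivalences on 500 random Fisher tables and 200 random
graphs. Every stochastic path is driven by an explicit integer seed and
is bit-reproducible; the CLI refuses to fall back to wall-clock seeding.

## Known limitations

* GS.sim treats the $n$ functional sets as exchangeable coordinates;
  overlapping or nested gene sets induce correlation between profile
  entries that the Pearson correlation does not model.
* The score depends on the universe choice, as every ORA does; comparing
  scores across collections with different universes is not meaningful.
* The mixture regression fixes two components; data generated by one or
  three regimes will still be forced into two (the degenerate fallback
  covers only the exactly-collinear case).
* The Wald CI for RR is asymptotic and the planted-RR coverage checks
  operate at large cohort sizes; small-cell tables rely on the flagged
  continuity correction.
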