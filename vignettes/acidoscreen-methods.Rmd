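---
title: "Methods and design of the acidoscreen pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of the acidoscreen pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(acidoscreen)
```

`acidoscreen` implements the analysis stages of a drug-repurposing study on
acidosis-adapted cancer cells: plate-screen normalization and QC, hit
calling, dose–response confirmation, Gene Ontology over-representation of a
differential-expression (DE) table, community detection on the ontology
graph, and expression summaries. This vignette records the models, the
parameter choices and their rationale, the numerical details, and what the
synthetic benchmark does and does not establish.

## Screen normalization and quality control

A viability screen reads one assay intensity per well. Each plate carries
its own vehicle (negative) and cytotoxic-QC (positive) control wells —
quadruplicates of each in the emulated design — and every compound well is
normalized against *its own plate's* control means:

$$\mathrm{PI} = 100\,\frac{\mu_{neg} - s}{\mu_{neg} - \mu_{pos}}.$$

Per-plate anchoring absorbs plate-to-plate drift in cell seeding and signal
gain; it assumes the controls on a plate are exchangeable with the compound
wells (no spatial/edge modeling is attempted — a deliberate non-goal).
Percent inhibition is **not clamped**: a compound more cytotoxic than the QC
scores above 100%, and confirmed screen hits do (110–117% in the bundled
published table). Plate quality is the screening-window coefficient

$$Z' = 1 - \frac{3(\sigma_{pos} + \sigma_{neg})}{|\mu_{pos} - \mu_{neg}|},$$

the standard definition; the source analysis names the statistic without
defining it, and no other convention is in common use for plate QC. $Z'\le 1$
always; values near 0.5–1 indicate a window adequate for single-replicate
screening, and negative values (overlapping controls) are returned rather
than raised so that failing plates remain visible in the output.

Hits are compounds with PI **strictly** above the threshold (default 70%).
The boundary behavior is not specified by the screen's description; strict
inequality is declared here and tested. One published confirmed hit
(Thimerosal, 66%) sits below that threshold; the bundled table reproduces
the published values verbatim, and the discrepancy — presumably a
confirmation-round value — is left as printed rather than reconciled.

## Dose–response confirmation

Confirmation assays titrate each hit over 0–15 µM. Viability follows the
four-parameter logistic

$$v(d) = \mathrm{bottom} + \frac{\mathrm{top} - \mathrm{bottom}}
{1 + (d/\mathrm{IC50})^{h}},$$

fit by unweighted least squares on the viability scale
(`minpack.lm::nlsLM`). Because the 4PL surface is multimodal in
(IC50, $h$), fitting is multi-start: a 5-point geometric IC50 grid spanning
the positive tested doses crossed with Hill slopes $\{1, 2, -1, -2\}$, best
residual sum of squares wins. The fitted curve is reported in the canonical
orientation (top ≥ bottom, flipping the Hill sign if needed), `converged`
comes from the optimizer status, and an IC50 outside the positive tested
dose range raises an extrapolation warning — such values (they occur when
the top dose barely reaches half-effect) are order-of-magnitude estimates
at best. All-equal viabilities are a hard error: no finite IC50 exists.

Selectivity across cell lines is summarized as pairwise IC50 ratios over
converged fits; a compound is flagged *preferential for acid-adapted cells*
when IC50(adapted) < IC50(parental) and both fall below IC50(normal). At
the potency contrast reported for the lead compound (3.4, 1.72 and
~10 µM), the adapted/parental ratio is ≈ 0.51.

## Gene universe, DE filtering and classic-Fisher enrichment

The enrichment universe is the set of *quantified* genes: CPM > 1 in at
least 3 samples, with CPM$(g,s) = 10^6\,c_{gs}/\sum_g c_{gs}$. The study
set is the significantly altered genes, `padj < 0.05` (strict; adjusted
p-values, the standard DE-pipeline output), intersected with the universe.
The fold-change summary uses `|log2fc| > 1`, i.e. a two-sided fold change
of 2 — the source convention does not say whether down-regulated genes were
filtered on the linear or log scale, and the symmetric log-scale reading is
implemented rather than guessed as one-sided.

Annotations are closed over ancestors before testing (true-path rule): a
gene annotated to a term is annotated to all its ancestors. Each term is
then tested by the classic one-sided Fisher exact test — the unconditioned
per-term test, with no parent–child decorrelation, which is exactly what
the "classic" algorithm of the standard topology-based GO tools computes —
equivalently the hypergeometric upper tail $P(X \ge k)$ for $k$ study genes
annotated among $K$ universe genes annotated, study size $n$, universe size
$N$. Three procedural rules mirror the source analysis:

* terms with fewer than 5 annotated genes are excluded **before** testing;
  the count is taken within the universe after propagation (the source does
  not say which set; universe counting is declared and tested);
* the top 1000 terms by ascending p are retained (ties broken by term id
  for determinism);
* term significance is raw p < 0.05 with **no** multiple-testing
  correction, matching the reported convention — the term list is a
  screening summary, not a calibrated discovery set.

## Community detection and graph collapse

The graph stage works on the subgraph induced by the significant terms plus
all their ancestors, edges directed child → parent. Communities minimize
the spin-glass Potts Hamiltonian

$$H(\sigma) = -\sum_{i<j}\left[A_{ij} - \gamma\,\frac{k_i k_j}{2m}\right]
\delta(\sigma_i, \sigma_j)$$

on the undirected simple view, with $\gamma = 1$ (the configuration-model
null; minimizing H is then equivalent to maximizing Newman modularity) and
at most 200 spin states — the cap used in the source analysis.
Optimization is simulated annealing over single-node label moves
(geometric schedule, defaults $t: 1 \to 0.01$, cooling 0.99, one sweep =
$|V|$ proposals), five seeded restarts plus one deterministic greedy run,
followed by a zero-temperature best-move polish; the best Hamiltonian
wins. On every ≤ 9-node suite graph this reaches the exhaustive minimum
over all set partitions. Disconnected inputs are partitioned per
weakly-connected component with disjoint label ranges (the classical
spin-glass implementation rejects disconnected graphs; silence in the
source is resolved by per-component operation), and an edgeless graph
degenerates to singleton communities with a warning.

Each community is represented by its member with the largest HITS
authority score — the dominant eigenvector of $A^\top A$, computed by power
iteration with L2 normalization to an L1 tolerance of $10^{-10}$. With
child → parent edges, authority accumulates at general (ancestral) terms,
matching the "highest in-degree" reading; edge direction is a declared
choice, as the source never states it. Exact score ties are broken
uniformly at random; the tie-break RNG stream is derived from (seed,
community label), so adding or removing one community never perturbs the
choices of the others. Score equality is taken at a relative tolerance of
$10^{-12}$: symmetric positions produce bitwise-equal scores through
identical arithmetic, and the tolerance only guards against non-associative
summation order.

Collapse proceeds in two stages: (1) contract each community into its
representative, inheriting inter-community edges with direction,
deduplicated, self-loops removed; (2) re-attach every significant term as a
leaf with a single membership edge to its community node. Member counts on
community nodes sum to the input node count. The published figure legend
suggests an alternative inter-community edge rule — an edge when the
representatives are each other's ancestors — which conflicts with the
textual "merge and simplify" description; both are implemented
(`edge_mode = "contracted"` default, `"rep-ancestry"` optional) and neither
is asserted as the original intent. The collapsed graph exports to GraphML
and DOT with `kind`, representative, member-count and color-index
attributes.

## Expression summaries

The variance-stabilizing transform is $\log_2(\mathrm{CPM} + 1)$. The
original analysis used a regularized-log transform from a dedicated
DE-modeling package; the downstream operations (row scaling, PCA, community
grouping) are transform-agnostic, so this pipeline uses the simpler
monotone, library-size-invariant log-CPM and makes no claim of numeric
equivalence to figures produced with the shrinkage transform.

Row scaling is either to the unit interval (as in the community heatmap) or
to z-scores (as before PCA); constant rows map to zeros and are flagged
rather than producing NaNs. PCA uses the top 500 genes by variance,
centered and scaled per gene, via SVD; component signs are fixed by making
the largest-magnitude loading positive, so results are deterministic and
invariant to gene order. Community expression profiles take each
community's member genes as the union of genes annotated to any member
term — multi-community genes appear once per community, a declared rule
where the source states none — grouped by community and ordered within by
hierarchical clustering (Euclidean distance, average linkage, the defaults
of the classic heatmap tooling).

## The synthetic benchmark: what it emulates, and what it does not

The generator plants ground truth in every input class, with defaults
chosen once to match the emulated study's stated conditions:

* **Plates**: 96 wells, one compound per well, 4 + 4 control wells per
  plate (88 compound wells/plate); the exact control layout within a plate
  was never published and is exposed as configuration. The positive-control
  effect is 0.8 (the QC compound left ~20% viability). Well noise is
  multiplicative log-normal — plate-reader noise is scale-proportional and
  positivity is preserved — with CV 0.09, set a priori so the realized
  plate Z′ averages ≈ 0.6 under quadruplicate controls
  ($1 - 3\,\mathrm{cv}\,(1 + 0.2)/0.8 \approx 0.6$), the assay quality
  reported for the screen. The planted hit fraction is 55/1280 (the
  screen's primary hit rate); hits draw inhibition uniformly from 85–120%,
  non-hits from 0–40%.
* **Dose–response**: 4PL curves over 0–15 µM in duplicate wells with
  Gaussian viability noise (SD 3 viability points), at planted potencies —
  the demo uses 3.4/1.72/10 µM for parental, adapted and normal lines.
* **Ontology/annotations/DE**: a random rooted DAG in levels (every
  non-root term has a parent on the level above, up to one extra parent
  shallower); genes annotated directly to 1–3 non-root terms; planted
  terms topped up to ≥ 30 genes and their genes oversampled into the DE
  set at odds 20; adjusted p-values constructed so exactly the planted DE
  genes (10% of genes) pass α.
* **Counts**: negative-binomial, log-normal baseline means, dispersion
  0.05 (a typical bulk RNA-seq scale), fold changes planted in condition 2,
  triplicate libraries as in the emulated design.

What passing on this benchmark shows: the normalization algebra is exact,
hit calling separates the planted effect sizes at the screen's noise level,
the Fisher machinery is numerically identical to the hypergeometric tail,
the annealer reaches provable optima at small scale, and the pipeline is
deterministic end to end. What it does not show: robustness to spatial
plate artifacts, batch effects, annotation bias, correlated genes,
dispersion–mean trends, or any property of the real ontology's topology —
none of which the generator emulates. Conclusions about real screens
require real controls.

## Reproducibility and problem sizes

All stochastic functions take an explicit seed and restore the caller's
RNG state; a single pipeline seed fans out into named per-stage streams, so
stages can be rerun in isolation. Re-running the demo with one seed is
byte-identical across runs, manifest included (the manifest deliberately
records no timestamps).

The bundled demo runs at a deliberately small scale — 300 compounds over
four plates, a 200-term ontology with 5 planted terms, 2000 genes in
2 × 3 samples — chosen so the full pipeline, including annealing restarts,
completes in seconds while still exercising every code path at realistic
shapes. The published counterpart of this analysis operated at 1280
compounds and genome scale; nothing in the implementation is specific to
the demo scale.

## Known limitations

* The spin-glass annealer is exact only in expectation; on large graphs it
  returns a good local minimum, not a certificate. Restarts and the greedy
  polish mitigate but do not eliminate this.
* HITS authority is meaningful within a weakly connected component; nodes
  with no in-edges legitimately score 0, and a component whose dominant
  eigenpair of $A^\top A$ is (near-)degenerate has no uniquely defined
  score vector.
* The log-CPM transform under-stabilizes low-count genes relative to
  shrinkage transforms; PCA on few samples should be read accordingly.
* Enrichment p-values are unadjusted by design (matching the emulated
  procedure) and should be treated as a ranking, not as calibrated error
  control.
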