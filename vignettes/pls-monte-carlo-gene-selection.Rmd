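---
title: "PLS and Monte Carlo gene selection: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{PLS and Monte Carlo gene selection: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plsmc)
```

## The problem and the model

Expression studies of a *continuous* disease index face a `p >> n` regression
problem: tens of thousands of genes, a couple of hundred samples, and a
response measured on an ordinal-continuous severity scale. Per-gene
variance or regression screens treat genes independently and cannot absorb
shared nuisance structure (array batch factors, demographic gradients)
that inflates marginal associations. `plsmc` instead models all genes
jointly with PLS1 regression and selects genes by combining three
statistics computed from that joint model: VIP with a permutation-null FDR,
Monte Carlo coefficient reliability, and an RMSECV-optimised reliability
cutoff.

PLS1 assumes an (approximately) linear association between expression and
the phenotype, concentrated in a small number of latent directions. For a
scalar response the NIPALS inner loop converges after a single pass, so
`pls1()` implements the direct recursion (weights from the covariance
`X'y`, scores, loadings, deflation) — mathematically identical to iterated
NIPALS for a univariate response, and deterministic. The response is
deflated during fitting, which for PLS1 is provably a no-op; the
`deflate_y` switch exists so the test suite can verify that identity rather
than assume it.

Two model-level error policies are deliberate: a constant response is an
error (every downstream statistic would be undefined), and an exhausted
deflation (requesting more components than the data's effective rank) is an
error in a direct fit but is tolerated inside cross-validation, where
larger counts simply reuse the largest achievable model and the RMSECV
curve flattens. That keeps the component scan well-defined on exactly
low-rank data instead of failing on the cleanest possible input.

## Preprocessing scope

The package assumes probe-level, background-corrected log2 intensities. Of
the classical three-step summarisation it implements the two reproducible
matrix-level steps — quantile normalization across samples (delegated to
`limma::normalizeQuantiles`, ties averaged over the reference values at the
tied ranks) and Tukey median polish (`stats::medpolish`, rows swept first,
`tol = 0.01`, `max_iter = 10` — conventional settings; the decomposition
identity `overall + row + col + residual = input` holds exactly at any
iteration count). Model-based background correction of raw array
intensities is out of scope because it needs probe-level CEL data this
package never sees; deposited matrices are frequently already normalized,
so both steps are optional in `preprocess_expression()` and in the
pipeline. Zero-variance genes are removed before fitting because
unit-variance autoscaling is undefined for them; missing values are a
load-time error rather than an imputation problem.

## Parameters that matter

| parameter | default | meaning and rationale |
|---|---|---|
| `folds` | 4 | RMSECV folds for both the component and the cutoff scan. |
| `a_max` | 10 | largest latent-component count scanned; capped automatically so every fold and half-sample refit stays feasible. |
| `rel_tol` | 0.01 | elbow rule: smallest `A` whose relative RMSECV improvement to `A+1` falls below 1% (capped at the curve argmin; `rel_tol = 0` is exactly the argmin). Operationalises "the descending trend loses strength". |
| `n_perm` | 1000 | response permutations for the VIP null. |
| `alpha` | 0.05 | FDR threshold defining candidates. |
| `n_subsets` | 100 | Monte Carlo subsets for the reliability. |
| `fraction` | 0.5 | subset size as a fraction of samples (half-sampling, without replacement). |
| `grid_size` | 100 | quantile grid over candidate \|reliability\| values for the cutoff scan (plus the exact value 0). |
| `hub_threshold` | 10 | a network hub has degree strictly greater than this. |
| `scale` | TRUE | autoscale predictor columns; VIP is conventionally defined on autoscaled predictors. Switchable, and the package's invariants hold either way. |

The phenotype is used in its native units (an index; the reference
simulation uses a 0–100 range); RMSECV is therefore in phenotype units.

## Reconstructed statistics: the open design choices

Three pieces of the procedure are specified only loosely in the literature
this package operationalises; each is implemented as the standard reading
and documented here as a reconstruction.

**FDR estimator.** "FDR from the empirical VIP distribution" is implemented
as the pooled permutation tail-ratio familiar from SAM-style procedures:
`FDR(v) = min(1, V̂(v) / R(v))` with `R(v)` the observed count of VIPs at or
above `v` and `V̂(v)` the per-replicate average count in the pooled null,
followed by cumulative-min monotonisation from the largest VIP downward.
Monotonisation guarantees the top-ranked gene carries the smallest FDR and
that thresholding at `alpha` selects a VIP-contiguous set. Permutation
refits reuse the observed component count (no per-replicate re-selection):
this keeps the null comparable and the cost linear in the number of
permutations.

**Reliability.** "Regression coefficient reliability" is implemented as the
signal-to-noise ratio `mean/sd` of a gene's coefficient across the Monte
Carlo subset refits (sample standard deviation, `n−1` denominator),
following the Monte Carlo variable-selection tradition of scoring both
magnitude and stability. Coefficients are compared on the original gene
scale. If the spread collapses below `1e-12` — e.g. a gene reproducing the
response exactly — the reliability is the documented sentinel
`sign(mean) · 1e12`, which passes any finite cutoff.

**Stage order.** VIP requires a fixed component count, so the candidate
screen cannot literally precede component selection. The default order
chooses `A*` first and computes VIP/FDR at `A*`; `order = "paper"` follows
the published narrative instead, computing VIP/FDR at `a_max` components
before `A*` is chosen for the reliability stages. Both orders are
deterministic and tested.

Other numerical choices: fold partitions are uniform random splits into
nearly equal blocks (no stratification — the response is continuous),
drawn against sample identifiers in sorted order, so cross-validation is
invariant to row reordering; Monte Carlo subsets are drawn without
replacement, independently per subset, from a per-stage seed derived from
the master seed; the cutoff comparison is strict (`|reliability| > cutoff`),
RMSECV ties in the cutoff scan break toward the larger cutoff (the sparser
model), the scan shares one fold partition across all cutoffs so models are
compared on identical splits, and a degenerate grid (all reliabilities
equal) returns the common value with a warning.

## Enrichment and network conventions

Enrichment is the exact hypergeometric upper tail (`stats::phyper`,
log-space, stable far beyond 1e5-gene backgrounds) over a *flat* gene→term
table — no ontology DAG, no ancestor propagation; if term ancestry matters,
propagate before loading. The background is the intersection of measured
and annotated genes, matching the convention of reporting the annotated
universe, and raw p-values are the primary output with Benjamini–Hochberg
adjustment appended for convenience.

The interaction network is the induced subgraph of the interaction list on
the selected genes: undirected (interaction records carry direction
inconsistently, and degree counts interactions symmetrically), duplicate
orientations collapsed, self-loops dropped, isolated selected genes kept as
degree-0 nodes. Hubs are nodes with degree strictly above the threshold.
Exports (SIF, GraphML with degree/hub/regulation attributes, TSV edge list)
use lexicographic node and edge order so repeated exports are
byte-identical; a `min_degree_display` filter reproduces figure-style
pruning without affecting the analysis.

## What the synthetic generator does and does not emulate

`simulate_dataset()` draws a uniform phenotype over a configurable range
(`"bimodal"` mode mixes a low and a high group, mimicking a cohort that
pools patients with controls), plants `n_informative` genes whose
standardised expression is linear in the standardised phenotype with
configurable effect size and sign mixing, optionally adds low-rank
array-specific nuisance factors loading on *all* genes, and adds i.i.d.
Gaussian noise around per-gene baselines on a log2-like scale. The
defaults — 120 samples, 1,000 genes, 30 informative genes of absolute
effect 1.5 against unit noise — define the package's reference study, a
deliberately reduced-scale analogue of a ~220-sample, ~22,000-probe array
cohort. `simulate_annotation()` plants one term that preferentially covers
the informative genes; `simulate_interactions()` provides a
preferential-attachment graph (scale-free-ish degrees) and an exact
fixed-degree construction (Havel–Hakimi) for planted-hub truths.

What it does **not** emulate: heavy-tailed and heteroscedastic residuals,
correlated co-expression modules among null genes, probe-level effects,
annotation bias toward well-studied genes, or literature-derived
interaction density among disease genes. Passing the planted-recovery and
null-calibration tests therefore demonstrates correctness and calibration
of the *procedure* under its own model assumptions, not performance on any
particular real cohort — on real data the FDR remains empirical-null based
and the reliability remains resampling based, but effect sizes and noise
are whatever the data provide.

## Problem sizes used by the test suite

Tests run the method at sizes chosen to exercise every code path while
keeping the default suite quick: oracle equivalence on 50 random problems
(10–30 samples, 5–50 genes); null calibration on 100 pure-noise studies of
40 samples × 200 genes with 200 permutations; planted recovery and
end-to-end determinism on the reference study (120 × 1,000) with 200
permutations and 50 Monte Carlo subsets. The full published-scale
configuration (≈220 samples, ≈22,000 probes, 1,000 permutations) runs with
the same code and defaults; it is simply larger.

## Known limitations

- PLS1 only: a single continuous response. No PLS2, kernel or sparse
  variants.
- Linearity: a strongly non-linear gene–phenotype relationship will be
  under-ranked by VIP.
- The FDR estimator and reliability formula are standard reconstructions
  (above); alternative estimators (e.g. per-gene rather than pooled nulls)
  would give different borderline calls.
- The annotation is flat and the network analysis is degree-only — by
  design, matching the scope of the procedure it implements.
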