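---
title: "Methods: estimating and comparing symptom networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: estimating and comparing symptom networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(SymptomNet)
```

## The estimation procedure and its assumptions

SymptomNet treats a battery of psychometric scores — here 17 items
spanning neurocognitive tests, affective severity scales and
psychosocial functioning domains — as the nodes of an undirected
weighted network. The procedure is deliberately simple and fully
explicit:

1. **Association.** Every item pair gets a Spearman rank correlation,
   with average ranks for ties. These instruments are integer-scored and
   tie heavily, so the tie convention matters; average ranks are the
   standard choice and are what the included rank-then-Pearson oracle in
   the test suite verifies against. The only distributional assumption
   is monotone association: Spearman is invariant under strictly
   monotone transforms of any item, so scale nonlinearity (e.g. floor
   effects in MMSE) does not distort edges, only genuine rank structure
   does.
2. **Significance thresholding.** An edge is kept iff its two-sided
   p-value falls below `alpha` (default 0.05), and its weight is the
   signed correlation; everything else is exactly 0. No regularization
   and, by default, no multiple-testing correction is applied: the
   target estimand is the plain thresholded zero-order correlation
   network. Holm or Benjamini–Hochberg adjustment is available via
   `thresholdNetwork(..., adjust =)` for users who want family-wise
   control, at the cost of changing the estimand.
3. **Centrality.** Degree, strength, the tuning-parameter blend
   `k^(1-α)·s^α`, Dijkstra shortest paths on lengths `(1/|w|)^α`,
   Freeman betweenness with fractional credit over tied shortest paths,
   and closeness as the reciprocal of summed distance to reachable
   nodes. All are computed on absolute weights (see "Signed edges"
   below) and reported raw and z-standardized across the nodes.
4. **Predictability.** Each node is regressed on its current network
   neighbours by OLS with intercept; the reported value is
   `R² = 1 − SSE/SST`, floored at 0. A node with no neighbours scores
   exactly 0.
5. **Comparison.** For cohort × timepoint arms sharing a battery, the
   pipeline reports descriptive deltas (per-node centrality and
   predictability changes, per-domain-block edge-count and mean-|w|
   changes). No inferential test of network differences is computed:
   the deltas describe, they do not test.

P-values use the t approximation
`t = ρ·√((n−2)/(1−ρ²))` on `n−2` degrees of freedom, which is adequate
for n ≳ 10. For very small arms (a 16-subject follow-up is realistic in
this setting) `spearmanMatrix(pMethod = "permutation")` provides a
seeded permutation p-value instead; it is not the default because the
t rule is the explicitly defined estimator of the pipeline.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `alpha` (edge threshold) | 0.05 | two-sided significance level per pair; edges kept at `p < alpha` |
| `centralityAlpha` (α) | 1 | Opsahl tuning parameter; 0 counts edges, 1 weighs them; affects blend and all path measures |
| `missing` | `complete_rows` | listwise deletion; `pairwise` uses complete cases per pair |
| `ridge` | `FALSE` | small-sample fallback for predictability (penalty `1e-3·trace(X'X)/p`); default errors instead, because no principled small-n rule exists |
| `layoutSeed`, `layoutIterations` | 42, 500 | deterministic layout reproducibility |

α = 1 makes the blended centrality coincide with strength and edge
lengths equal `1/|w|`; this is the most common convention and the one
adopted here as default, since nothing in the estimand pins α down —
any positive value is legitimate, and all functions expose it.

## Signed edges and design choices that were genuinely open

**Negative weights.** Path and strength computations use `|w|`: a strong
negative correlation binds two symptoms as tightly as a strong positive
one, and Dijkstra requires positive lengths. The sign is kept for
reporting (edge colour, the signed `expected_influence` column
`Σ_j w_ij` emitted next to strength).

**Closeness.** Defined as `1/Σ_j d(i,j)` over the nodes reachable from
`i`, with isolated nodes scored 0. On disconnected networks this makes
closeness comparable only within components; `harmonic = TRUE` switches
to harmonic closeness, which handles disconnection gracefully, but the
reciprocal-sum form is the default because it is the classical measure
the centrality profile is built on.

**Betweenness summation.** The ratio `g_jk(i)/g_jk` is summed over
unordered pairs `{j,k}` with `j ≠ i ≠ k`, endpoints excluded, using the
counting identity `g_jk(i) = g_ji·g_ik` when `d(j,i)+d(i,k)` ties
`d(j,k)`.

**Predictability definition.** "How well the neighbours predict a node"
is implemented as in-sample explained variance (R² of the neighbour
regression), the standard nodewise-predictability notion for continuous
variables; the RMSE is emitted alongside. In-sample rather than
cross-validated, because the measure describes the fitted network, not
out-of-sample generalization; R² values at small n are accordingly
optimistic, which is a known property, not a bug.

## Numerical choices

- **Tied path lengths.** Two path lengths tie when they agree within a
  relative tolerance of 1e−9, so floating-point sums that are
  mathematically equal share fractional betweenness credit instead of
  being split arbitrarily by rounding order.
- **PSD repair.** Block-filled target correlation matrices need not be
  positive semidefinite; they are projected by eigenvalue clipping at 0,
  reconstruction, and rescaling to unit diagonal. The result is
  guaranteed PSD to within 1e−10 and is the matrix actually sampled
  from — meaning extreme specs are repaired toward feasibility rather
  than rejected.
- **Degenerate inputs.** A constant column (possible after clamping at a
  scale bound) has no defined rank correlation; it contributes
  `rho = 0, p = 1`, i.e. no edge. An all-`p = 1` estimate yields the
  empty network; centrality standardization of a zero-variance column
  returns 0 rather than NaN; `SST = 0` (constant regression target)
  yields predictability 0.
- **Layout.** FR constant `k = √(1/N)`; repulsion truncated beyond 3k;
  temperature cooling linearly from 0.1 to 0 over the iterations;
  coordinates centred on the centroid so a single node sits at the
  origin. The layout is seed-deterministic and otherwise arbitrary up to
  rotation; no attempt is made to reproduce any specific published
  figure's coordinates.

## What the cohort generator emulates — and what it does not

`sampleCohort()` draws a latent multivariate normal with a
block-structured target correlation (one value per domain, one per
domain pair, optional item-level bridge overrides), then maps each
column to its item's mean and SD, rounds to integers and clamps to the
published score range — a Gaussian copula with integer margins. The
defaults encode the study conditions the package is designed around:
87 MDD-like and 56 BD-like subjects at baseline, 16 and 29 retained at
twelve weeks (retention 45/143 overall), within-domain latent
correlation 0.6, between-domain 0.1, and latent attenuation 0.4 at the
second timepoint. Item means and SDs are mid-range plausible values for
a moderately-to-severely depressed clinical sample (e.g. MoCA 20 ± 4,
BDI-II 28 ± 9); they were fixed once, on clinical plausibility, and are
fixtures, not estimates of any real cohort.

The generator reproduces the features the analysis is sensitive to:
bounded integer scores with heavy ties, block-wise Spearman structure,
domain bridges, paired designs with subject retention, and mean shifts
under treatment. It does **not** emulate ordinal category thresholds
(IRT-style item response), floor/ceiling pile-ups beyond what clamping
induces, missing data mechanisms, outliers, or any treatment mechanism
beyond "attenuate correlations, shift means". Clamping at extreme means
mildly attenuates realized correlations relative to the latent targets;
this is documented rather than corrected. Consequently, passing tests on
synthetic cohorts demonstrate that the estimator recovers the structure
this generator plants at these sample sizes — they are evidence about
the pipeline's correctness and sensitivity, not about any real
population.

The two presets (`presetCohortConfig("MDD")`, `"BD"`) differ only in
their bridge structure — the MDD-like preset couples affective and
psychosocial blocks with no direct affective–neurocognitive bridges; the
BD-like preset hyperconnects the psychosocial block and routes
neurocognitive bridges through MCA — and serve as illustrative,
qualitatively distinct fixtures.

One property worth knowing when interpreting simulated bridge counts:
under a block-factor structure the sample correlations of a null
between-domain block co-move through the sampled factor correlation, so
spurious between-domain edges arrive in bursts rather than
independently. Replicate-level assertions about "exactly zero"
between-domain edges are therefore unstable by nature; aggregate
contrasts (medians and means across seeds) are the meaningful check, and
that is what the test suite asserts.

## Problem sizes used by the test suite

The suite verifies path measures against an exhaustive
simple-path-enumeration oracle on 200 random graphs of up to 7 nodes,
the Spearman estimator against a from-scratch rank-then-Pearson oracle
on 100 heavy-tie integer pairs, predictability against the normal
equations on 50 random problems (n = 40, up to 4 predictors), and the
simulation-recovery properties at the design sizes above (50 replicates
for density recovery, 20 for hub recovery and attenuation loss). These
sizes make the oracle checks exact and the Monte-Carlo rates stable
while keeping a full run inside a couple of minutes; they are the
package's chosen verification scales.

## Known limitations

- Thresholded zero-order correlation networks conflate direct and
  indirect association; partial-correlation or regularized estimators
  are out of scope by design.
- Descriptive deltas carry no uncertainty; with arms of 16–87 subjects,
  edge counts and centrality orderings vary substantially across
  replicates, and the package makes no significance claim about
  between-arm differences.
- The undirected estimand supports no directional statement about which
  domain "drives" another; the report confines itself to connectivity
  and centrality numbers.
- In-sample predictability at n comparable to the neighbour count is
  optimistic even with the ridge fallback; treat small-arm
  predictability means as descriptive.
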