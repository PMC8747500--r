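---
title: "Quantifying tight-junction nano-architecture from dSTORM localizations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying tight-junction nano-architecture from dSTORM localizations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tjstorm)
```

## The measurement problem

Blood-brain-barrier tight junctions are built from claudin-5, ZO1 and
occludin arranged at scales far below the diffraction limit. Direct
stochastic optical reconstruction microscopy (dSTORM) resolves single
antibody-labeled molecules at roughly 20 nm precision and summarizes each
capillary cross-section as a *molecular list*: one row per resolved signal
with planar coordinates in nanometres. Two facts shape everything
downstream:

* **Every signal is an amplified proxy.** A labeled target yields several
  localizations (polyclonal primaries, multiple secondaries, repeated
  fluorophore blinking), and the label itself sits up to ~40 nm from the
  epitope. Counts are therefore comparable *between conditions*, not
  absolute molecule numbers.
* **The unit of organization is the cluster.** Junctional proteins form
  dense foci; their size, signal content and density - not raw intensity -
  carry the biology.

`tjstorm` implements the full quantification chain on such lists: cluster
analysis, per-capillary metrics, claudin-5/ZO1 coupling, and a tracer
leakage index, together with a generative simulator so every stage is
testable without microscope data.

## The clustering rule

Two localizations are *clustered* when their Euclidean distance is
**strictly smaller** than a threshold $t$ (default $t = 70$ nm), and a
cluster is the transitive closure of that relation - single-linkage cut at
$t$. Every localization belongs to exactly one cluster. The implementation
(grid-bucketed union-find in C++) is contractually equal to the brute-force
all-pairs definition; the test suite asserts this equivalence against two
independent oracles on hundreds of random instances, including the strict
inequality at exactly $t$.

The 70 nm default reflects the physical constraints of the labeling
strategy: the antibody stack forbids thresholds below ~40 nm, junctional
contact points extend to ~100 nm, and cluster densities are stable across
the 50-100 nm range. `threshold_sweep()` reproduces that robustness check;
single-linkage monotonicity guarantees that partitions at smaller
thresholds refine partitions at larger ones, which the suite asserts as a
property.

Per cluster we report the signal count $n$, the convex-hull area $A$
(µm²), the density $n/A$ (signals/µm²), centroid and hull. The choice of
the convex hull as "cluster area" is a reproducibility convention: absolute
areas depend on the estimator, so cross-condition *fold changes* are the
comparable quantity. Clusters with fewer than three points, or collinear
ones, have no meaningful hull area; they are flagged degenerate, carry area
0 and an undefined density, and are excluded from density summaries (the
exclusion count is logged). `min_points` defaults to 3, the smallest
non-degenerate set.

## Per-capillary quantities

The capillary cross-section - the endothelial unit - is an annotated simple
polygon. Within it we count total signals (boundary-inclusive
point-in-polygon), count non-degenerate clusters (a boundary-straddling
cluster belongs to the capillary iff its centroid is inside - a
deterministic, order-free rule), and normalize totals by capillary
diameter.

"Diameter" of a non-circular lumen is an estimator convention, and the
original manual measurement procedure is unknown, so three estimators are
provided and agree on circles: the default *matched ellipse* (axis ratio
from the polygon's central second moments, scaled to the polygon area, mean
of major and minor diameters - robust for elongated lumens), the
equivalent-circle diameter $2\sqrt{A/\pi}$, and the maximum Feret caliper.
Whether totals should be normalized per diameter or per circumference is
ambiguous in places; both are available (`normalize_by`), diameter being
the default, and the choice is echoed in every output row.

**Cluster coupling.** A claudin-5 cluster is *coupled* to ZO1 when the
minimum member-to-member distance to any ZO1 cluster is at most
`pairing_nm` (default 100 nm - the scale of the junctional insets where
coupled pairs are visible; no published rule exists, so the criterion is a
package convention, configurable and always reported). Coupled vs
independent cluster densities are summarized as mean ± s.e.m. and their
ratio, with empty groups flagged explicitly rather than returning silent
`NaN`s.

## The leakage index

Tracer challenge experiments ask whether injected molecules cross the
junction: signal on the abluminal (brain-facing) side of the claudin-5 ring
is the readout. The measurement band is the region between the outward
offsets of the ring polygon at 100 and 300 nm (both configurable). For a
convex ring the offset region is an exact Minkowski sum with a disc, so

$$\text{band area} = P\,(d_{out} - d_{in}) + \pi\,(d_{out}^2 - d_{in}^2)$$

with $P$ the ring perimeter - no discretization error; membership is tested
with exact point-to-boundary distances. Non-convex annotations are rejected
with a pointer to `ring_from_localizations()`, which fits the ring as the
convex hull of the claudin-5 signal. The band covers the full
circumference; restricting to a sub-arc is left to the ROI annotation.

The *relative leakage index* of a capillary is its abluminal tracer density
divided by the mean density of a reference group, whose mean index is
therefore exactly 1 by construction - an identity the tests assert to
machine precision, for any data. The index is invariant to global rescaling
of densities.

## Group comparisons

Two groups are compared with a two-tailed Mann-Whitney U test: exact
enumeration of all rank labelings when both groups have at most 8
observations (exact under ties; $p = \min(1, 2\min(P(U\le u), P(U\ge u)))$),
and a tie-corrected, continuity-corrected normal approximation otherwise.
The continuity correction is what brings the approximation within 0.01 of
the exact tail already at $n = 9$ per group; without it the discrepancy
reaches 0.04. Three or more groups use tie-corrected Kruskal-Wallis with
Dunn's pairwise z-tests; the multiplicity adjustment (Dunn-Bonferroni by
default, any `p.adjust` method selectable) is always reported. Type-I error
of the approximate test is verified by simulation to sit in [0.03, 0.07] at
$\alpha = 0.05$.

## What the simulator states, and what a green test establishes

`generate_scene()` draws from a Neyman-Scott compound process:

| parameter | default | meaning |
|---|---|---|
| `ring_diameter_um` | 5.9 (P9-like) / 11.1 (E12-like) | capillary calibre |
| `n_clusters` | 12 / 31 | foci per cross-section |
| `molecules_per_cluster` | 100 / 145 | zero-truncated Poisson mean |
| `blinks_per_molecule` | 3 | geometric (≥ 1) mean - overcounting |
| `cluster_radius_nm` | ~300 (disc) | focus extent |
| `sigma_loc_nm` | 20 | localization precision |
| `background_rate_um2` | 2 (60 for occludin-like) | dispersed signal |

Cluster centers sit on the ring circumference (or a strand, or dispersed);
molecules spread uniformly in a disc around each center (a Gaussian option
exists, but Gaussian tails intrinsically shed satellite fragments at the
70 nm cut - discs match the discrete-foci phenotype and were chosen for the
presets); every blink adds independent Gaussian localization noise; tracer
channels are homogeneous Poisson fields in the lumen and in the abluminal
annulus with a controllable density ratio. Preset parameters were fixed
once from the reported regimes (ring diameters 5.9/11.1 µm, per-capillary
totals of a few thousand vs ~14k signals, ~12 vs ~31 foci, 20 nm precision,
3x overcounting) and are not fitted to any dataset.

Every localization carries its lineage (molecule → cluster, background,
or tracer class), and each planted cluster records the convex-hull density
of its true member set. *Planted density is defined under the same hull
convention the pipeline uses*: the convex hull of a finite sample is a
biased estimator of a region's geometric area (relative bias $O(n^{-2/3})$),
so comparing recovered densities against a parameter density would fail at
any sample size for reasons unrelated to the method. With the
truth-membership definition, recovery error isolates partitioning mistakes
- which is the thing worth testing.

The simulator does **not** model photokinetics (duty cycles, frame
structure), camera/PSF effects, chromatic registration error, drift, or 3D
structure. A green recovery test therefore establishes that the analysis
chain is correct on data matching its stated generative assumptions - not
that those assumptions describe any particular microscope.

Recovery criteria involving ratios of group means (the 10x abluminal
contrast, the 5x coupled/independent contrast) are judged against
delta-method standard errors of the ratio: the reference-group mean in the
denominator fluctuates too (it dominates the variance at 10 capillaries per
group), and ignoring it would falsely reject unbiased recoveries.

## Numerical conventions and degenerate inputs

* All internal computation in nm; areas reported in µm², densities in
  signals/µm², normalized abundance in signals/µm.
* Coordinates follow the camera export convention (x right, y down, origin
  top-left); all quantities are invariant under rigid motions, asserted to
  1e-9 relative.
* Distances exactly at a threshold never merge (strict inequality); ties in
  rank tests use midranks with the standard tie corrections.
* Empty tables, empty groups, degenerate hulls and all-tied samples are
  explicit cases: empty partitions are valid, undefined ratios are flagged,
  an all-tied Mann-Whitney returns $p = 1$.
* Cluster ids are contiguous integers in order of first appearance, making
  outputs deterministic for a given record order while the partition itself
  is order-invariant.
* Scene generation seeds the RNG locally and restores the caller's state.

## Known limitations

Convex-hull areas underestimate concave or fragmented foci; alpha-shapes
would refine this but change absolute values, not fold-changes. The
abluminal band requires a convex ring. Coupling uses a single distance
criterion, not colocalization statistics. No blink-grouping temporal
correction is applied - overcounting is treated as a multiplicative factor
that cancels in relative comparisons, and the simulator models it
explicitly instead.
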