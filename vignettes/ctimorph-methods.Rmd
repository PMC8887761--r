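---
title: "Methods: CTI morphometry, normalization and network topology"
author: "ctimorph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: CTI morphometry, normalization and network topology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctimorph)
```

## Scope and data model

The cavotricuspid isthmus (CTI) is the quadrilateral region of the right
atrium between the terminal crest (TC) and the vestibule (VB), bounded
laterally by the inferolateral (ILI) and paraseptal (PSI) isthmus lines and
divided by the central isthmus (CI). Within it, cable-like pectinate muscles
(PMs) form a branching/merging network that carries electrical activation
from the TC to the VB; its geometry and topology are relevant to
isthmus-dependent flutter and to ablation planning.

`ctimorph` consumes *annotations*, not photographs: per specimen, a JSON
file holds the six boundary corner points (intersections of ILI/CI/PSI with
VB and TC), the TC/VB contours and the three isthmus polylines, the closed
CTI boundary polygon, labelled ramification sites, and one closed contour
per PM segment. All geometry is stored in mm; pixel files are converted at
read time using the image resolution (µm/px). The package reduces the
anatomy to a 2-D representation, which is adequate for thin, flattened
preparations but not for strongly three-dimensional trabeculations.

Ramifications carry one of six level symbols with the fixed order
`c < p < x < y < a < v`: TC exit sites (`c`), the first posterior branching
level (`p`), optional intermediate sublevels (`x`, `y`), the last anterior
merging level (`a`), and VB entry sites (`v`). Anchors outside the region of
interest (e.g. `c0`) are stored like real ramifications with `index = 0` and
`virtual = TRUE`; they remain valid segment endpoints but are excluded from
per-level counts and from the RI/CXI histograms.

### Segment inclusion filters

Analysis includes a PM segment when its rectangle-equivalent diameter is at
least `min_diameter` (default 0.1 mm — the annotation practice only resolves
strands down to roughly 100 µm), it lies at the endocardial surface, and it
is not one of the rare epicardial strands oriented orthogonally to the PM
ensemble. `filter_segments()` is a strict partition: every input segment
lands either in the included set or in the excluded set with exactly one
reason code, and degenerate contours are routed to the excluded set rather
than raising errors.

## Rectangle-equivalent length and diameter

Irregular, elongated contours are summarized by the rectangle with the same
area $A$ and circumference $C$:

$$L = \frac{C + \sqrt{C^2 - 16A}}{4}, \qquad
  D = \frac{C - \sqrt{C^2 - 16A}}{4},$$

which satisfy $L D = A$ and $L + D = C/2$ and invert the forward map exactly
for every true rectangle. The approximation is intended for short and/or
thin strands.

**Degenerate inputs.** When $C^2 < 16A$ no rectangle has that $(A, C)$ pair:
the contour is "rounder" than any rectangle of its perimeter (by the
isoperimetric inequality the square $C^2 = 16A$ is the limit). We clamp to
the square limit $L = D = C/4$, set a `clamped` flag and warn. This choice
preserves $L + D = C/2$, keeps $L$ monotone in $C$, and makes the clamping
condition exactly testable ($C^2 < 16A$ if and only if `clamped`).

## Per-specimen morphometry

* `CTI_A` is the area of the CTI boundary polygon.
* `CTI_m` (muscular area) is the area of the *union* of the included PM
  contours clipped to the CTI boundary. The union counts overlaps at
  ramifications once; this is coverage, not summation. A `sum_overlaps`
  switch reproduces the naive summed-area variant for sensitivity checks.
* `CTI_nm` (non-muscular area) is `CTI_A − CTI_m` minus the parts of the
  TC and VB contours inside the CTI boundary, floored at zero with a
  warning. The TC/VB contributions are clipped because only their portion
  inside the CTI can displace non-muscular area there; `TC_A`, `TC_L`,
  `TC_D` (and the VB analogues) are nevertheless reported for the *full*
  contours, because those describe the structures themselves. The
  rectangle-equivalent estimator is applied to TC and VB like to any other
  elongated contour.
* Isthmus lengths are polyline arc lengths (the drawn isthmus lines are
  curves, so corner-to-corner chords would underestimate), and the
  trapezoid ratios CI/ILI, PSI/CI, PSI/ILI are their plain quotients.
  Ratios are stored as dimensionless quotients; table/CSV output multiplies
  by 100.

**Polygon boolean areas.** No polygon-clipping dependency is used. Union
and intersection areas are computed by an exact vertical slab sweep: break
abscissae are all vertex x-coordinates plus all pairwise edge-crossing
x-coordinates; between consecutive breaks the cross-sectional union length
is linear in $x$, so the midpoint rule integrates each slab exactly. The
algorithm is $O(E^2)$ in the number of edges, which is ample for
annotation-scale inputs (tens of small contours), and is validated against
hand-constructed overlap/clipping cases in the tests.

## Two-patch bilinear normalization (NCTI)

To compare specimens of different size and shape, the CTI is mapped onto a
unit square: the left quadrilateral (between ILI and CI) onto
$l \in [0, 0.5]$ and the right one (between CI and PSI) onto
$l \in [0.5, 1]$, with the VB edge at $m = 0$ and the TC edge at $m = 1$.
Each patch uses the bilinear form

$$x = \alpha_1 + \alpha_2 l + \alpha_3 m + \alpha_4 l m, \qquad
  y = \beta_1 + \beta_2 l + \beta_3 m + \beta_4 l m,$$

whose coefficients are fixed by the four corner constraints; for the left
patch the solve matrix (inverse of the corner design matrix) is the
constant matrix with rows $(1,0,0,0)$, $(-2,2,0,0)$, $(-1,0,0,1)$,
$(2,-2,2,-2)$, independent of the corner layout. The two patches agree
along the shared CI edge by construction.

**Inverse map.** Eliminating $l$ gives a quadratic $a m^2 + b m + c = 0$
with

$$a = \alpha_4\beta_3 - \alpha_3\beta_4,\quad
  b = \alpha_4\beta_1 - \alpha_1\beta_4 + \alpha_2\beta_3 - \alpha_3\beta_2
      + x\beta_4 - y\alpha_4,\quad
  c = \alpha_2\beta_1 - \alpha_1\beta_2 + x\beta_2 - y\alpha_2.$$

Note the **negative** sign of the $\alpha_3\beta_2$ term in $b$: one also
finds this coefficient quoted elsewhere with a positive sign, which breaks
the forward–inverse round trip on generic (non-parallelogram) patches. The
round-trip property test (100 random layouts, 1e-9 mm) is the arbiter for
this sign.

Numerical choices for the inverse:

* **Affine fallback.** When $|a| < 10^{-12}\max(|b|, |c|, 1)$ the patch is
  (numerically) a parallelogram and $m = -c/b$ is used; the tests check
  agreement with the closed-form affine inverse.
* **Root and patch selection.** Both quadratic roots are computed under
  both patches. Among the real candidates, solutions with
  $m \in [-0.25, 1.25]$ are preferred; the candidate whose $(l, m)$ lies
  closest (Euclidean distance) to that patch's unit domain wins, with ties
  broken toward the left patch. Points inside either patch therefore invert
  exactly, while points outside the region of interest (virtual anchors,
  ramifications beyond the curved TC/VB borders) receive a well-defined
  nearest-patch extrapolation. How far-outside points "should" be mapped is
  not observable from the data; this rule is our choice and coordinates
  outside $[0,1]$ are deliberately retained.
* **Degenerate layouts.** Coincident or collinear corners of a patch raise
  a degenerate-quadrilateral error at fit time.

## Network topology

Edges of the PM multigraph are directed by ascending level order (TC → VB);
a segment annotated in descending order is auto-reversed with a warning.
Parallel strands between the same node pair are distinct edges. For each
ramification, $RI = N_\text{afferent} + N_\text{efferent}$ and
$CXI = N_\text{efferent} - N_\text{afferent}$ (positive: branching;
negative: merging).

* **Same-level (`ii`) segments** have no level-defined direction. They are
  directed from the lower to the higher ramification index, i.e.
  inferolateral → paraseptal (indices increment in that direction by
  convention). Any fixed direction is acceptable for the conservation laws
  $\sum CXI = 0$ and $\sum RI = 2\,|E|$, which hold structurally because
  every edge contributes exactly one afferent and one efferent; this choice
  also makes re-indexing invariance testable.
* **Sector crossings.** The posterior, central and anterior sectors are the
  open level-order intervals $(c, p)$, $(p, a)$ and $(a, v)$; a segment
  crosses a sector iff the open interval of orders it bridges overlaps the
  sector's interval. Under this rule a `cv` segment crosses all three
  sectors and `ii` segments cross none. The alternative "full-span" rule
  (segment must bridge the whole sector) undercounts mid-sector strands and
  is inconsistent with per-type cohort bookkeeping; the overlap rule is an
  inference, documented as such.
* **Paraseptal-half consolidation.** Restricted to segments touching
  $l > 0.5$: `Plain` (none), `Simple` (all paraseptal-half nodes have
  $RI \le 2$ on the restricted subgraph; parallel strands allowed), the two
  crossover variants (a segment entering from, or leaving into, the
  inferolateral half, direction given by level order), and the two
  `Complex` variants (some paraseptal-half node with $RI \ge 3$). If both
  crossover directions occur without branching — a combination outside the
  six-class scheme — the entering (IL→PS) variant takes precedence; with
  branching the class is `ComplexCrossover` regardless of direction.

## Cohort statistics

Summaries are normality-gated: Shapiro–Wilk at $\alpha = 0.05$, mean ±
sample SD when normality is not rejected, otherwise median ± MAD. The MAD
is the **raw** median absolute deviation (no 1.4826 consistency factor),
the convention used in cohort tables that pair a median of 3.40 with a MAD
of 0.93 over a range 1.80–6.20. Group comparisons use the two-sided
Mann–Whitney test: the exact null when both groups have $\le 8$
observations and no ties, otherwise the tie-corrected normal approximation
with continuity correction. Pairwise segment-type comparisons are
unadjusted by default (an explicit choice mirroring exploratory practice;
`adjust = "holm"` is available). Correlation panels report Spearman's
$\rho$ with an OLS line and a pointwise 95% mean-response band — the band
construction is an assumption, as scatter-plot conventions rarely state it.
For cross-specimen comparability, segment areas are scaled by the
specimen's muscular area $CTI_m$ and lengths/diameters by
$\sqrt{CTI_m}$, making the scaled metrics invariant under uniform
geometric rescaling.

## The synthetic cohort generator

The generator exists so that every pipeline stage can be exercised, with
ground truth, without any external data. Defaults live in a versioned
config (`inst/extdata/default_params.json`) calibrated to the bundled
reference cohort statistics (rabbit CTI, n = 52): body weight lognormal
around a 3.40 kg median; CTI area lognormal around 124 mm² coupled to
weight by a Gaussian copula on ranks with Spearman ρ = 0.49 (a
rank-preserving coupling reproduces a target rank correlation by
construction); isthmus lengths around 13.1 mm (ILI) with CI/ILI ≈ 75% and
PSI/CI ≈ 49%, occasional non-decremental orderings arising naturally from
the ratio distributions; per-level ramification counts around medians
4/3/1/0/3/4; wiring with per-level efferent-count and target-level
distributions proportioned to the reference per-type segment counts; and
per-type segment diameters around the reference medians.

Construction choices that make recovery tests sharp:

* Node positions are drawn in normalized coordinates (entries along TC,
  exits along VB, branching near 75% and merging near 30% of the NCTI
  height, laterally biased inferolateral) and pushed through the
  specimen's *own* bilinear map into image coordinates — so the
  normalization stage must recover them to round-off.
* Segment contours are **rectangles** (length = node distance ×
  tortuosity ≥ 1, width = the sampled diameter), so the
  rectangle-equivalent estimator recovers each (L, D) exactly and
  per-level counts and class labels are lossless.
* The paraseptal half is populated by a deliberate per-class motif (the
  base network is confined to $l \le 0.47$), with the class drawn from the
  configured six-class mixture unless forced. This mirrors the observation
  that network complexity concentrates inferolaterally, and it makes
  class-wise cohorts recover exactly. When exact per-level counts are
  forced instead, the motif is skipped and nodes span the full width.
* Each specimen uses an RNG substream derived from the cohort seed and its
  index, so cohorts are reproducible (byte-identical files) and
  order-independent.

What the generator does **not** emulate: irregular (non-rectangular) PM
contours and fan-shaped insertions — consequently the generated muscular
fraction of the CTI runs below the reference cohort's mean; curved TC/VB
borders (corners are joined by straight edges, so generated ramifications
rarely fall outside the unit square, unlike real preparations); spatial
clustering of ramifications beyond the coarse height/laterality priors; and
any histological microstructure. Sector-crossing counts reproduce the
qualitative profile (central > posterior ≈ anterior) but run somewhat above
the reference medians. Passing recovery tests therefore demonstrates
correctness of the geometry/topology computations, not realism of every
distributional detail of real cohorts.

## Problem sizes and tolerances

The test suite exercises: 1000 random rectangles for the estimator
identities (1e-9); 100 random corner layouts for corner exactness (1e-12,
relative), CI-edge continuity and forward–inverse round trips (1e-9 mm);
conservation laws on every network of 30- and 200-specimen cohorts;
class-wise recovery on 6 × 4 specimens; and cohort parameter recovery
(CI/ILI within 3 standard errors at n = 52). The acceptance script
regenerates a 52-specimen cohort — the reference cohort size — and
recomputes all reported quantities from scratch.

## Known limitations

* Level labels are annotation inputs; the package validates ordering
  consistency but does not infer levels from geometry.
* The 2-D reduction ignores epicardial strands crossing above the plane;
  such segments can only be excluded via the orthogonal-epicardial flag.
* `CTI_nm` subtracts PM, TC and VB coverage independently; where a PM
  contour overlaps the TC/VB strips inside the CTI the overlap is
  subtracted twice, which is why the value is floored at zero with a
  warning rather than trusted blindly.
* The paraseptal classification depends on the $l = 0.5$ threshold through
  the normalized coordinates; ramifications extremely close to the CI line
  could flip class under reannotation.
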