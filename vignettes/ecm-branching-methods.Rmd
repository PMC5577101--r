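---
title: "Methods: quantifying ECM accumulation and fibril branching"
author: "ecmscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying ECM accumulation and fibril branching}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecmscreen)
```

## The measurement problem

Cultured cells (renal proximal tubular epithelial cells in the motivating
application) deposit an extracellular matrix (ECM) that can be stained in
situ after the cell layer is removed. Automated fluorescence microscopy of
such plates yields two kinds of endpoint:

* **how much** matrix accumulated — total stain intensity above a fixed
  threshold, normalised to a per-well viability signal (or, for
  radiolabelling assays, ECM counts per minute normalised to total cell
  counts); and
* **how the matrix is organised** — a fibril-branching analysis that
  segments the fibrillar network, reduces it to a skeleton, and counts the
  branches it is made of.

The second endpoint is the package's core. A pro-fibrotic stimulus such as
TGF&beta;1 produces a dense mesh of fine fibres linking a few major fibres;
some modulators (the BMP antagonist Gremlin-1 is the canonical example)
leave the *amount* of matrix unchanged but reorganise it into sparse,
thicker, less connected fibrils. Branch counting detects that difference
where a pure intensity endpoint cannot.

## The branching pipeline

Each well is imaged as four fields (1104 × 1104 px at 2 × 2 binning) that
are tiled into one 2208 × 2208 px mosaic before analysis; the mosaic is the
unit of computation throughout (`tileFields()`, `analyzeWell()`). All
pixel grids use (row, col) coordinates, 0-based, origin top-left, and all
intensities stay on the native integer camera scale — nothing is rescaled
on load.

1. **Adaptive segmentation** (`adaptiveSegment()`). A pixel is foreground
   iff its intensity strictly exceeds the Gaussian-weighted local mean plus
   a constant offset. The window is 51 px (Gaussian sigma = window/6,
   truncated at the window, borders reflected half-sample); the offset
   defaults to twice the robust background sigma (1.4826 × MAD of the
   image), floored at 1 count. Both are exposed because staining intensity
   and camera gain vary between instruments.
2. **Fast-marching skeletonization** (`skeletonizeMask()`). The distance
   of every foreground pixel to the background is computed by first-order
   fast marching (Eikonal equation, unit speed; background pixels are
   frozen sources at distance 0). The skeleton is then extracted by
   distance-ordered homotopic thinning: simple pixels — deletions that
   provably preserve the component and hole structure under the standard
   (8-foreground, 4-background) connectivity pairing — are removed in
   increasing distance order, and pixels with at most one foreground
   neighbour (arm tips) are kept. The result is a thin centreline (no
   2 × 2 all-true block) with exactly one skeleton component per mask
   component. In rare symmetric configurations (e.g. four diagonal arms
   meeting in a 2 × 2 core) thinness and tip preservation conflict; the
   implementation then sacrifices the nearest 1–2 px arm, still by
   simple-point deletions only, so topology is never broken.
3. **Spur pruning** (`pruneSpurs()`). Boundary irregularities of wide
   fibres leave short terminal twigs on the skeleton; each twig would
   otherwise add a junction and split a genuine fibre path in two. Arms
   shorter than 4 px running from an endpoint to the first junction are
   removed (whole components never are).
4. **Marker regions** (`extractMarkerRegions()`). Skeleton pixels with
   three or more skeleton neighbours are junction pixels; they belong to
   no marker. The markers are the 8-connected components of the remaining
   skeleton — the maximal paths between junctions and endpoints. Two
   refinements make this robust: components shorter than 3 px are
   discarded as noise, and short paths (< 12 px) that connect two distinct
   junction clusters are folded into the junction. The latter matters
   because an X-crossing of two fibres thins to a pair of nearby
   Y-junctions joined by a short connector whose length grows as the
   crossing angle shallows (roughly mask width / tan θ); counting the
   connector as a branch would systematically overcount crossings.
5. **Branch growth** (`growBranches()`). Each marker is grown into the
   surrounding foreground of the *original* image by a priority flood
   fill: a queue ordered by (pixel intensity descending, marker label
   ascending, insertion order ascending) expands all fronts simultaneously,
   so bright structures are claimed before dim ones and every foreground
   pixel 8-connected to a marker is assigned to exactly one marker.
   Intensity ties go to the lowest marker label, which makes the partition
   fully deterministic.
6. **Inclusion band** (`filterBranches()`). A grown branch is retained iff
   its mean intensity lies in the closed interval
   [marker mean − 50, marker mean + 150] native counts. Branches smaller
   than 5 px² are discarded outright first; excluded branches are kept
   with `retained = FALSE` for audit. The band is read as one asymmetric
   closed interval around the marker mean; whether the original tool meant
   that or two one-sided alternatives cannot be settled from its
   description, so both offsets are configurable and the default encodes
   the interval reading.
7. **Summary** (`summarizeBranches()`). The per-well endpoint is the count
   of retained branches and their mean area (px², µm² when a pixel size is
   known). The mean area is undefined (NA) when nothing is retained.

The pipeline is deterministic: identical inputs and parameters give
identical summaries, and whole runs are hash-reproducible under a fixed
seed and configuration.

### The intensity scale implied by the band

The inclusion band is specified in *absolute* counts, yet the native export
scale of the original instrument is not stated anywhere. Those two facts
constrain each other. A fibre with a Gaussian cross-section of amplitude
*A* above background, segmented by the adaptive rule above, yields a grown
region whose mean sits roughly 0.3 × *A* below the ridge (marker) mean —
the flanks of the profile are included in the region but not in the
skeleton. A lower offset of 50 counts therefore only retains genuine
branches when *A* is of order 150 counts or less. The synthetic generator
consequently emulates a dim stain: fibre peak 120 counts over a
100-count background with additive Gaussian noise of sigma 6 (SNR 20).
This is the regime in which an absolute −50/+150 band is a meaningful
inclusion criterion; on brighter data a user should scale the offsets with
their amplitude (both are parameters).

## The synthetic fibril generator

`generateFibrilImage()` draws each fibre as a smoothed polyline (quadratic
Bézier, control-point deviation ≤ `curvature`) painted with a Gaussian
cross-section by dense sampling with a per-pixel maximum, on a constant
background with additive clipped Gaussian noise. Ground truth is computed
from the exact geometry, not from pixels: nodes are fibre endpoints and
pairwise polyline intersections (hits closer than 1.5 px are merged), each
fibre contributes one edge per span between consecutive nodes along its
arc length, and the true branch count is the edge count. This mirrors the
operational definition the pipeline uses (skeleton paths between
junctions/endpoints), which is what makes recovery well-posed.

Default network: 3 major fibres (sigma 2.5 px) plus 40 mesh fibres
(sigma 1.2 px) on a 512 px image — the dense stimulated phenotype.
`generatePhenotypePair()` derives the altered phenotype by keeping the
major fibres, quartering the mesh count and doubling all widths: sparser,
thicker, less connected by construction. `generateCleanNetwork()`
rejection-samples straight, noiseless fibres so that every pair either
crosses transversally (≥ 35°) or stays ≥ 10 widths apart and all nodes are
≥ 30 px apart; these are the conditions under which branch recovery is
tested exactly. `crossingFibreWell()` is the two-fibre reference with a
ground truth of exactly 4 branches.

What the generator does **not** emulate: optical point-spread blurring,
Poisson photon statistics, uneven illumination, staining heterogeneity
along a fibre, out-of-focus fields, and physical fibre bundling. Passing
the recovery tests therefore shows the pipeline's operators implement
their definitions correctly and discriminate the two phenotypes under
clean conditions — not that branch counts on real micrographs are
unbiased. On real data the absolute count depends on segmentation
parameters; comparisons should be within-plate against controls.

Plate-level readouts (`generatePlateReadouts()`) follow a four-parameter
logistic in concentration with mean-one log-normal multiplicative noise;
the defaults (bottom 1, top 4, EC50 15 ng/mL, Hill 1.3, CV 0.1, 8
half-log concentrations × 4 replicates) emulate a potent pro-fibrotic
stimulation with a > 3-fold window on the viability-normalised intensity
scale.

## Dose-response fitting and summaries

`fit4PL()` fits `y = bottom + (top − bottom)/(1 + (EC50/x)^hill)` by
Levenberg–Marquardt least squares (minpack.lm), with EC50 fitted on the
log scale and multi-start initialisation over a 7-point log-spaced EC50
grid × 3 Hill starts (sign chosen from the rank correlation of the data).
The orientation is normalised to `top ≥ bottom` — swapping the asymptotes
while negating the Hill slope is an exact reparameterisation of the same
curve. Flat responses return a degenerate `converged = FALSE` fit rather
than an error, because screening plates do produce them. Zero/vehicle
concentrations are rejected by the fit: they are the unstimulated anchor,
not a point on the log-concentration axis. No weighting is applied by
default; `1/y²` weighting is behind a flag. EC50s are reported in the
input's concentration units, never converted.

Cross-experiment potencies are summarised as geometric mean, min, max and
n (`summarizeExperiments()`) — the natural scale for a parameter that is
log-normally distributed across repeats.

## Statistics

`studentsT()` is the pooled-variance unpaired t-test (Welch behind a
flag), two-sided; `oneWayAnova()` the standard between/within
decomposition (both delegate to `stats`). Zero-variance degeneracies are
reported, not thrown. `dunnettTest()` performs single-step many-to-one
comparisons against the control using the multivariate-t Dunnett
distribution evaluated by seeded Monte-Carlo integration (default 10^5
draws; accuracy about ±0.002 in p). Draws are generated per comparison
sequentially from one seed, so enlarging the family never perturbs the
draws of existing comparisons — adjusted p-values are monotone in family
size — and the adjusted p is floored at the raw p. With one comparison the
exact raw p is returned. A unit test cross-checks the adjustment against
`multcomp::glht` on the same data.

## Problem sizes used by the checks

The validation suite enumerates all 37 196 connected 4 × 4 masks for the
skeleton contract, compares segmentation with a per-pixel brute force on
50 random 16 × 16 images, verifies branch recovery on 20 clean 384 px
networks and the crossing fixture, discriminates 12 paired phenotype wells
at 512 px, recovers EC50 over 100 simulated plates, and estimates the
Dunnett family-wise error over 2000 simulated null experiments (10^4
draws each). These sizes were chosen as the smallest at which each
property is sharply testable.

## Known limitations

* Branch counts depend on segmentation parameters; only the defaults'
  regime is validated. Fibre *width* and orientation anisotropy are not
  quantified.
* The fast-marching distance is first-order accurate; skeleton position
  can wobble ±1 px on wide structures. Topology, which the endpoint
  depends on, is unaffected.
* The junction-merge radius (12 px) caps the resolvable distance between
  genuine neighbouring junctions; networks denser than that merge them.
* The Dunnett adjustment is Monte-Carlo; p-values carry ±0.002 noise and
  require a seed for exact reproducibility.
* ΔΔCt assumes equal amplification efficiency; no efficiency correction
  is applied.
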