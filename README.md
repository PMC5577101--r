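# ecmscreen

High-content quantification of deposited extracellular matrix (ECM) and
its fibrillar organisation, for plate-based in vitro fibrosis models.

Fibrosis is driven by excess accumulation of ECM proteins. Screening
assays that stain the decellularised matrix in situ and image it by
automated fluorescence microscopy yield two complementary endpoints, both
implemented here:

* **ECM accumulation** — total stain intensity above a fixed threshold,
  normalised per well to a viability signal `I_norm = I_ECM / I_viability`
  (or, for ¹⁴C-amino-acid incorporation assays, `cpm_ECM / cpm_cells`),
  with percent inhibition
  `100 · (x_stim − x) / (x_stim − x_unstim)`, fold change, and ΔΔCt
  relative expression against a housekeeper panel.
* **Matrix organisation** — a fibril-branching analysis: the four camera
  fields of each well (1104 × 1104 px) are tiled into one mosaic; an
  adaptive per-pixel threshold (intensity > Gaussian local mean + offset)
  segments the fibrillar network; the segmented regions are skeletonized
  via a fast-marching distance transform with distance-ordered homotopic
  thinning; skeleton paths between junctions/endpoints form marker
  regions; markers are grown over the original image by an
  intensity-priority flood fill; and grown branches are retained when
  their mean intensity lies within `[marker mean − 50, marker mean + 150]`
  native counts. The per-well endpoint is the retained branch count and
  mean branch area.

Dose-response data are fitted with the four-parameter logistic
`y = bottom + (top − bottom) / (1 + (EC50/x)^hill)` (multi-start
Levenberg–Marquardt, EC50 on the log scale), and per-experiment potencies
are summarised as geometric mean / min / max / n. Group comparisons use
the unpaired Student's t-test, one-way ANOVA and Dunnett's post-hoc test
versus control (seeded Monte-Carlo multivariate-t adjustment).

A synthetic fibrillar-network generator with exact ground-truth topology
(fibre endpoints and crossings as graph nodes, spans as edges) makes every
stage testable without microscope data.

## Worked example

Simulate a paired phenotype experiment — a dense stimulated network versus
the sparse, thick-fibril altered phenotype — and run the branching
pipeline on both wells:

```r
library(ecmscreen)

pair <- generatePhenotypePair(fibrilSpec())   # control vs altered spec
ctrl <- pair$control; ctrl@seed <- 101L
alt  <- pair$altered; alt@seed  <- 102L
g1 <- generateFibrilImage(ctrl, wellId = "A01")
g2 <- generateFibrilImage(alt,  wellId = "B01")
g1$well
#> WellImage A01: 512 x 512 px, 16-bit
g1$truth
#> GroundTruth: 43 fibres, 548 nodes, 967 branches

rbind(analyzeWell(g1$well), analyzeWell(g2$well))
#>   well_id n_branches mean_branch_area_px2 mean_branch_area_um2
#> 1     A01        321             134.2960                   NA
#> 2     B01         94             313.2447                   NA
```

The altered phenotype keeps the same stain intensity but shows ~3.5× fewer,
larger branches — the organisation signal that a pure intensity endpoint
misses. (The pipeline counts fewer branches than the 967 ground-truth graph
edges on this dense mesh because crossings closer than the 12 px
junction-merge radius coalesce; the control/altered contrast is what the
endpoint measures.)

Fit a simulated dose-response plate and summarise potencies across
experiments:

```r
ro  <- generatePlateReadouts(doseResponseSpec(seed = 1))
fit <- fit4PL(ro$concentration, ro$ecm_signal / ro$viability_signal,
              unit = "ng/mL")
fit
#> Fit4PL: bottom 0.9991, top 3.969, ec50 14.72 ng/mL, hill 1.23 (rss 2.105, converged)

summarizeExperiments(c(12.9, 14.9, 16.1, 17.4))
#>   geometric_mean  min  max n
#> 1       15.23308 12.9 17.4 4
```

A command-line entry point is installed at
`inst/scripts/ecmscreen` with subcommands `simulate`, `branches`,
`quantify`, `fit` and `stats` (`--config`, `--seed`, `--outdir`,
`--plate-map`, `--images`, `--input`); every run writes its resolved
configuration beside its outputs and is hash-reproducible under a fixed
seed.

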