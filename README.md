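# octquant

Quantitative analysis of macular retinal layers on 3D spectral-domain
optical coherence tomography (SD-OCT), for researchers studying inner
retinal damage from ganglion-cell disease (glaucoma, chiasmal compression
by pituitary tumours, other optic neuropathies).

For each retinal layer of interest — the macular retinal nerve fiber layer
(mRNFL), the combined ganglion cell + inner plexiform layers (GCIPL), the
ganglion cell complex (GCC), and the total retina — the package computes
three indices over the superonasal (SN), inferonasal (IN), superotemporal
(ST) and inferotemporal (IT) quadrants of a 5.0 mm fovea-centered square,
plus the global average:

* **thickness** *d* (µm) — voxel count between the layer's bounding
  surfaces × depth pitch;
* **optical intensity ratio** — mean layer intensity normalized by a
  reference layer (selected by the quality-adjusted coefficient-of-variation
  procedure; RPE by default);
* **optical-intensity attenuation coefficient** (OIAC, mm⁻¹)

  μ = ln(R·β + 1) / (2d),

  with *R* the ratio of the depth-integrated layer signal to the
  depth-integrated reference-layer signal and β a calibration constant
  (default 2.3; `fit_beta()` calibrates it from phantoms or cohorts).

Around this core the package provides: a layered Beer–Lambert speckle
phantom generator with exact ground truth (single volumes and two-group
patient/control cohorts with designed effects), open-format volume and
surface I/O (multi-page TIFF / NRRD + JSON sidecar, TSV/JSON surfaces), a
per-B-scan dynamic-programming surface segmenter with flattening and QC,
fovea-centered laterality-aware quadrant geometry, and the accompanying
statistical layer: normality-gated t / Mann–Whitney comparisons, Pearson
correlation, chi-square, and ROC analysis with DeLong variance and paired
AUC comparison.

## Worked example

```r
library(octquant)

## a synthetic eye with known ground truth
pv  <- generate_volume(phantom_spec(seed = 1))
pv$volume
#> <oct_volume phantom> 128x64x256 voxels @ 46.88x93.75x2.30 um, OD, Q=70.0

## segment the 11 surfaces and compare against truth
seg <- segment_surfaces(pv$volume)
mean(abs(unclass(seg$surfaces) - unclass(pv$truth$surfaces)))
#> 1.15            # mean boundary error in voxels, under default speckle

## fovea, quadrants, and quadrant-wise mRNFL thickness (um)
fov  <- locate_fovea(pv$truth$surfaces, pv$volume$voxel_size)
grid <- make_quadrant_grid(fov, dim(pv$truth$surfaces)[1:2],
                           pv$volume$voxel_size, "OD")
region_values(thickness_map(pv$truth$surfaces, "mRNFL",
                            pv$volume$voxel_size), grid)$values
#>      SN      IN      ST      IT Average
#>   30.67   30.65   30.83   30.51   30.66

## a full simulated case-control study (38 patients / 39 controls)
b <- run_pipeline(run_config(seed = 1))
subset(b$comparisons, metric == "thickness" & layer == "mRNFL")
#>     metric layer  region patient_mean ... control_mean ... test         p
#>  thickness mRNFL      SN        27.07          31.02        t    1.2e-06
#>  thickness mRNFL      IN        25.64          30.38        t    2.1e-08
#>  thickness mRNFL      ST        29.65          31.00        t    8.8e-02
#>  thickness mRNFL      IT        29.15          30.73        t    3.4e-02
#>  thickness mRNFL Average        27.83          30.77        t    1.8e-04
```

The simulated patients carry the designed chiasmal-compression pattern —
nasal-predominant mRNFL thinning — and the comparison table recovers it:
strong SN/IN significance, marginal temporal rows. The ROC stage shows
thickness discriminating slightly better than the attenuation coefficient
for the global mRNFL average, with the paired DeLong test on their AUC
difference:

```r
subset(b$roc, layer == "mRNFL" & region == "Average")
#>     metric  region    auc      se  ci_lo  ci_hi     z        p
#>  thickness Average 0.7473 0.05738 0.6348 0.8598 4.310  1.6e-05
#>       oiac Average 0.7260 0.05945 0.6095 0.8426 3.803  1.4e-04
b$roc_pairs[b$roc_pairs$region == "Average", ]
#>   region delta_auc      se    ci_lo  ci_hi      z     p
#>  Average   0.02126 0.02591 -0.02952 0.07204 0.8204 0.412
```

`render_report(b)` formats all tables (demographics, thickness / intensity
ratio / OIAC comparisons, correlations, ROC, paired AUC) as markdown with
the conventional `mean±SD` layout; `run_config(out_dir = ...)` writes every
table as CSV together with the configuration and a run log. A thin shell
wrapper lives at `inst/scripts/run_pipeline.R`.

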