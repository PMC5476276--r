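---
title: "Quantifying retinal layers on 3D SD-OCT: thickness, intensity ratio, and the attenuation coefficient"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying retinal layers on 3D SD-OCT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(octquant)
```

## The measurement problem

Spectral-domain optical coherence tomography (SD-OCT) images the retina as a
3D grid of backscattered-intensity voxels. Diseases that damage retinal
ganglion cells — glaucoma, or compression of the optic chiasm by a pituitary
tumour — thin the inner retinal layers, and may also change their optical
reflectivity before any thickness change is measurable. `octquant`
implements the three indices commonly used to quantify this on macular
volumes, per retinal layer and per quadrant of a 5.0 mm fovea-centered
square:

* **thickness** (µm): voxels between the layer's bounding surfaces times the
  depth pitch;
* **optical intensity ratio** (unitless): mean layer intensity normalized by
  a reference layer, since raw device intensities are arbitrary and vary
  with image quality;
* **optical-intensity attenuation coefficient** (OIAC, mm⁻¹):

  $$\mu = \frac{\ln(R\,\beta + 1)}{2d},$$

  where $R$ is the ratio of the depth-integrated signal of the layer of
  interest to that of the reference layer, $d$ the layer thickness in mm,
  and $\beta$ a calibration constant. The OIAC combines morphology ($d$)
  and reflectivity ($R$) into an estimate of the layer's light attenuation.

The analysed slabs are the macular retinal nerve fiber layer (mRNFL), the
combined ganglion cell and inner plexiform layers (GCIPL), the ganglion
cell complex (GCC = mRNFL + GCIPL), and the total retina. Each is reported
for the superonasal (SN), inferonasal (IN), superotemporal (ST), and
inferotemporal (IT) quadrants plus the global average over the square.

Because no clinical volumes ship with the package, a synthetic phantom
module generates volumes and whole two-group cohorts with known ground
truth; every claim the package makes about itself is a property test
against that truth.

## The phantom's signal model

A phantom A-line is a stack of ten layers (RNFL, GCL, IPL, INL, OPL, ONL,
ELM, ISOS, OS, RPE) between vitreous above and a rapidly attenuated
sub-RPE residual below. The noise-free intensity at depth $z$ inside
layer $l$ follows two-way Beer–Lambert attenuation:

$$I(z) = I_0\, b_l\, \exp\!\Big(-2 \int_0^z \mu(u)\, du\Big),$$

with $b_l$ the layer's backscatter fraction and $\mu$ in mm⁻¹. Speckle is
multiplicative unit-mean Gamma noise (shape $k$, rate $k$), the standard
surrogate for coherent-imaging noise that leaves the expected intensity
unbiased; the device-style image-quality score is a monotone map of the
speckle shape, $q = 100k/(k + 12)$, placing the default $k = 28$ at the
device-typical $q \approx 70$. The foveal pit thins RNFL/GCL/IPL with a
Gaussian radial profile towards (one voxel above) zero at its centre;
outer layers are unaffected. A parabolic axial bowl emulates retinal
curvature, and each layer's thickness field carries a smooth ±4%
sinusoidal spatial variation.

Key defaults, chosen once as study conditions: grid 128×64×256 voxels
with the transverse pitch scaled so the field of view is 6×6 mm (the full
512×256 grid reproduces the 11.72×23.44 µm pitch of the reference device;
the desk-scale grid keeps a volume's generation plus segmentation around
a few seconds), depth pitch 2.3 µm, incident intensity 60 000 AU on the
16-bit scale, layer thicknesses summing to ≈285 µm, attenuation defaults
near the magnitudes reported for these layers in vivo (mRNFL ≈ 7.4 mm⁻¹,
GCIPL ≈ 5.6 mm⁻¹).

What the phantom does *not* emulate: vascular shadows, motion artifacts
and black-band dropouts (excluded scans in clinical practice), focus and
depth-dependent device roll-off, and the device's proprietary intensity
post-processing. One visible consequence of the last point: with
physically plausible attenuation values, the phantom's raw RPE is not the
brightest layer (as it is on device-processed exports); the contrast
*signs* at each boundary, which the segmenter relies on, are preserved.
Passing tests therefore demonstrate correctness of the quantification
machinery under the stated model, not robustness to device pathology.

## Cohorts and the designed disease effect

`cohort_spec()` describes a patient/control study (default 38/39, the
size of the motivating dataset). Patient effects are additive per-layer,
per-quadrant thickness deltas and per-layer attenuation deltas; defaults
emulate chiasmal compression: nasal-predominant mRNFL thinning (−4.2 µm
SN, −5.1 µm IN, ≈−1.5 µm temporally), smaller GCIPL thinning, and a
+0.2 mm⁻¹ mRNFL attenuation increase. Between-subject variation combines
a global multiplicative thickness factor (3% SD), per-layer additive
offsets (1–4 µm SD), attenuation offsets, and demographics drawn to match
the study population (ages, sex ratio, laterality mix, quality
70 ± 6.5).

Cohorts are generated in two modes. `volumes = TRUE` renders every voxel
grid — used for small end-to-end checks and for exercising the segmenter.
The default *truth mode* skips voxelization and evaluates the same
Beer–Lambert model in closed form per A-line ([expected_layer_signals()]),
optionally multiplying each layer integral by a Gamma draw with shape
$n_{\text{vox}} k$ — exactly the distribution of a sum of $n_{\text{vox}}$
unit-mean speckle voxels — so the two routes share first- and second-order
statistics. A consistency test holds the two paths to within Monte-Carlo
error of each other. Truth mode is what makes 100-replicate cohort
studies run in minutes rather than days.

For the reference-layer procedure the relevant structure is injected at
the summary level: each layer's backscatter is coupled to the quality
score (coefficient 0.45 per 100 quality units) except one designed
quality-independent layer (RPE, coupling 0, and a smaller residual
between-subject SD of 0.5% vs 2%), mirroring the empirical observation
that RPE scattering is comparatively uniform and quality-insensitive.

## Segmentation and geometry

The built-in segmenter is a deliberate simplification: per-B-scan dynamic
programming on a signed axial-gradient cost (median-3 along depth, boxcar-5
along the fast axis), finding the eleven boundaries sequentially top-down,
each within a search band placed relative to the boundary above. Because
band offsets are non-negative, surfaces cannot cross by construction; the
smoothness constraint (±2 voxels between neighbouring A-lines) matches the
phantom's curvature. Inner boundaries allow a zero gap so the foveal pit
is representable. Featureless B-scans (gradient below 30 AU) are QC-failed
rather than guessed. This stands in for full 3D graph-search segmentation,
which is out of scope; externally computed surfaces can be imported via
`read_surfaces()` and used everywhere the internal segmenter's output is.

Flattening shifts each A-line by a whole number of voxels so a chosen
boundary (default the OS/RPE interface, i.e. the outer photoreceptor
band — the anchor boundary is a package convention, configurable) sits at
constant depth. Integer shifts make thickness maps bit-identical before
and after flattening, which is asserted as an invariant.

The fovea is the A-line minimizing the ILM-to-RNFL/GCL distance within
the central third of the en-face plane ("central region" is not
quantified in the source description; a third is this package's choice),
with ties broken towards the scan centre and then scan order. The 5 mm
square is split by axis-aligned midlines through the fovea — not
diagonals; the reading of the quadrant figure is ambiguous, so the
alternative is isolated behind `make_quadrant_grid()`. Nasal/temporal
assignment flips with laterality (OD/OS); the fovea's own column and row
are assigned to the nasal/superior side, which makes quadrant values
exactly invariant under x-mirroring plus laterality flip. The global
average is the mean over all labelled A-lines, not the mean of quadrant
means, so clipped or masked quadrants do not bias it.

## Quantification conventions

Surface depths are 0-based fractional voxel indices; a layer occupies the
half-open slab $[\lceil s_{\text{top}}\rceil, \lceil s_{\text{bottom}}\rceil)$,
making voxel counts tile each A-line exactly and thickness additive
(GCC = mRNFL + GCIPL bit-exactly in voxel units).

In the OIAC, "integrated signal" is the per-A-line *sum* over the slab's
voxels, not the mean — a mean-based $R$ would change with $d$ and break
the formula's derivation. The logarithm is natural (the Beer–Lambert
convention; the base is exposed in `analysis_config()` because it only
rescales $\mu$). $d$ is converted to mm before dividing so $\mu$ is in
mm⁻¹. A-lines whose layer is thinner than 5 µm (the pit, for inner
layers) are excluded from quadrant means and tallied, never imputed —
imputation would manufacture infinite or zero attenuation. The intensity
ratio is computed per A-line and then quadrant-averaged, paralleling the
per-A-line OIAC; whether the original analysis averaged per A-line or
pooled per quadrant is not stated, so the choice is kept in one place.

**Calibrating β.** Two interpretations of "optimal fitting" are
implemented in `fit_beta()`. With ground truth (mode a): least-squares
$\beta$ against known $\mu$, algebraic for a single observation. Without
(mode b): grid search minimizing the absolute correlation between
per-subject $\mu$ and $d$, on the premise that a tissue property should
not depend on layer thickness. The default β = 2.3 is the published
fitted value and is used when no calibration set is supplied. One
structural caveat, verified by the recovery tests: a single global β
inverts the Beer–Lambert stack exactly only where the tissue *between*
the layer and the reference layer is laterally homogeneous. The phantom's
thickness wobble deliberately violates this, which is why recovery is
held to 2% on the homogeneous (wobble-free) phantom and 10% under the
default wobble-plus-speckle conditions.

**Reference layer.** The selection table reproduces the quality-adjusted
coefficient-of-variation procedure: per candidate layer, the
across-subject variance of mean intensity is reduced by the share
explained by the quality score ($\text{adj var} = s^2(1 - r^2)$), and
the candidate with the lowest adjusted CV wins. Among near-ties (within a
1.5× margin) RPE is preferred, encoding the domain argument that its
scattering is not altered by inner-retinal disease; both the margin and
the candidate list are configuration.

## Statistics

Group comparisons follow the published recipe: a Kolmogorov–Smirnov
normality screen per group — Lilliefors-corrected, because parameters are
estimated from the sample and the plain KS p-value would be
anti-conservative — gates between the unpaired equal-variance t-test
(Welch available as an option) and the two-sided Mann–Whitney U test.
Pearson correlation relates intensity ratio to thickness; the 2×2
chi-square (no continuity correction by default; the original's choice is
unstated) compares sex ratios. ROC analysis computes the AUC via the
Mann–Whitney identity and its variance by DeLong's structural components,
implemented in-package and cross-checked in the test suite against an
independent implementation (pROC); paired AUC differences use the paired
DeLong covariance. Marker orientation is chosen per variable so the
reported AUC is ≥ 0.5, and recorded. No multiple-testing correction is
applied, matching the original analysis; a Holm adjustment can be applied
downstream by the user.

Calibration of all of this is part of the acceptance suite: type-I error
of the gated comparison and of the paired DeLong test under seeded nulls
at the study's group sizes (2000 replicates), CI coverage for the null
AUC, and exact agreement of U and AUC with brute-force pair counting.

## Problem sizes and runtime choices

The test suite and acceptance script run entirely on desk-scale problems,
chosen so the whole suite completes in minutes: 128×64×256 phantom
volumes for segmentation and OIAC recovery, 64×32 en-face grids for
cohort truth-mode studies, 77-subject cohorts, 100 cohort replicates for
the end-to-end designed-effect study, 200 cohorts for reference-layer
recovery, and 1000–2000 replicates for oracle and calibration checks.
The full 512×256×992 clinical grid is supported by the same code paths
(volume generation proceeds one B-scan at a time to bound memory) but is
not exercised by default.

## Known limitations

* The segmenter is phantom-grade; real pathology, vessels, or low-quality
  scans require imported surfaces.
* Eq-1 OIAC with a global β is structurally approximate under lateral
  heterogeneity (quantified above); per-layer calibration absorbs most
  but not all of it.
* Phantom intensity magnitudes are not device-calibrated, so intensity
  ratios and default-β OIAC values are not numerically comparable to
  published clinical tables, only structurally.
* The quality score model (Gamma-shape mapping) is a testability device,
  not a model of any vendor's quality index.
* `.fds` vendor exports are not parsed; volumes must be converted to
  TIFF or NRRD first.
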