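---
title: "Coronary calcium scoring: thresholded and spatially weighted methods"
author: "cacscore"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coronary calcium scoring: thresholded and spatially weighted methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cacscore)
```

## The problem

Coronary artery calcium (CAC) on non-contrast cardiac CT is a standard
marker of subclinical atherosclerosis. The conventional quantification, the
Agatston score (AS), is deliberately conservative: a calcified lesion is
only counted if at least 4 contiguous voxels reach 130 Hounsfield units
(HU) within the coronary search region. That makes the AS a strong event
predictor but a poor measure of *early* disease: a large fraction of
screened participants receive a score of exactly zero even though many of
them carry small or low-density calcifications pushed below the threshold
by partial-volume averaging. Excess zeros also complicate statistical
modelling of disease extent and progression.

The spatially weighted calcium score (SWCS) addresses this by removing the
threshold entirely. Every voxel in the search region contributes a
continuous weight calibrated against a calcium-hydroxyapatite phantom
scanned with the participant, adjusted by the attenuation of its spatial
neighbours. The result is a strictly positive, continuous score that is
comparable to the AS where the AS is informative, and still orders disease
burden where the AS is zero.

This package implements both scores, the phantom calibration between them,
a synthetic cardiac-CT cohort generator with analytic ground truth, and
the test-retest reproducibility statistics used to compare the two
methods. All validation properties are exercised on synthetic cohorts;
no patient data is required or included.

## The Agatston score as implemented

Within the search region (the union of all voxels whose centres fall
within 8 mm of the reader-traced artery centerlines), candidate lesions
are connected components of voxels with attenuation >= 130 HU. Components
with fewer than 4 voxels are discarded. Each accepted lesion contributes

    lesion score = volume (mm^3) x coefficient(max HU)

with the coefficient 1 for a lesion maximum of 130-199 HU, 2 for 200-299,
3 for 300-399 and 4 for >= 400. The AS of the scan is the sum over
lesions, and a participant's score is the arithmetic mean over their
(one or two) scans.

Two conventions deserve note:

* **Contiguity** is 26-connectivity (full 3x3x3 shell) by default, with
  6-connectivity available. Coronary lesions span slices, and the full
  shell is the more permissive reading of "contiguous voxels" in 3D.
* **Volume, not per-slice area.** The score multiplies the lesion's 3D
  volume by the coefficient. The classic 1990 formulation scored per-slice
  areas; the volume form is what this implementation targets, and a
  per-slice mode is deliberately out of scope.

Lesion labelling is order-independent; lesions are reported sorted by
their smallest linear voxel index so outputs are stable.

## Phantom calibration

Each scan includes a phantom with inserts of known calcium-hydroxyapatite
density (reference design: 0, 50, 100, 200 mg/mL) placed beneath the
thorax. `extractPhantomStats()` computes the per-insert sample mean and SD
of attenuation; `fitCalibration()` fits two ordinary-least-squares lines:

* mean HU = a_mu + b_mu x density
* sd HU = a_sigma + b_sigma x density

The SD is fitted linearly rather than pooled because with four inserts
both fits are overdetermined and the residuals provide a cheap quality
check; a constant-SD phantom simply yields a near-zero fitted slope.

The weighting function operates at a **criterion density** c. By default c
is the density whose fitted mean attenuation equals 130 HU, i.e.
`c = (130 - a_mu) / b_mu` clipped to the phantom range. This anchors the
continuous score to the conventional operating point, which is what makes
supra-threshold SWCS values comparable to the AS. The operating point is

    mu_c = a_mu + b_mu * c,    sigma_c = max(a_sigma + b_sigma * c, floor)

with `sigmaFloor` defaulting to 1 HU. The floor exists for degenerate
inputs: a noise-free synthetic scan has insert SD exactly 0, and without
the floor the weight function would collapse to a step at mu_c —
reintroducing the threshold the method is designed to remove.

## The SWCS

Step 1 assigns every region voxel a weight

    w(HU) = Phi((HU - mu_c) / sigma_c)

where Phi is the standard normal CDF: the probability that a voxel drawn
from the phantom-implied attenuation distribution at the criterion
density would show at most the observed attenuation. This form is smooth,
strictly increasing in HU, threshold-free, and parameterized entirely by
the scan's own phantom, so weights are comparable across scanners and
sessions. The exact functional form is a design choice of this package
(the weighting interface is pluggable); any form with these properties
would serve.

Step 2 adjusts each voxel by its neighbourhood:

    s(v) = w(v) x mean{ w(u) : u in N(v) }

with N(v) the 3x3x3 box including v (a 7-voxel face neighbourhood is
available). The multiplicative neighbourhood mean up-weights voxels whose
neighbours also show high attenuation and suppresses isolated noise
spikes, with no free parameters. At volume borders the neighbourhood is
truncated — the mean runs over the voxels that exist, with no padding.
Voxels outside the search region carry weight 0, and region voxels
adjacent to the boundary therefore see their out-of-region neighbours as
zeros; the region is where evidence of coronary calcium is admissible.

The scan score is

    SWCS = kappa x sum over region of s(v) x voxel volume (mm^3)

`kappa` defaults to 1. An auxiliary `calibrateKappa()` regresses AS on
SWCS through the origin over a supra-threshold cohort if numeric
comparability to AS units is wanted; it rescales without changing any
ordering.

### Numerical floor and positivity

`pnorm` underflows to exactly 0 for z below about -38, so air (-1000 HU)
would receive weight 0 and an all-air region would produce SWCS = 0 —
violating the method's strict-positivity property. Weights are therefore
floored at 1e-12. The floor is far below any physiologically relevant
weight (soft tissue at 30 HU with sigma_c = 10 sits near 1e-13 only for
its *squared* contribution) and guarantees SWCS > 0 for any non-empty
region. Strict monotonicity in HU holds above the floor; between two
voxels both at the floor (attenuation below roughly mu_c - 38 sigma_c)
the score is flat, which is irrelevant at tissue attenuations.

## Search-region geometry

Voxel centres are at `origin + index * spacing` (0-based index maths,
1-based R indices); distances are Euclidean point-to-segment distances to
the centerline polyline, so sparse centerline sampling cannot open gaps.
Anisotropic spacing (e.g. 0.68 x 0.68 x 3 mm) is respected throughout; no
resampling is performed, because the reference protocol scores native
2.5/3.0 mm slices. Whether reading software applies the 8 mm constraint
in 3D or per slice is not documented; full 3D Euclidean distance is the
default, and a per-slice mode (`roiMode = "2d"`: in-plane distance,
restricted to slices overlapping the segment's z extent) is provided.

## Reproducibility statistics

For participants with two scans, the primary measure is the percent
difference `|x1 - x2| / ((x1 + x2)/2) * 100`, symmetric, scale-invariant
and bounded by 200; it is undefined when both scores are zero, and such
pairs are excluded and counted. `reproducibilityTable()` computes both
methods' percent differences on the *identical* participant subset, the
per-participant paired contrast (AS% - SWCS%), and a 95% bootstrap
percentile CI for its median and mean (resampling participants, 2000
draws, seeded — chosen for distribution-freeness since the sampling
distribution of a median of skewed differences is awkward analytically).
Subset filters mirror the standard reporting strata (AS > 0 on either
scan, on both scans, both scans under a cutoff).

The ICC is the one-way random-effects ICC(1,1),
`(MSB - MSW) / (MSB + MSW)` for two replicates: scan order within a
participant is exchangeable (acquisition order was randomized in the
reference protocol), so a systematic scan effect is not modelled by
default; a two-way agreement variant ICC(2,1) is available behind
`type = "twoway"`.

## The synthetic cohort generator

`syntheticCohortConfig()` defines the simulated study: 48 x 48 x 20 voxel
volumes at 0.68 x 0.68 x 3 mm (3 mm slices as in electron-beam
acquisition), soft-tissue background at 30 HU, four z-aligned cylindrical
phantom inserts (radius 2.2 mm) near the posterior edge, a five-point
artery centerline wandering through the anterior half, spherical plaques
of uniform density placed within 4 mm of the centerline, and additive
Gaussian scanner noise of 10 HU. The simulated scanner maps density to
attenuation linearly with intercept 30 HU and slope 1 HU/(mg/mL), placing
130 HU at 100 mg/mL — inside the phantom range, so the automatic criterion
density is interpolated, never extrapolated.

Half the participants (configurable) carry only sub-threshold plaques
(35-75 mg/mL, i.e. roughly 65-105 HU: below the threshold even under
noise) and score AS = 0; the rest carry supra-threshold plaques
(120-380 mg/mL). Within each group a participant-level severity latent
`u ~ U(0,1)` jointly grades plaque count, radius and density, with
independent per-plaque jitter: extent and density of calcification
co-vary, as they do in real atherosclerotic burden. This coupling is what
makes a single continuum of "disease severity" identifiable in rank-based
checks. Replicate scans share the plaque ground truth but draw independent
noise and a small rigid repositioning jitter (SD 0.3 mm) for both the
trajectory and the plaques, mimicking two consecutive acquisitions.

Partial volume arises naturally from voxel-centre sampling of the
analytic spheres: a 1.6 mm-radius plaque can fall between 3 mm slice
centres and present only a handful of voxels, or none above threshold.
No point-spread-function blur is applied by default, so ground truth stays
analytic.

### What the generator does *not* emulate

Realistic anatomy, contrast, cardiac and respiratory motion, ECG-gating
artifacts, beam hardening, vendor-specific noise spectra, and reader
variability in tracing centerlines. Passing tests on this cohort
demonstrate that the *algorithms* have their stated mathematical
properties (oracle equivalence, threshold contrast, positivity, ordering,
calibration recovery) — not that the SWCS is clinically validated on real
scanners; that evidence must come from cohort data.

One consequence of the simplified plaque model is worth stating plainly:
synthetic supra-threshold plaques are solid and well above 130 HU, so the
AS is *more* stable between replicate scans here than the SWCS (whose
continuous weights respond to every noise realization). In clinical data
the opposite direction has been reported, driven by lesions hovering at
the detection boundary. The demo therefore reports the paired
reproducibility contrast as it finds it, and the direction property of the
statistics machinery is exercised by a score-level simulation with planted
noise asymmetry, where the expected sign is known by construction.

## Problem sizes and tolerances

The bundled demonstration (`runDemo()`) and the acceptance script use a
200-participant, two-scan cohort — large enough for stable stratum
correlations (roughly 100 participants per stratum) while scoring in well
under a minute per hundred scans. Unit tests use cohorts of 2-60
participants and constructed volumes of up to 16^3 voxels, where
brute-force oracles (per-voxel distance scans, label-propagation
components, the naive SWCS double loop) remain exact and fast. Oracle
equivalence is asserted to 1e-9; NIfTI header geometry round-trips at
single precision because the NIfTI-1 format stores it as 32-bit floats.

## Known limitations

* The weighting function and neighbourhood adjustment are principled
  reconstructions of a two-step design (phantom-derived weight, neighbour
  adjustment), not a byte-level reimplementation of any site's reading
  software; both are pluggable interfaces.
* Candidate-lesion review by analysts is replaced by an optional exclusion
  mask; there is no interactive step.
* Scores from scans without a phantom cannot be calibrated; there is no
  fallback to scanner-nominal HU (an optional affine recalibration of HU
  against a reference line exists, off by default).
* NRRD input is not supported; volumes are NIfTI-1.
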