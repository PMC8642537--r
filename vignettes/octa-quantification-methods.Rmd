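---
title: "Methods: enface OCTA quantification and clustered comparison"
author: "octaquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: enface OCTA quantification and clustered comparison}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette records how each stage of the pipeline is defined, which
parameters matter, and where a genuinely open design choice was resolved —
so that results computed with the package can be interpreted and, where
needed, re-configured.

## Image model and conventions

An enface angiogram is a square matrix of decorrelation intensities
normalized to [0, 1], with a physical field width (default 3 mm). All
coordinates are 0-based `(row, col)` in row-major order and distances are
measured between pixel centers; the pixel size in µm is
`field_width_mm * 1000 / n_cols` (9.87 µm at the default 304 px). Every
physically meaningful threshold is configured in µm and converted through
this pixel size, because the field of view is metric while processing is
pixelwise. The default resolution 304 × 304 matches common commercial
export sizes but is fully configurable, since export resolution varies by
device and software version.

## Binarization

The foveal avascular zone (FAZ) contains no flowing blood, so its
interior intensity distribution is pure noise. The vessel threshold is

```
threshold = mean(FAZ intensities) + k * SD(FAZ intensities),   k = 1.2
```

with the **population** SD (divide by *n*): the FAZ sample is the full
population of reference pixels, not a sample from a larger one, and
intensity statistics conventionally use the population form. A
`sd_type = "sample"` switch restores the *n* − 1 form; at typical FAZ
sizes (thousands of pixels) the difference is negligible.

**What gets thresholded** was an open question, and the package resolves
it empirically. Three modes exist:

* `"gated"` (default): the *raw* image is thresholded at the
  FAZ-referenced value, and only pixels with nonzero Frangi vesselness
  are kept. The threshold is defined in decorrelation units, which is the
  scale the FAZ statistic lives on, and the vesselness filter plays its
  stated role of noise suppression.
* `"raw"`: threshold the raw image only.
* `"enhanced"`: threshold the vesselness image itself. This mode is kept
  for comparability, but it degenerates on realistic inputs: the Frangi
  response inside the FAZ is crushed toward 0 by the global structure-ness
  normalization, the threshold lands near 0, and every pixel of the
  vesselness halo around a vessel becomes foreground. On synthetic
  networks this roughly doubles VD relative to truth, while the gated mode
  recovers a noise-free network's density to a fraction of a percentage
  point.

Binarization is strict (`intensity > threshold`), so raising the
threshold can only remove pixels. Vessel components smaller than
`min_object_px` (default 20 px ≈ two capillary diameters of length) are
removed as speckle; with this cleanup a vessel-free noise image yields an
empty vessel map.

## Vesselness, skeleton, perimeter

The Frangi filter computes scale-normalized Hessian eigenvalues by
separable Gaussian-derivative convolution (replicate padding, kernels
truncated at 4σ and corrected to annihilate constants exactly) at scales
{1, 1.5, 2} px — capillaries are 1–2 px wide at ~10 µm/px — with the
standard blobness parameter β = 0.5 and the structure-ness constant set
to half the maximal Hessian norm per scale. Responses below an absolute
Hessian-norm floor of 1e-8 are treated as flat, so constant images map to
zero vesselness rather than normalized numerical dust.

Skeletonization is sequential deletion of *simple points* (8-connected
foreground, 4-connected background) in four directional subiterations,
retaining endpoints, until stable. Because only simple points are ever
deleted, connected components and holes — hence the Euler number — are
preserved by construction, and the result contains no 2 × 2 foreground
block. The contract is the topology postcondition, not a named algorithm.

The perimeter map marks foreground pixels 4-adjacent to background (the
image border counts as background).

## Vascular indices

**VD, VLD, VDI.** VD and VLD are occupancy percentages of the vessel and
skeleton maps. VDI is reported as **VD / VLD** — mean vessel caliber in
pixels — although the describing sentence in the quantification
literature is sometimes phrased as the inverse: published per-plexus
values near 2.2–2.3 alongside VD ≈ 26–31% are only consistent with a
mean-caliber reading (a quotient > 1). The literal inverse is available
via `vdi_inverted`.

**FD.** Box counts over a grid anchored at the image origin (for
determinism) at sizes {2, 4, 8, 16, 32, 64} px, ordinary least squares of
log N(s) on log(1/s) over all sizes, no windowing. A single pixel gives a
flat count curve and FD 0; an empty skeleton is reported missing.

**VTI.** The skeleton is decomposed into maximal paths between *nodes*
(pixels with ≠ 2 skeleton neighbors in 8-connectivity). Arc length uses
the chain-code metric (1 per axial, √2 per diagonal step); the chord is
the Euclidean endpoint distance. Segments shorter than 3 px are discarded
(1–2 px spurs are thinning artifacts; configurable), as are zero-chord
segments (a loop attached to a single node). Isolated closed loops are
split into two halves so both carry a nonzero chord. The index is the
arc-length-weighted mean of arc/chord ratios (unweighted available);
weighting prevents many short, trivially straight segments from washing
out the curvature of long vessels. Note that two orthogonal 1-px lines
crossing produce a small clique of nodes at the intersection under
8-connectivity — decomposition still covers every pixel, but "one
crossing = exactly four segments" holds only for diagonal crossings.

**VCI.** The isoperimetric quotient P²/(4πA). Two conventions are
implemented because the printed definition (squared perimeter *pixel
count* over 4π times vessel pixel count, pooled over the image) cannot
reproduce the ~1.1 scale reported for capillary networks: pooled counts
on a fused network give values in the thousands, since every inner hole
boundary adds perimeter. The default computes the quotient per
8-connected component and averages with area weights; the literal pooled
form is available via `vci_pooled`. Independently of pooling, the
perimeter is measured as boundary *length* — the corner-corrected
chain-code length (0.980 per axial, 1.406 per diagonal step), which is
nearly unbiased on rasterized smooth shapes — rather than the raw border
pixel count, which undercounts diagonal runs by up to √2 (a digital disk
of radius 50 px has 280 border pixels against a true circumference of
314). With this measure a rasterized disk scores 1.06 and a square 1.24
(analytically 1 and 4/π ≈ 1.273). `perimeter_measure = "pixel_count"`
restores the literal count. The discrepancy between either reading and
the published ~1.1 scale on real networks remains documented, not
resolved; VCI values are comparable only within one convention.

## Nonperfusion

Both measures threshold an exact Euclidean distance transform (scaled to
µm) and exclude the FAZ from the deficit *numerator* only — the
physiologically avascular center is not nonperfusion, but it remains part
of the field, so the denominator stays the whole image
(`denominator = "image_minus_faz"` switches this).

* **CNP**: distance to the nearest **vessel** pixel > 30 µm, then an area
  attribute filter (remove deficit regions < 500 px²) followed by erosion
  (disk radius 1 px), in that order.
* **GPD**: distance to the nearest **skeleton** pixel > 30 µm, no
  morphology.

30 µm is the conventional normal inter-capillary bound of the perfusion-
deficit literature; both thresholds, the attribute-filter area and the
erosion radius are configurable. The defaults were chosen to suppress
single-capillary gaps on synthetic normal networks. Since skeleton ⊆
vessel map, skeleton distances dominate pointwise and GPD ≥ CNP whenever
morphology is disabled.

Two systematic biases are worth knowing. First, a deficit region is
bounded by the 30 µm iso-distance line, not the anatomical lesion border,
so a shell of roughly the threshold width inside each lesion is never
flagged: a 10% lesion made of a few 300–450 µm patches is recovered about
0.8 points low by GPD. Second, the CNP morphology erodes every region
boundary by a further pixel, adding about another 0.8 points; disabling
`cnp_morphology` removes that bias. These are properties of the measures,
not of noise — they persist at noise zero.

The fallback FAZ detector (used only when no mask is supplied) closes
1-px gaps in the vessel map and returns the connected background
component containing the image center; it rejects images whose center is
a vessel pixel. No dilated FAZ margin is excluded from GPD.

## Synthetic data: what it does and does not emulate

`make_network()` builds a perturbed two-family sine lattice (spacing set
by the density target, fraction ≈ 2/spacing), a few 3-px trunks, a
central FAZ disk (default radius 350 µm ≈ 0.38 mm² — a normal-sized
FAZ), circular dropout lesions with radii up to 450 µm (nonperfusion
patches in retinopathy are typically a few hundred µm across) totalling a
requested fraction, and multiplicative Gaussian speckle (default SD 0.2).
Truth masks are exact by construction; every generator is a pure function
of (parameters, seed).

This emulates what the *pipeline* sees — tubular bright structures, a
noise-only FAZ, well-defined avascular patches — but not vascular
physiology: no branching hierarchy, no flow-dependent signal, no
projection artifacts, no segmentation error. Passing tests therefore
validate the measurement chain, not device-specific image quality, and
results on real scans will additionally reflect those artifacts.

`make_cohort()` simulates metric sets directly: per metric, a baseline
mean/SD (taken from typical published per-plexus values in diabetic
eyes), plus an additive DME shift (+3 percentage points on GPD/CNP, half
on the DCP; −2.5 on VD), a smaller same-direction PDR shift, and a
per-patient Gaussian effect shared by fellow eyes with correlation ρ =
0.5. Defaults give 92 patients, ~138 eyes, ~43% DME. CST is drawn so the
DME label and the classification rule (CST > 350 µm, strictly, or
central cysts) agree exactly. Nonperfusion metrics are clamped at 0 and
VTI at 1, which leaves null-cohort group contrasts unbiased because the
clamping is group-independent.

## Clustered comparison

Each metric is analyzed with a marginal Gaussian-identity model
`metric ~ DME + stage(PDR)` — one model per metric, matching the usual
reporting of adjusted group contrasts — with patients as clusters and an
exchangeable working correlation, estimated by moments and iterated to
convergence (tolerance 1e-10 on coefficients, α clamped to [0, 0.99]).
Gaussian identity fits continuous indices whose values stay far from
their bounds; no link is needed.

Inference uses the **Mancl–DeRouen bias-corrected** cluster-robust
sandwich covariance and a **t reference with (clusters − parameters)
degrees of freedom**. Both corrections matter at this design size: the
uncorrected sandwich with ~50–90 clusters and a high-leverage continuous
covariate (CST) underestimates standard errors enough to push 95% CI
coverage below 85% and the nominal 5% test toward 6.5%; with the
corrections the type-I error calibrates to ~0.05 and coverage to ≥ 95%.
For singleton clusters the correction coincides with HC3, which is the
cross-check used in the tests. An `working = "independence"` option fixes
α = 0; this is also the regime where the point estimate is exactly
invariant to duplicating every eye within its cluster — under an
exchangeable working correlation with mixed cluster sizes that invariance
does *not* hold, because duplication changes the exchangeable shrinkage
factor α/(1 + (n−1)α) non-proportionally across cluster sizes.

Bonferroni correction multiplies raw p-values by the family size
(default 15, the per-plexus metric family) and caps at 1. Demographic
comparisons (Welch t, chi-square) are provided as conventional
conveniences. SCP:DCP ratios are per-eye quotients, missing when the DCP
denominator is 0.

## Problem sizes and determinism

The test suite exercises: analytic shapes at 150–304 px; 100 seeded
networks at 160 px for the structural invariants; 20 noise-free 304 px
networks for lesion recovery; 1000 null cohorts for type-I error, 200
for power, 100 for CI coverage and 50 for effect directions. These sizes
keep Monte-Carlo standard errors well inside the asserted bands (e.g.
±0.7 points on the type-I rate). All randomness flows through explicit
seeds; fixed config plus seed reproduces every CSV byte for byte.

## Known limitations

* VCI is convention-dependent (see above); compare only within one
  setting.
* VTI depends on the segment decomposition rule; values are comparable
  only across images processed with the same spur threshold and
  connectivity.
* CNP carries the erosion bias by construction; for unbiased lesion-area
  estimates use GPD or disable the morphology.
* The binarization inflates VD under heavy speckle (any mean + 1.2 SD
  rule admits ~10% of a Gaussian noise tail); the vesselness gate and
  component cleanup remove most but not all of it when noise clusters
  touch vessels.
* The cohort generator draws metrics directly rather than rendering and
  measuring images per eye; it validates the statistical stage, not the
  image stage, under cohort-scale replication.
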