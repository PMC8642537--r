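# octaquant

Quantification of enface OCT angiography (OCTA) images of the retinal
microvasculature, with a clustered statistical comparison for fellow-eye
cohorts. The package targets the question of how capillary nonperfusion
and vascular geometry differ between groups of diabetic eyes — for example
eyes with and without diabetic macular edema (DME) — when each patient may
contribute both eyes.

It is written for researchers working with 3 × 3 mm macular enface scans
of the superficial (SCP) and deep (DCP) capillary plexus who need
reproducible, scriptable versions of the standard OCTA indices, plus a
synthetic-angiogram generator with exact ground truth for validating them.

## What it computes

**Preprocessing.** A Frangi vesselness filter suppresses speckle; the
image is binarized at the FAZ-referenced threshold

> threshold = mean + 1.2 · SD

of the decorrelation signal inside the foveal avascular zone (FAZ), whose
interior carries no flow and is therefore a pure-noise reference. The
binary map is skeletonized by topology-preserving thinning and its
perimeter map extracted.

**Vascular indices**, per plexus:

| index | definition |
|---|---|
| VD | vessel pixels / image pixels (%) |
| VLD | skeleton pixels / image pixels (%) |
| VDI | VD / VLD — mean vessel caliber in pixels |
| FD | box-counting fractal dimension of the skeleton |
| VTI | arc-length / chord-length ratio of skeleton segments (≥ 1) |
| VCI | isoperimetric quotient P² / (4π A) of the vessel map |

**Nonperfusion**, from exact Euclidean distance maps with FAZ exclusion:

- **CNP** (capillary nonperfusion): image fraction farther than a normal
  inter-capillary bound (default 30 µm) from the nearest *vessel* pixel,
  after attribute filtering and erosion;
- **GPD** (geometric perfusion deficit): the analogous fraction measured
  from the *skeleton*.

**Statistics.** A Gaussian-identity generalized estimating equation (GEE)
with exchangeable working correlation compares each metric between groups
while accounting for the correlation of fellow eyes within a patient,
adjusted for diabetic-retinopathy stage (NPDR vs. PDR), with
bias-corrected cluster-robust standard errors and Bonferroni correction
across the metric family. SCP:DCP ratio metrics and within-subgroup
associations with central subfield thickness (CST) are included.

**Synthetic data.** `make_shape()` produces analytic shapes with
closed-form index values; `make_network()` produces capillary-lattice
angiograms with a central FAZ, dropout lesions of known area and speckle
noise, all with exact truth masks; `make_cohort()` simulates a two-group
fellow-eye cohort (92 patients / ~138 eyes by default) with a shared
per-patient random effect and additive DME shifts.

## Worked example

```r
library(octaquant)

net <- make_network(density_target = 28, dropout_fraction = 6,
                    noise_sd = 0.2, seed = 42)   # 304 x 304, 3 mm field
res <- quantify_enface(net$image, net$truth$faz_mask)
res$metrics
#> metric_set:
#>   vd           28.9928
#>   vld          22.0297
#>   vdi          1.3161
#>   fd           1.7731
#>   vti          1.1026
#>   vci          4938.1516
#>   cnp_pct      5.1041
#>   gpd_pct      8.5169
#>   faz_area_mm2 0.3837
```

The generated network truly occupies 25.9% of the field and carries a
6.1% dropout lesion: the measured VD (29.0%) sits a few points above the
truth because speckle adjacent to vessels survives thresholding, CNP
(5.1%) underestimates the lesion slightly because a 30 µm shell at the
lesion border stays within the normal inter-capillary distance of the
surrounding vessels, and GPD (8.5%) exceeds CNP because skeleton distances
dominate vessel distances everywhere. VCI on a fused capillary network is
orders of magnitude above 1 — see the vignette for why this index is only
comparable within one convention.

A simulated cohort comparison (92 patients, 142 eyes, 56 with DME):

```r
co  <- make_cohort(cohort_spec(seed = 1))
rep <- compare_all_metrics(co)
head(rep[order(rep$p_raw), c("metric", "estimate", "se", "p_bonferroni")])
#>         metric estimate    se p_bonferroni
#> 11 dcp_cnp_pct     1.47 0.215     1.54e-08
#> 13      dcp_vd    -3.63 0.568     1.11e-07
#> 12 dcp_gpd_pct     1.59 0.274     1.42e-06
#> 4  scp_cnp_pct     3.46 0.673     2.45e-05
#> 5  scp_gpd_pct     3.13 0.662     1.26e-04
#> 6       scp_vd    -2.74 0.637     6.53e-04
```

DME eyes show higher nonperfusion and lower vessel density in both
plexuses — the directions built into the generator — with
Bonferroni-corrected GEE p-values.

## Command line

```sh
Rscript inst/cli/octaquant.R simulate --out-dir run1 --seed 7
Rscript inst/cli/octaquant.R metrics  --image run1/example_scp.png \
        --faz run1/truth_faz.png --out run1/metrics.csv
Rscript inst/cli/octaquant.R compare  --table run1/cohort.csv \
        --out run1/report.csv
```

Runs with a fixed config and seed are byte-identical in their CSV outputs.

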