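# ctburden

Whole-burden response assessment of diffuse liver metastases on
contrast-enhanced CT.

Patients with diffuse hepatic metastases (common in gastroenteropancreatic
neuroendocrine tumors) carry anywhere from a handful to well over a hundred
liver lesions. RECIST 1.1 grades treatment response from the diameters of at
most two target lesions per organ, measured in one axial plane — a thin
summary of a three-dimensional, often necrotic or hypervascular burden.
`ctburden` implements a computer-aided alternative that measures **every**
lesion:

* **Liver segmentation** — a two-component Gaussian mixture over the HU
  histogram of a radiologist-seeded axial slice, fitted by
  expectation-maximization; thresholding at μ<sub>L</sub> ± k·σ<sub>L</sub>,
  largest-connected-component retention, morphological closing.
* **Tumor segmentation** — per-voxel classification inside the liver by a
  four-layer backpropagation neural network over 10 features of each voxel's
  11×11×11 neighborhood: {mean, sd, skewness, kurtosis, median} of the HU
  values and {contrast, correlation, entropy, energy, homogeneity} of a
  symmetric 3-D gray-level co-occurrence matrix (32 levels, 13 directions),
  followed by morphological clean-up and optional batch edits.
* **Response metrics** — total tumor volume *V* (cm³), mean volumetric tumor
  density *D* (HU over all tumor voxels), RECIST diameter sum *S* (cm), the
  percent changes ΔV, ΔD, ΔS, the combined statistic
  **Δ(V+D) = ΔV + ΔD**, and the RECIST 1.1 category (CR/PR/SD/PD).
* **Cohort statistics** — Pearson correlation of each change metric with
  progression-free survival (complete cases), plus progression /
  nonprogression group summaries. A 25-patient response table ships as a
  fixture.
* **Phantom generator** — paired pre/post synthetic CT volumes (ellipsoidal
  liver, spherical lesions, Gaussian noise) with analytic ground truth, so
  the whole chain is testable without clinical data.

## Worked example

Cohort layer — the packaged 25-patient table (percent changes, RECIST
category, PFS):

```r
library(ctburden)
tab <- read_cohort(cohort_fixture_path())
rep <- correlation_report(tab)
print(rep[, c("metric", "r", "p_value", "n", "significant")], digits = 3)
#>            metric      r p_value  n significant
#> combined combined -0.653 0.00132 21        TRUE
#> volume     volume -0.617 0.00289 21        TRUE
#> density   density -0.226 0.32464 21       FALSE
#> size         size -0.548 0.01019 21        TRUE
```

Each row correlates one change metric with PFS over the 21 patients with
recorded survival. The combined Δ(V+D) tracks outcome more strongly
(r = −0.653) than size change alone (r = −0.548); density change alone does
not correlate (P = 0.325). Group means by progression status:

```r
group_summaries(tab)
#>                         group  n mean_volume_pct mean_density_pct mean_size_pct
#> progression       progression  7          134.07           -8.710         75.01
#> nonprogression nonprogression 18           36.56            6.435        -13.46
```

Image layer — a synthetic pre/post pair whose tumors grow 1.5× in volume
and drop 10 HU, measured through the metric chain on ground-truth masks:

```r
cfg <- phantom_config(dim = c(40, 56, 56), spacing = c(2, 2, 2),
                      liver_semiaxes_mm = c(30, 44, 44), n_tumors = 4,
                      tumor_radius_mm = c(5, 9), volume_scale = 1.5,
                      hu_shift = -10, seed = 42)
ph <- make_phantom(cfg)
measure_response(ph$truth$tumor_mask_pre, ph$truth$tumor_mask_post,
                 ph$pre, ph$post)
#> <response_record>
#>   deltaV = +49.95%  deltaD = -17.07%  deltaS = +47.62%  delta(V+D) = +32.89%
#>   RECIST: PD (progression)
```

The measured ΔV of +49.95% recovers the configured +50% to within grid
discretization; the +47.62% diameter-sum increase classifies the case PD.
For the full chain (EM liver segmentation → texture/NN tumor segmentation →
metrics) see `run_pipeline()` and `recover_metrics(ph, "pipeline", ...)`;
a thin command-line dispatcher over the same functions is installed at
`inst/cli/ctburden`.

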