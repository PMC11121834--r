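# rvcpf — simplified right-ventricular volumetry with the cone–pyramid formula

Quantifying the right ventricle (RV) on cardiac MR is the clinical reference
for RV size and function, but the standard workflow — manually contouring the
endocardial border on every slice of a short-axis stack and summing
area × thickness (disk summation) — is slow and observer-dependent,
particularly at the basal slices near the tricuspid valve. The cone–pyramid
formula (CPF) is a drastically simpler alternative: model the RV cavity as a
truncated cone minus a truncated rhomboid pyramid, and estimate each volume
from just two linear measurements in the four-chamber view,

    EDV = 1.21 · Dd² · Ld        ESV = 1.21 · Ds² · Ls
    EF  = (EDV − ESV) · 100 / EDV

where `Dd`/`Ds` are the basal diameters at the tricuspid-valve level (cm) and
`Ld`/`Ls` the baso-apical lengths (cm) at end-diastole/end-systole. Volumes
are in mL and are indexed to body surface area (mL/m²); RV enlargement and
reduced RV function are called against sex-specific reference limits
(EDV index > 123/104 mL/m², ESV index > 59/48 mL/m², EF < 42/46 % for
men/women).

`rvcpf` is for methodologists who want to study this estimator rather than
apply it to patients: it implements both quantification routes and a fully
synthetic validation bench, so that every stage — geometry, rasterized
segmentations, observer noise, agreement statistics — is testable without
patient data.

The package provides:

* **An explicit geometric family behind the constant.** The solid with taper
  ratio `alpha`, rhombus diagonals `p0·D` and `q0·D` has cavity volume
  `k·D²·L` with closed-form `k = (1 + α + α²)(π(1+p0)²/12 − p0·q0/6)`, and —
  by construction — a four-chamber basal chord of exactly `D`.
  `calibrate_shape()` solves for the member whose `k` is exactly 1.21.
* **Phantom plumbing:** analytic volumes, cross-sections, point membership,
  Monte-Carlo volume oracles, short-axis/long-axis rasterization to binary
  masks (default 8 mm slices, 1 mm pixels).
* **Both quantification methods:** `disk_summation_volume()` on mask stacks,
  `cpf_volume()`/`ejection_fraction()`/`index_to_bsa()`/`classify_rv()` on
  linear measurements.
* **A synthetic cohort generator** reproducing realistic population
  statistics (Dd 4.2 ± 0.6 cm, Ld 7.7 ± 1.1 cm, 70 % male,
  BSA 1.99 ± 0.2 m²), phase-specific shapes, observer noise, and an
  outflow-tract (RVOT) appendage invisible to the four-chamber measurements.
* **The method-comparison stage:** Pearson correlation, Bland–Altman limits
  of agreement, ROC/AUC with DeLong CIs and Youden-index cut-offs, and
  ICC(A,1) observer reliability, assembled by `build_comparison_report()`.

## Worked example

```r
library(rvcpf)

# a shape whose geometric coefficient is exactly the formula constant
shape <- calibrate_shape(alpha = 0.3, q0 = 0.9, target_k = 1.21)
shape
#> RV shape: alpha = 0.3000, p0 = 0.9700, q0 = 0.9000 (k = 1.2100)

# phantom at the cohort-mean dimensions; CPF and the closed form agree exactly
g <- phantom_geometry(shape, D = 4.2, L = 7.7)
g
#> RV phantom: D = 4.200 cm, L = 7.700 cm, k = 1.2100, volume = 164.35 mL

# the standard method on the same phantom: 8 mm slices, 1 mm pixels
stack <- rasterize_short_axis(g, slice_thickness = 0.8, pixel_size = 0.1)
disk_summation_volume(stack)
#> disk_summation volume: 164.83 mL over 10 slices (t = 0.80 cm)

# a full simulated 70-patient method-comparison study
study <- run_study(study_config("realistic", n = 70, seed = 42))
study$report
#> Agreement (standard vs CPF):
#>   RV-EDV index (mL/m2)   83.0 ± 30.8 |   86.8 ± 33.5 | diff  -3.8 ±  6.4 | r = 0.984
#>   RV-ESV index (mL/m2)   44.2 ± 17.1 |   51.7 ± 19.6 | diff  -7.4 ±  4.5 | r = 0.980
#>   RV-EF (%)              46.5 ±  6.9 |   40.1 ±  8.2 | diff   6.5 ±  5.9 | r = 0.712
#> ...
```

Reading the report: each agreement row shows mean ± SD for the standard
method, then for CPF, then the paired difference (standard − CPF) and the
Pearson correlation. In the default scenario CPF overestimates both volumes
(negative differences; systole more than diastole, because the contracted RV
is more crescent-shaped than the model assumes while the formula constant is
fixed) and consequently underestimates EF. The ROC block shows how well the
CPF values recover the standard-method classification of enlarged RV and
reduced RV function, with Youden-optimal cut-offs; the reliability block
gives intra-/inter-observer differences and ICCs for repeated CPF readings.

In the `"ideal"` scenario (no noise, no shape jitter, no RVOT, shapes
calibrated to 1.21) the formula is exact by construction and the report
isolates the rasterization error of disk summation (bias below a fraction of
a mL/m², r > 0.999, ICC = 1).

## Command-line use

A thin CLI over the same functions is installed with the package:

```sh
Rscript $(Rscript -e 'cat(system.file("cli", "rvcpf.R", package = "rvcpf"))') \
    simulate --seed 1 --n 70 --scenario realistic --out study_out/
```

Subcommands: `simulate` (full pipeline), `quantify` (re-quantify a stored
cohort), `compare` (statistics from a results table), `report` (re-render a
study directory). All outputs are CSV/JSON with a provenance stamp (package
version, seed, config hash).

## Limitations

The phantom family is a geometric idealization: no trabeculation, papillary
muscles, crescent geometries in which the rhombus exits the circle, or
congenital RV shapes, and the RVOT appendage is a volume-accurate but
anatomically schematic patch. Conclusions from the synthetic bench
characterize the estimator's behavior under its own assumptions, not
clinical performance. See the methods vignette
(`vignettes/rv-quantification-methods.Rmd`) for the full model description
and design rationale.
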