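# breastdens

Breast density — the proportion of fibroglandular ("dense") tissue in the
breast — is a major image-based marker of breast cancer risk, and it can be
measured from very different data: 2D digital mammograms, acquisition
metadata alone, or 3D breast MRI. `breastdens` implements five measurement
pathways in one tested R toolkit, for imaging scientists and biostatisticians
who need per-subject density outcomes and method-agreement analyses:

* **HSM** — histogram segmentation of a raw mammogram: an intensity threshold
  splits the breast region into glandular area G<sub>AREA</sub> and fat area
  F<sub>AREA</sub>, then
  `%-G = G_AREA / (G_AREA + F_AREA)` and
  `GV = c · G_AREA · t`, `FV = c · F_AREA · t`, `TV = GV + FV`
  with compression thickness `t` (mm) and unit correction factor `c`
  (default 9.96 mL per pixel-area × thickness for the reference geometry).
* **MATH** — a fixed linear model predicting `%-G` from eleven
  exposure-control variables in the mammogram DICOM header (intercept 481.33;
  filter/anode material coded molybdenum = 1, rhodium = 0), with
  `GV = TV · %-G/100`, `FV = TV − GV`.
* **FFDM** — the mammography unit's own header density estimate ("Raddose"),
  passed through the same volume decomposition.
* **3DGRE and STIR MRI** — two-Gaussian decomposition of the voxel-intensity
  histogram of a masked 3D breast model (adipose + gland, the two-compartment
  assumption); gland fraction from the analytic component areas
  `A·σ·√(2π)`, total volume from masked voxel count × voxel volume
  (voxel ratio × reconstructed voxel size³).
* **Concordance** — Pearson correlation matrices between methods and paired
  mean differences with 95% CIs under Benjamini–Hochberg FDR control.

Seeded phantom generators with exact planted ground truth cover all three
input kinds (2D mammograms with metadata, 3D volumes, multi-method measure
tables), so every pathway is testable end to end without clinical data.

## Worked example

Generate a mammogram phantom with 40% planted glandular fraction, run the
three mammographic pathways, then an MRI phantom and the agreement
statistics:

```r
library(breastdens)

sp <- phantom_spec(shape = c(110, 110), gland_fraction = 0.40, seed = 7)
ph <- make_mammogram_phantom(sp)
res <- hsm_density(ph$record)
print(res)
#> Segmentation at threshold 118.5: gland 2683 px, fat 4025 px, total 6708 px (40.0% gland)
#> Breast composition [HSM]: %-G = 40.00, GV = 1336134.0 mL, FV = 2004450.0 mL, TV = 3340584.0 mL

math_composition(ph$record, tv_ml = res$composition$tv_ml)
#> Breast composition [MATH]: %-G = 29.08, GV = 971448.2 mL, FV = 2369135.8 mL, TV = 3340584.0 mL
ffdm_composition(ph$record, tv_ml = res$composition$tv_ml)
#> Breast composition [FFDM]: %-G = 38.30, GV = 1279443.7 mL, FV = 2061140.3 mL, TV = 3340584.0 mL
```

The HSM threshold (118.5) was chosen by Otsu's criterion on the breast-ROI
histogram and recovers the planted 40% exactly; the volumes are on an
arbitrary scale because the 9.96 factor is specific to one imager's geometry
(calibrate it for absolute mL). The MATH value is the linear model evaluated
on the phantom's simulated header; FFDM echoes the simulated Raddose header
estimate (38.3 here, the planted truth plus header noise).

```r
msp <- phantom_spec(c(32, 32, 32), 0.30, gland_mean = 80, fat_mean = 200,
                    gland_sd = 20, fat_sd = 20, seed = 7)
mres <- mri_density(make_mri_phantom(msp, "STIR")$volume)
print(mres)
#> Two-Gaussian histogram decomposition
#>   component 1 (low):  A = 143.4, mean = 80.08, sd = 20.19, area = 7256
#>   component 2 (high): A = 61.56, mean = 200.1, sd = 20.19, area = 3116
#>   rss = 9292, converged = TRUE
#>   gland = high-mean component (STIR) -> fraction 0.3004
#> Breast composition [STIR]: %-G = 30.04, GV = 3.0 mL, FV = 7.0 mL, TV = 10.0 mL
```

Under STIR fat is suppressed (dark), so the bright component is gland; its
area share recovers the planted 30% to 0.04 points. TV is exact: 10,048
masked voxels × 1 mm³.

```r
tab <- make_measure_table(300, inter_method_rho = 0.9,
                          offsets = c(STIR = 50), seed = 7)
pairwise_mean_differences(tab, "tv_ml")
#> Pairwise mean differences (tv_ml), BH-FDR at alpha = 0.05
#>  method_a method_b   n mean_diff  ci_low ci_high   p_value p_adjusted significant
#>       HSM     FFDM 300   -0.2102  -7.121   6.701 9.523e-01  9.523e-01       FALSE
#>       ...
#>       HSM     STIR 300  -54.2900 -62.080 -46.490 1.712e-33  8.561e-33        TRUE
```

Only the pairs involving the method with the planted 50 mL offset are
significant after FDR; `correlation_matrix(tab, "tv_ml")` shows the planted
cross-method correlation (~0.9) throughout.

A command-line interface wrapping the same functions ships at
`inst/cli/breastdens` (subcommands `synth`, `mammo-hsm`, `mammo-math`,
`mammo-ffdm`, `mri-fit`, `concordance`), writing CSV results plus a
provenance JSON per output.

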