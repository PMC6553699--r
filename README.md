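# wsshisto

Registration of patient-specific wall shear stress (WSS) maps to serial
histology of excised carotid plaques.

## The problem

Whether low or high wall shear stress — the frictional force (Pa) blood flow
exerts on the endothelium — drives the composition of advanced carotid
plaques can only be settled against histology, the gold standard for plaque
composition. But WSS lives on the in vivo lumen surface (MRI geometry + CFD)
and histology lives in 2D sections of an excised, deformed specimen.
`wsshisto` implements the bridging pipeline for researchers working with
carotid endarterectomy (CEA) specimens:

* **Shared image domain.** All modalities are carried into the frame of the
  en-face photographs taken of each 1 mm transverse tissue section:
  photo-stack assembly by landmark-based rigid fits, then in vivo MRI →
  ex vivo MRI → photo stack, each via a landmark-anchored similarity
  transform (rotation θ, isotropic scale s, translation t) plus a
  contour-driven cubic B-spline free-form deformation; histology → photo by
  per-slice similarity transforms.
* **Radial binning.** Per section, WSS mesh vertices within ±0.3 mm axially
  are pooled, split into 8 radial sectors about the maximally-inscribed-circle
  centerline point, and reduced to per-bin mean/min/max WSS
  (`floor(8·θ/2π)` with half-open CCW wedges). Plaque thickness per bin is
  the mean shortest lumen-to-media distance; component areas come from the
  shoelace formula.
* **Quality control.** Dice similarity coefficient `2|A∩B|/(|A|+|B|)` and
  symmetric curve Hausdorff distance per section; set-union exclusion
  bookkeeping over three observer-assigned error types.
* **Mismatch sensitivity.** The WSS field is relocated axially
  (±0.3 / ±0.6 mm); per-bin |ΔWSS|, paired Wilcoxon signed-rank tests
  (exact null for n ≤ 25) and WSS–thickness Pearson correlations quantify
  how registration error would propagate into biological conclusions.
* **Phantoms.** A synthetic-specimen generator with analytic WSS field
  `τ(z,θ) = τ₀ + g·z + A·cos θ`, known ground-truth transform chains and
  closed-form per-bin means makes every stage testable without patient data.

## Worked example

```r
library(wsshisto)

spec   <- phantom_spec(n_sections = 6, deformation_magnitude_mm = 0.5, rng_seed = 42)
bundle <- generate_phantom(spec)
cfg <- pipeline_config(list(specimen_from_bundle(bundle, "CEA1")),
                       output_dir = "run",
                       reg_params = bspline_params(iterations = 200),
                       relocations_mm = c(-0.6, -0.3, 0, 0.3, 0.6), seed = 42)
res <- run_pipeline(cfg)

head(as.data.frame(res$bin_table)[, c("slice_index", "bin_index", "mean_wss_pa",
                                      "min_wss_pa", "max_wss_pa",
                                      "plaque_thickness_mm")], 4)
#>   slice_index bin_index mean_wss_pa min_wss_pa max_wss_pa plaque_thickness_mm
#> 1           0         0       2.450      2.339      2.530               1.499
#> 2           0         1       2.187      1.992      2.368               1.499
#> 3           0         2       1.813      1.632      2.008               1.499
#> 4           0         3       1.550      1.470      1.661               1.499
```

Each row is one radial bin of one section: the mean/min/max WSS (Pa) of the
mesh vertices projected into that 45° sector, and the bin's mean plaque
thickness (mm). With the default phantom (τ₀ = 2 Pa, A = 0.5 Pa) bins facing
+x read ≈ 2.5 Pa and bins facing −x ≈ 1.5 Pa; the 1.5 mm wall appears as
~1.499 mm thickness (lumen-contour resampling at 0.05 mm).

```r
for (dz in c("0.3", "0.6"))
  cat("dz =", dz, "mm: grand |delta mean WSS| =",
      round(res$sensitivity$deltas[[dz]]$grand["dmean_pa"], 3), "Pa\n")
#> dz = 0.3 mm: grand |delta mean WSS| = 0.03 Pa
#> dz = 0.6 mm: grand |delta mean WSS| = 0.06 Pa
```

The relocation deltas scale exactly with the axial WSS gradient
(`g = 0.1 Pa/mm` here, so 0.3 mm of mismatch shifts bin means by 0.03 Pa) —
the analytic analogue of a mismatch simulation on real specimens.

```r
res$qc$cross_specimen
#>   error_type dsc_before dsc_after hd_before_mm hd_after_mm
#> 1      type2       1.00      1.00         0.00        0.00
#> 2      type3       0.99      0.99         0.02        0.02
```

On this mildly deformed phantom the recovered chain leaves essentially no
residual mismatch (DSC ≈ 1, HD ≈ 0.02 mm), so exclusion changes nothing; on
real data these summaries reproduce the before/after-exclusion table layout.

A command-line driver wraps the same machinery:

```sh
Rscript inst/cli/wsshisto.R phantom --spec spec.yaml --out specimen1
Rscript inst/cli/wsshisto.R all --config run.yaml
```

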