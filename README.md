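# retinaquant

Quantitative analysis of three retinal imaging endpoints used in myopia
research, plus the cohort statistics that relate them:

- **RNFL birefringence (PS-OCT).** The phase retardation per unit depth
  (PR/UD, degree/100 µm) of the peripapillary retinal nerve fiber layer is
  the slope *b* of the linear model `retardation = a + b·depth` fitted to
  the pooled retardation–depth points of each quadrant (temporal, superior,
  nasal, inferior; 512 A-scans each on a 2048-A-scan circle scan). PR/UD is
  proportional to birefringence, which reflects axonal microtubule
  integrity.
- **Macular vessel density (OCTA).** Enface angiograms are upsampled to
  1024 px, corrected for ocular magnification with Bennett's factor
  `3.382 × 0.013062 × (AL − 1.82)`, binarized, split at the 25-µm caliber
  threshold, skeletonized, and the microvessel skeleton inside a
  0.6/2.5-mm annulus centred on the foveal avascular zone is summarized by
  the rotated-grid box-counting fractal dimension
  `Dbox = −d log N(s) / d log s`, with the minimum non-empty-box count over
  grid rotations at each box size.
- **Blood-flow velocity (RFI).** Per-vessel signed velocities (arterioles
  negative toward the fovea, venules positive away) are validated,
  Bennett-compensated, and summarized as mean speeds per eye.
- **Cohort statistics.** One-way ANOVA with Fisher LSD post hoc tests,
  Pearson correlation, overall multiple-regression F, and noncentral-F
  sample-size solving, written from first principles and cross-checked
  against the standard R fits in the test suite.

A synthetic-data generator produces every input the pipeline consumes —
circumpapillary scans with known slopes, angiograms with known vessel
calibers and avascular zone, fractal fixtures with closed-form dimension,
and a three-group cohort (healthy control / moderate myopia / high myopia)
with the study's demographic distributions — so every stage is testable
against ground truth without clinical data.

The package is aimed at ophthalmic imaging researchers who want a tested,
inspectable reference implementation of these measurements.

## Worked example

```r
library(retinaquant)

# --- birefringence from a synthetic circumpapillary scan ------------------
scan <- gen_circumpapillary_scan(scan_gen_params(seed = 7))
summarize_scan(scan)
#> PR/UD (degree/100 um):
#>      T      S      N      I
#> 10.036 13.984  9.998 14.005
#> average PR/UD: 12.006 degree/100 um
#> RNFL thickness (um):
#>   T   S   N   I
#>  70 120  80 130
#> average thickness: 100.0 um
```

The generator was asked for quadrant slopes (10, 14, 10, 14) with
0.5-degree noise; the pooled fits recover them to about 0.04 degree/100 µm.

```r
# --- vessel density from a synthetic angiogram ----------------------------
ang <- gen_angiogram(vessel_gen_params(n_micro = 90, seed = 7))
vessel_density_pipeline(ang, analysis_px = 512, rotation_step_deg = 45)
#> box-counting fractal dimension Dbox = 1.3894 (7280 foreground px,
#>   12 box sizes, 45 deg rotation step)
```

`Dbox` rises toward 2 as the skeletonized network fills the annulus more
densely; across generated density levels it orders scenes by their true
vessel content (a property the tests verify).

```r
# --- blood-flow summary with magnification compensation -------------------
vel <- gen_velocity_table(seed = 7)
summarize_eye(compensate_velocity(vel, axial_length_mm = 26.9))
#> eye blood-flow summary: arteriolar 4.05 mm/s (n=6), venular 3.97 mm/s (n=6)

# --- full cohort analysis -------------------------------------------------
co <- gen_cohort(cohort_gen_params(seed = 7))
run_study_analysis(co)
#> cohort analysis report
#> endpoint                          F          p
#> pr_ud_i                      23.379     0.0000
#> dbox_superficial             71.339     0.0000
#> dbox_deep                    50.024     0.0000
#> arteriolar_speed              0.793     0.4569
#> venular_speed                 0.494     0.6126
#> ...
#> multiple regression of average PR/UD: F = 1.693, p = 0.138, R^2 = 0.143 (n = 68)
```

The default cohort reproduces the study design's qualitative pattern: a
significant inferior-quadrant PR/UD deficit in high myopia, vessel density
ordered HC > MM > HM with a strongly significant omnibus test, and null
velocity endpoints.

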