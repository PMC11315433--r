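# canalarea

Estimating the cross-sectional area of the cervical central canal (C2-3 to
C6-7) from two linear CT measurements — the anteroposterior (AP) diameter
and the interpedicular distance (IPD) — instead of tracing it by hand.
Intended for spine researchers evaluating linear-measurement-based (and
ultimately AI-driven) canal assessment, and for anyone who needs the
accompanying method-agreement machinery on per-patient, per-level
measurement tables.

## The model

Three closed-form shape approximations share the product
`P = AP · IPD` (mm²):

| shape | formula | behaviour vs manual tracing |
|---|---|---|
| ellipse | (π/4)·AP·IPD | underestimates (−2.8% to −8.3%) |
| triangle | (1/2)·AP·IPD | underestimates badly (≈ −40%) |
| rectangle | AP·IPD | overestimates (+17% to +24%) |

Because the ellipse and rectangle err in opposite directions, a per-level
**second-order approximation** (SOA) combines the full ellipse value with a
small fitted fraction of the rectangle value,

```
SOA = 1·ellipse + c·rectangle = (π/4 + c) · AP · IPD
```

with published per-level weights `c` from 0.07091 (C2-3) down to 0.0210019
(C6-7), available as `builtin_soa_coefficients()` and refittable on your
own cohort with `fit_soa()` (through-origin least squares, or mean-matching
that zeroes the paired mean difference exactly). Agreement against manual
measurement is reported per level as the paired mean difference ± SD with
95% CI, percent error, Pearson correlation (weak/moderate/strong bands at
0.4 and 0.7), and a two-sided paired t-test.

Because no patient-level data are published, the package ships a seeded
synthetic-cohort generator (`generate_cohort()`) calibrated to the
published normative level summaries (`study_level_summary()`: 803 patients,
per-level area means/SDs and correlations), so the entire pipeline is
testable end to end without external data.

## Worked example

```r
library(canalarea)

cohort <- generate_cohort(default_sim_params(seed = 17))
cohort
#> # Canal measurement cohort: 4015 records, 803 patients (provenance: synthetic:seed=17)
#> # A tibble: 4,015 × 5
#>   patient_id level ap_diameter_mm ipd_mm measured_area_mm2
#>   <chr>      <fct>          <dbl>  <dbl>             <dbl>
#> 1 P0001      C2-3            14.3   27.2              407.
#> 2 P0002      C2-3            11.6   19.8              206.
#> 3 P0003      C2-3            15.7   27.2              362.

res <- run_pipeline(cohort = cohort, out_dir = "report")
res$tables$table2[res$tables$table2$level == "C6-7", ]
#>   level shape     mean_difference p      correlation
#> 1 C6-7  ellipse   -3.92±58.66     0.0584 0.684
#> 2 C6-7  triangle  -101.62±43.41   <0.001 0.684
#> 3 C6-7  rectangle 69.54±75.74     <0.001 0.684
```

Reading the C6-7 rows: on this synthetic cohort the ellipse is nearly
unbiased there (−3.9 mm² on a ~271 mm² canal, t-test not significant), the
triangle misses by −102 mm² and the rectangle by +70 mm², and all three
share one correlation (0.684) with the measured area because each is a
positive multiple of AP·IPD. `run_pipeline()` writes four CSV tables
(per-level means, mean differences, percent errors, SOA summary) plus a
run log into `report/`; with `soa_coeffs = "fitted", soa_method =
"mean_match"` the SOA mean-difference column is zero and every paired-t
p-value is 1 by construction.

A thin command-line wrapper is installed at `exec/canalarea`:

```sh
Rscript exec/canalarea simulate --seed 17 --out cohort.csv
Rscript exec/canalarea report --in cohort.csv --out-dir report/
```

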