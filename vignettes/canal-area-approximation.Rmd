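---
title: "Approximating cervical canal area from two linear measurements"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Approximating cervical canal area from two linear measurements}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(canalarea)
```

## The problem

Central canal stenosis of the cervical spine is assessed on imaging by the
cross-sectional area of the bony canal. Tracing that area by hand on CT is
slow and observer-dependent, whereas two linear measurements — the
anteroposterior (AP) diameter and the interpedicular distance (IPD) — are
quick, reproducible, and well within the reach of automated measurement
tools. `canalarea` implements a model that estimates the canal area at the
cervical disc levels C2-3 through C6-7 from those two lengths alone, plus
the agreement machinery needed to judge any such estimate against manually
traced areas.

## Shape approximations

With AP and IPD in mm, the canal cross-section is modelled as

* an **ellipse** with semi-axes IPD/2 and AP/2: $A_e = \frac{\pi}{4}\,\mathrm{AP}\cdot\mathrm{IPD}$,
* a **triangle** with base IPD and height AP: $A_t = \frac{1}{2}\,\mathrm{AP}\cdot\mathrm{IPD}$,
* the bounding **rectangle**: $A_r = \mathrm{AP}\cdot\mathrm{IPD}$.

All three are positive multiples of the same product $P = \mathrm{AP}\cdot\mathrm{IPD}$,
with two consequences the package leans on throughout. First, the exact
identities $A_e = (\pi/4)A_r$ and $A_t = A_r/2$ hold on every record, so any
per-level mean table of the three approximations is internally redundant —
a useful consistency check. Second, Pearson correlation is invariant under
positive scaling, so at a given level all three shapes share a single
correlation with the manual measurement; correlation discriminates between
levels, never between shapes.

In the normative reference summary shipped as `study_level_summary()`
(803 adults aged 18–35, non-pathologic), the ellipse consistently
*under*-estimates the manually traced area (mean difference −7.5 to
−23.2 mm² across levels) while the rectangle consistently
*over*-estimates it (+47 to +65 mm²); the triangle underestimates
severely (around −40%) and is not useful on its own or as a correction
term.

## The second-order approximation

The two opposite, systematic biases invite a per-level combination: keep
the full ellipse value and add a small fraction $c$ of the rectangle value,

$$A_{soa} = 1\cdot A_e + c \cdot A_r = \left(\frac{\pi}{4} + c\right) P.$$

The published per-level weights (`builtin_soa_coefficients()`) range from
0.07091 at C2-3 down to 0.0210019 at C6-7 — smaller caudally, where the
canal is already most elliptical. Although the source equations typeset
the combination with a "×", it is implemented here as the sum above:
a product of two areas would carry units of mm⁴, the prose describes the
ellipse's full value being *combined with a proportion* of the rectangle
value to offset under- versus over-estimation, and only the additive
reading reproduces the published per-level SOA means from the level means
(e.g. $257.54 + 0.07091 \times 327.91 = 280.79$ mm² at C2-3). One published
row (C6-7, 271.92 mm²) is not reproducible from its own level means
(which give 270.92 mm²) and is treated as internally inconsistent; it is
excluded from numeric checks.

### Fitting the coefficient

The original calibration is described only as a best fit tuned until a
paired t-test lost significance, which does not pin down an estimator.
Two are provided:

* `least_squares` (default): $c = \sum r_i d_i / \sum r_i^2$ with
  $d_i = m_i - e_i$, the through-origin least-squares slope of the ellipse
  residual on the rectangle area. It satisfies exact residual
  orthogonality, $\sum r_i (d_i - c\,r_i) = 0$.
* `mean_match`: $c = \bar d / \bar r$, which forces the per-level paired
  mean difference — and hence the paired-t statistic — to exactly zero
  ($p = 1$), the non-significance property the published procedure aimed
  for.

These genuinely differ on real data. Under the reference correlation
structure ($r \approx 0.54$–$0.70$), the covariance of the manual area with
$P$ is *smaller* than $(\pi/4)\,\mathrm{var}(P)$, so the through-origin
least-squares slope of the residual can be negative (it is at C6-7 on
synthetic cohorts), while `mean_match` always lands in the published
0.02–0.07 range — indeed `mean_match` applied to the published level means
essentially reproduces the published coefficients
($23.18/327.91 = 0.0707$ at C2-3 versus the published 0.07091). The
published weights therefore behave like mean-matching calibrations, and
`mean_match` is the method whose fitted coefficients are asserted to fall
in $(0, 0.12)$ in the test suite; `least_squares` keeps its own guarantees
(orthogonality, unbiased recovery of a planted coefficient when the noise
is independent of the rectangle area).

## Agreement statistics

For each level and approximation, `evaluate_cohort()` reports the paired
mean difference ± SD (sample SD, $n-1$; sign convention approximation −
manual, so underestimation is negative), its 95% CI
($\bar d \pm t_{0.975,\,n-1}\,SE$), the Pearson correlation with a
weak/moderate/strong band (|r| < 0.4, 0.4–0.7, ≥ 0.7), and a two-sided
paired t-test (α = 0.05; identical pairs give $t=0, p=1$; a constant
non-zero difference gives $t=\pm\infty, p=0$). No multiple-testing
correction is applied across the 15 shape × level tests, matching the
original analysis. Percent error comes in three modes:

* `of_means` (default): $100(\bar a - \bar m)/\bar m$, the relative bias of
  the level mean. This is the definition under which the published
  per-shape percent-error table is exactly recomputable from the level
  means.
* `mean_of_ratios`: mean of the signed per-record percent errors.
* `mean_abs_ratio`: mean absolute percent error. This mode exists because
  the published SOA table quotes 15–19% "percent error" for models whose
  mean difference is ~0 mm²; that is only coherent as a mean *absolute*
  error (for a difference with SD $s$ and mean ≈ 0,
  $E|d|/\bar m \approx s\sqrt{2/\pi}/\bar m \approx 17\%$ here). The
  report's SOA table uses this mode and says so in its run log; the exact
  published formula is undocumented, so those cells are not used as
  numeric targets.

## The synthetic cohort generator

No patient-level data accompany the reference summaries, so
`generate_cohort()` simulates cohorts with their statistical structure;
its defaults *are* the study conditions: $n = 803$ records per level, the
per-level manual-area means/SDs and product means/SDs of
`study_level_summary()`, and the published per-level correlations as
targets. Per level it draws

1. the product $P$ from a lognormal moment-matched to the rectangle
   mean/SD (lognormal rather than normal to guarantee positivity; the
   mean/variance → meanlog/sdlog map is exact, and any positive mean/SD
   pair is attainable, so the only rejected parameters are non-positive or
   non-finite ones);
2. the manual area as
   $\mu + \rho\,\sigma\, z(P) + \sqrt{1-\rho^2}\,\sigma\,\varepsilon$ with
   $z(P)$ the within-level standardised product and $\varepsilon$ unit
   normal, floored at 1 mm² (the floor sits > 4 SD below every level mean
   and is touched by far fewer than 0.1% of draws — tested);
3. an IPD/AP ratio from a lognormal with mean 2.0 and CV 0.10, splitting
   $P$ into $\mathrm{IPD} = \sqrt{PR}$, $\mathrm{AP} = \sqrt{P/R}$. The
   reference summaries never report AP or IPD separately, so this split is
   an invention; the ratio values encode that cervical canals are roughly
   twice as wide as deep. Every downstream statistic depends on the data
   only through $P$ and the manual area, and the noise is drawn before the
   ratio, so all evaluation output is invariant (to rounding) to the ratio
   parameters — asserted by a test.

Each level draws from its own substream seed derived from the global seed,
so cohorts are reproducible bit-for-bit and one level's draws do not
depend on another's size. What the generator deliberately does not model:
pathology (stenosis, deformity), inter-observer measurement error as a
separate variance component, between-level correlation within a patient,
and any real AP/IPD marginal distributions. Tests passing on synthetic
cohorts therefore validate the *pipeline machinery and its calibration*,
not the clinical performance of the approximations on new patients.

## Numerical and design choices

* All computation is in double precision; rounding to the display
  precision (2 dp for areas, 3 dp for correlations, p as "<0.001" below
  that threshold, otherwise 3 significant digits) happens only in the
  report tables written by `run_pipeline()`.
* Cohort CSVs serialise doubles with 17 significant digits, so
  write-then-read is the identity on records.
* Printed reference values carry 2-dp rounding; desk reproductions
  therefore compare at printed precision with the operands' rounding
  propagated (≤ 0.009 for a mean derived from one rounded mean, ≤ 0.005
  for direct matches) rather than demanding exact equality of rounded
  quantities.
* Validation is total: a measurement file either loads fully or fails
  with an error naming the first offending row and field.
* Problem sizes in the test suite follow the study conditions (803
  records per level) for calibration checks, with 50,000-record runs only
  for the convergence properties of the generator itself.

## Limitations

The approximations apply to non-pathologic cervical anatomy; canals
deformed by stenosis violate the shape assumptions, and external
validation on independent cohorts is out of scope here. The SOA
coefficients shipped in `builtin_soa_coefficients()` were calibrated on a
single 803-patient cohort and should be refit (`fit_soa()`) before use on
populations with different demographics.
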