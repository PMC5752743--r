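# phvalid

Validation tooling for **maturity-offset prediction equations** against the
criterion measure of somatic maturity timing: **age at peak height velocity
(APHV)** estimated from longitudinal stature by the **Preece–Baines
Model 1 (PB1)** growth curve.

Maturity offset equations promise a shortcut that youth-sport and
paediatric practitioners use daily: plug one visit's age and anthropometry
into a regression and read off how far the child is from their adolescent
growth spurt. Whether that shortcut agrees with APHV measured properly —
from serial annual heights — is an empirical question. `phvalid` packages
the full evaluation battery needed to answer it on any longitudinal cohort,
plus a cohort simulator with known ground truth so every stage is testable
without access to (typically unshareable) growth-study data.

## What it computes

**The criterion.** Serial heights are fitted per subject with the
5-parameter PB1 curve

$$h(t) = h_1 - \frac{2\,(h_1 - h_\theta)}{\exp(s_0 (t-\theta)) + \exp(s_1 (t-\theta))}$$

and observed APHV is the age maximising its analytic velocity.

**The predictors.** Five published maturity-offset equations, coefficients
stored to full printed precision: the recommended *Moore-1* pair (boys:
age × sitting height; girls: age × stature), the alternative *Moore-2*
boys' equation (age × stature), and the original four/five-term *Mirwald*
equations (leg length, sitting height, age, mass, mass-by-stature
ratio × 100). Predicted APHV = chronological age − offset.

**The battery.** Chronological-age groups by the midpoint rule
(8.0 = 7.50–8.49 y), years-from-PHV bins −3…+3, duplicate-visit removal
within age class, early/average/late classification around the cohort's
sex-specific mean APHV ± 1.0 y, per-bin bias summaries, percentages of
predictions within ±0.5 y of observed APHV, Bland–Altman regressions of
difference on mean, and intra-individual spread of predicted APHV.

**The simulator.** Study-sized cohorts (193 boys aged 8–18, 199 girls aged
8–16, annual visits) with APHV drawn from truncated normals
(boys 14.06 ± 1.11 y, girls 11.89 ± 1.00 y), realistic measurement noise,
missed late-adolescent visits and same-age-class duplicate visits — with
every subject's true parameters and true APHV recorded in a registry.

## Worked example

```r
library(phvalid)

cohort  <- generate_cohort(cohort_config(n_boys = 60, n_girls = 60, seed = 42))
results <- run_validation(cohort$visits)
results
#> PHV prediction-equation validation
#>   119 subjects analysed (1 excluded: 1 non-converged, 0 APHV outside span)
#>   sex   category     n
#> 1 F     early       11
#> 2 F     average     37
#> 3 F     late        11
#> 4 M     early        9
#> 5 M     average     42
#> 6 M     late         9
```

One non-converged PB1 fit was excluded and logged; the rest classify into
maturity groups around each sex's own mean APHV. The CA-group tables mirror
the standard descriptive layout — here boys at age group 14:

```r
dplyr::filter(results$by_ca, sex == "M", bin == 14) |>
  dplyr::select(equation, n, pred_aphv_mean, obs_aphv_mean, diff_mean, diff_sd)
#>   equation         n pred_aphv_mean obs_aphv_mean diff_mean diff_sd
#> 1 mirwald_boys    57           14.3          14.1     0.145   0.718
#> 2 moore1_boys     57           14.0          14.1    -0.141   0.733
#> 3 moore2_boys     57           14.0          14.1    -0.108   0.712
```

Near the average age at PHV the mean differences are small — the window
where these equations work best. Agreement across all visits is another
story:

```r
p <- dplyr::filter(results$predictions, equation == "moore1_boys")
bland_altman(p$predicted_aphv, p$observed_aphv)
#> Bland-Altman fit (n = 624)
#>   diff = 3.970 -0.319 x mean;  bias -0.455, LoA [-2.557, 1.647]
```

The strongly negative slope is the signature finding: predicted APHV is
compressed toward the sample mean, so the equations systematically
over-predict in early maturers and under-predict in late maturers.
`autoplot()` methods draw the fitted growth curves and Bland–Altman plots;
`tidy()`/`glance()` return model summaries as tibbles.

Single-visit predictions are plain vectorised functions:

```r
moore1_boys(age = 14, sitting_height = 82.2)
#> [1] -0.03332332   # years from PHV: essentially at peak
```

A thin CLI wraps the same functions
(`inst/exec/phvalid simulate|fit|predict|validate`), reading the visit CSV
schema `subject_id, sex, age_years, stature_cm, sitting_height_cm, mass_kg`.

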