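# spiraltremor

Quantifying essential-tremor (ET) severity from wearable sensors recorded
while a patient draws an Archimedes spiral on a digitizing tablet.

ET is an action tremor in the 4–12 Hz band, clinically rated on the
Fahn–Tolosa–Marin (FTM) scale. This package turns the standard
spiral-drawing assessment into two instrumented features per subject and
sensor site:

* **PSD ratio** ρ — integrated power spectral density of the
  high-pass-filtered acceleration vector magnitude √(ax² + ay² + az²) in
  the tremor band (4–12 Hz) divided by the voluntary-movement band
  (0.5–4 Hz). The vector magnitude makes ρ independent of sensor
  orientation; the ratio makes it independent of amplitude units.
* **Task time** T — total pen-down duration of the drawing, segmented from
  the tablet's pen pressure channel (pressure = 0 is pen-up).

From (T, ρ) the package

* estimates FTM severity by ordinary least squares, including the fixed
  published bivariate model `FTM = 8.2439 + 0.2791·T + 1.9890·ρ`
  (r² = 0.561, RMSE = 8.158 on its 17-subject fitting sample),
* compares subject groups nonparametrically (Shapiro–Wilk gate,
  Mann–Whitney U with the min-U convention, Kruskal–Wallis),
* classifies phenotype (control / ET−0 / ET+1 / ET+2) with leave-one-out
  cross-validated SVMs (linear and RBF kernels, per-fold standardisation),
* and simulates complete synthetic cohorts — pen traces, three-site
  accelerometry, clinical scores — with prescribed group statistics, so the
  whole pipeline is testable without clinical recordings.

Audience: movement-disorder and digital-biomarker researchers who have (or
want to simulate) tablet + IMU recordings of spiral drawing.

## Worked example

```r
library(spiraltremor)

# score the three ET subgroups' mean feature pairs with the published model
m <- published_ftm_model()
print(m)
#> FTM severity model (published coefficients):
#>   FTM = 8.2439 + 0.2791 * task_time + 1.9890 * psd_ratio
#>   r^2 = 0.561, RMSE = 8.158 FTM points, n = 17
predict_ftm(m, task_time = c(20.53, 19.82, 26.92), psd_ratio = c(2.84, 5.16, 6.96))
#> [1] 19.62258 24.03890 29.60071
```

Those three inputs are the ET−0, ET+1 and ET+2 group means of task time and
mid-forearm PSD ratio; the outputs are the corresponding sensor-estimated
group FTM scores (≈ 19.63, 24.0, 29.59 — an ordering consistent with the
clinical severity gradient across the subgroups).

```r
# simulate one drawing session and extract its features
pen <- synth_spiral_pen(duration_drawing = 12, seed = 1)
acc <- synth_accel(pen, tremor_spec(tremor_freq = 6.5, tremor_amplitude = 0.18), seed = 2)
extract_features(acc, pen, subject_id = "demo")
#>   subject_id site psd_ratio task_time
#> 1       demo   S2  7.072781        12

# full synthetic cohort: fit the severity model, run the classification grid
tab <- cohort_table(make_cohort(seed = 42), sites = "S2")
et  <- tab[tab$group != "control", ]
fit_bivariate(et$task_time, et$psd_ratio, et$ftm_mean)
#> FTM severity model:
#>   FTM = 13.0355 + 0.0550 * task_time + 3.2944 * psd_ratio
#>   r^2 = 0.192, RMSE = 8.473 FTM points, n = 17
run_classification_grid(tab)[, 1:4]
#>      feature_set n_classes best_kernel accuracy_percent
#> 1           time         2      linear         68.57143
#> 2           time         4      linear         57.14286
#> 3      psd_ratio         2      linear         82.85714
#> 4      psd_ratio         4      linear         48.57143
#> 5 time_psd_ratio         2      linear         88.57143
#> 6 time_psd_ratio         4      linear         51.42857
```

The simulated subject above has a heavy injected tremor, hence ρ ≈ 7; the
cohort-level fit and grid show the characteristic pattern of one random
17-subject ET draw: binary ET-vs-control separation is strong while the
4-class phenotype problem is much harder.

`run_pipeline(pipeline_config(seed = 1), "out/")` executes the whole chain
(simulate → write CSVs → re-ingest → features → statistics → classification
→ markdown report); reruns with the same seed are byte-identical. A thin
command-line wrapper with `simulate / features / analyze / classify / all`
subcommands is installed at `inst/cli/spiraltremor.R`.

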