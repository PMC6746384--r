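# lekaccel

Tools for asking a movement-ecology question with biologging data: **does
high ambient temperature suppress the display behaviour of a lekking
bird?** The package implements, end to end, the analysis chain used to
study the snort-call display of male little bustards (*Tetrax tetrax*)
tracked with back-mounted tri-axial accelerometers, and ships a
ground-truth synthetic study generator so the whole chain is testable
without field data. It is aimed at movement ecologists and methods
developers who want a reproducible, fully seeded reference pipeline for
accelerometer ethograms and thermal activity budgets.

## What it computes

* **Synthetic study generator** — 10-s, 1-Hz tri-axial bursts every 10 or
  20 min from 17 birds at 5 sites over an April–May season, with a known
  display-probability surface
  `logit p = β₀ + f_T(temp) + f_h(time) + f_d(date) + u_bird`,
  hourly site temperatures, and per-class burst signatures (the display
  class reproduces the video-validated posture: heave 0.60 g, sway
  −0.03 g, surge 0.81 g). Defaults are calibrated to the study's printed
  statistics (daytime mean 18 °C, corr(T, hour) = 0.51, daylight display
  prevalence 41.5 %, mean tracking 12.8 d).
* **Burst features** — 39 summary statistics per burst (per-axis moments,
  extremes and quartiles; pairwise covariance, correlation, mean absolute
  difference; vector-norm mean/sd; ODBA) on the first 7 s.
* **Behaviour classification** — random forest (bagged CART with per-node
  feature subsampling, in C++), decision tree, kNN and linear SVM, trained
  on a 10 % labelled subset, compared by pooled display precision/recall
  under 10-fold CV, best family deployed on the remaining 90 %.
* **Aggregation** — daylight window [5:00, 21:00), 2-day post-tagging
  exclusion, ≥ 2 bursts/hour for ≥ 11 of 16 daylight hours
  day-qualification, hourly display proportions averaged (unweighted) into
  daily display activity.
* **GAMMs** (mgcv) — burst-level binomial model
  `display ~ s(temp, k=4) + s(time, k=4) + s(jdate, k=4) + s(bird, bs="re")`
  and day-level Gaussian model
  `activity ~ s(daily_temp, k=4) + s(jdate, k=4) + s(bird, bs="re")`,
  with partial-effect curves ±95 % bands and 10-fold CV predictive error
  (misclassification % / NRMSE).
* **Warming projection** — mean change in predicted daily display activity
  when observed temperatures are shifted +1…+7 °C, date fixed, bird
  effect at population level, with analytic CIs.

## Worked example

```r
library(lekaccel)
cfg <- default_config()
cfg$seed <- 1L
res <- run_all(cfg)           # simulate -> features -> classify ->
                              # aggregate -> model -> project (~20 s)
```

Output printed by the run (abridged):

```
best family: random_forest
random forest CV: precision 1.000 recall 0.996
daylight bursts: 9694, estimated display fraction: 0.411
qualifying bird-days: 163
lekaccel hourly GAMM (REML)
              edf Ref.df  Chi.sq p-value
s(temp_c)   2.574  2.874  58.907       0
s(time)     2.882  2.989 103.486       0
s(jdate)    2.471  2.810  22.694       0
s(bird_id) 14.544 16.000 362.526       0
bird random-intercept variance: 0.1788
hourly CV error: 35.9 +- 1.6 %
daily CV NRMSE: 0.132 +- 0.036
   delta_c decrease_points decrease_relative_pct
1:       1            1.05                   2.6
2:       2            1.89                   4.6
...
7:       7            4.03                   9.9
```

Reading this: the random forest cleanly separates display from
non-display bursts (the synthetic classes are easier than field data, so
precision/recall near 1 rather than the study's 0.92/0.97 floor); 41 % of
daylight bursts are classified as display; the burst-level GAMM recovers
a nonlinear temperature effect (edf 2.6: steep decline to ~20 °C, then a
plateau), a morning-elevated time-of-day effect and a mid-season peak in
date; and shifting every observed day's temperature up by 1…7 °C lowers
mean daily display activity by about 1–4 percentage points (2.6–9.9 %
relative) for this realisation. `run_all(cfg, out_dir = "results/")`
additionally writes every stage's CSV/JSON outputs and a run manifest.

A command-line front end wraps the same stages:

```sh
Rscript -e 'lekaccel::lekaccel_main()' all --seed 1 --out results/
```

## Layout

* `R/synthetic.R` — generator + calibration routines
* `R/features.R`, `src/cart.cpp`, `R/classifier.R` — features and models
* `R/aggregate.R`, `R/models.R`, `R/project.R` — filters, GAMMs, scenarios
* `R/io.R`, `R/pipeline.R`, `R/cli.R` — formats, config, orchestration
* `vignettes/lekaccel-methods.Rmd` — full model description, calibration
  rationale and limitations
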