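# dmsapk

Pediatric Tc-99m DMSA renal pharmacokinetics from quantitative SPECT.

Tc-99m dimercaptosuccinic acid (DMSA) is a renal cortical agent and one of
the most common pediatric nuclear-medicine tracers, yet the kidney
kinetics used for pediatric dose estimates have historically come from
adult data. `dmsapk` is for imaging physicists and dosimetrists who want
to measure (or study the measurement of) pediatric kidney kinetics with
quantitative SPECT: it implements the full chain from simulated
acquisition through reconstruction and uptake quantification to kinetic
modelling and covariate statistics, with every stage testable against
known ground truth.

## What it computes

The kidney time-activity fraction follows the ICRP sum-of-exponentials
model

```
A_s(t)/A0 = F_S * sum_i a_i * exp(-ln(2) t / T_i)
```

with `F_S` the fractional distribution to the kidneys, `a_i` the fraction
of `F_S` with biological half-time `T_i` (negative `a_i` = uptake phase).
The pediatric model is `0.3 * (1.2 - exp(-ln(2) t / 1.1 h))`. Weighting
by physical decay (half-life 6.0 h) and integrating to infinity gives the
time-integrated activity coefficient (TIAC) in closed form:

```
TIAC = F_S * sum_i a_i / (lambda_i + lambda_p),   lambda = ln(2)/T
```

The package provides, by module:

* **Synthetic data** — `make_phantom()`, `simulate_acquisition()`,
  `simulate_planar()`, `cohort_spec()`/`sample_cohort()`: digital
  two-kidney phantoms, 360-degree multi-window SPECT projections with
  Poisson noise, anterior/posterior planar pairs, and 77-patient cohorts
  with known generating kinetics.
* **System model** — `forward_project()`/`back_project()`: rotation-based
  projector with attenuation and distance-dependent collimator response;
  the back projector is the exact adjoint.
* **SPECT quantification** — `attenuation_map_from_scatter_window()`,
  `reconstruct_osem()`, `sensitivity_from_flask()`,
  `kidney_activity_from_image()`, `fraction_injected()`: the CT-free
  clinical chain from raw counts to percent injected activity.
* **Planar/hybrid quantification** — `corrected_kidney_counts()`,
  `hybrid_calibrate()`: conjugate-view planar correction anchored to a
  same-session SPECT activity.
* **Kinetics** — `bin_records()`, `fit_biokinetic()`, `tiac()`,
  `tiac_uncertainty()`, `compare_models()`: 10-min binning, constrained
  weighted fitting (a1 = -1, T2 = Inf), closed-form TIAC with Monte-Carlo
  uncertainty, and model comparison against the shipped `icrp53`,
  `evans` and `current_study` parameter sets.
* **Statistics** — `median_regression()`, `run_covariate_regression()`:
  median (quantile) regression with bootstrap CIs/P values, univariate
  and multivariable, for age / weight / sex effects on uptake.

A binned pediatric uptake table (23 ten-minute bins, 97 measurements,
0.17-5.82 h) ships as plain CSV and is loaded with
`pediatric_uptake_bins()`.

## Worked example

Fit the constrained model to the shipped bin table and compare TIACs:

```r
library(dmsapk)
fit <- fit_biokinetic(pediatric_uptake_bins())
fit
#> Constrained biokinetic fit (a1 = -1, T2 = Inf), weighting = equal
#>     estimate     se
#> F_S   0.3040 0.0699
#> T1    0.8042 0.4033
#> a2    1.2049 0.3084

tiac_uncertainty(fit, n_draws = 5000, seed = 1)
#> TIAC = 2.859 h +/- 0.28 h (T_phys = 6 h)

models <- dmsa_models()[c("icrp53", "evans", "current_study")]
models$fitted <- fit$model
compare_models(models)[, c("model", "F_S", "T1_h", "a2", "tiac_h",
                           "pct_vs_reference")]
#>           model       F_S      T1_h       a2   tiac_h pct_vs_reference
#> 1        icrp53 0.5000000 1.0000000 1.000000 3.709787                0
#> 2         evans 0.4000000 1.0000000 1.000000 1.369768              -63
#> 3 current_study 0.3000000 1.1000000 1.200000 2.713892              -27
#> 4        fitted 0.3039632 0.8041886 1.204903 2.859312              -23
```

Reading: the fit to the binned pediatric data plateaus at
`F_S * a2 = 0.37` of the injected activity, reached with a ~0.8 h uptake
half-time; its decay-weighted TIAC (2.86 ± 0.28 h) and the tabulated
pediatric parameter set (2.71 h) both sit far below the adult ICRP 53
reference (3.71 h) — the pediatric kidney TIAC is 27% lower than the
adult value. The `evans` row shows the closed form applied to that
historical parameter set (1.37 h), which does not reproduce the 3 h
published with it; `compare_models()` flags this rather than hiding it.

An end-to-end simulated quantification:

```r
ph   <- make_phantom()                           # 64^3, kidneys hold 30 MBq of 100
proj <- simulate_acquisition(ph, acquisition_geometry(n_views = 60),
                             sensitivity = 5005, time_post_injection = 3,
                             noise = TRUE, seed = 1)
img  <- reconstruct_osem(proj, true_mu_map(ph), n_iterations = 5, n_subsets = 16)
ka   <- kidney_activity_from_image(img)
fraction_injected(ka$activity, A0 = 100, t_image = 3)
#> [1] 0.2975  (ground truth 0.3)
```

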