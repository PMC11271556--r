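# mfrkit

Quantification of myocardial blood flow (MBF) and myocardial flow reserve
(MFR) from dynamic cardiac SPECT time-activity curves, and an in-silico
test bench for the *processing repeatability* of the two kinetic models in
routine use. It is aimed at nuclear-cardiology physicists and
quantification-software developers who want to study how operator-dependent
post-processing (valve-plane placement, axis orientation, motion
correction, extracardiac activity) propagates into flow estimates — without
access to patient images.

## The two models

Both work from the left-ventricular blood-pool curve `C_b(t)` and the 17
AHA segment curves `C_s(t)`, frame-averaged on the 23-frame dynamic
schedule (15 × 6 s, 4 × 30 s, 4 × 60 s; 450 s).

**Net retention (RET)** — uptake as the late-window myocardial mean with a
single global blood-spillover correction β, normalised by the early blood
integral:

    R_s = ( mean C_s[T1,T2] − β · mean C_b[T1,T2] ) / ∫₀^T0 C_b dt

with defaults β = 0.15, T0 = T1 = 210 s, T2 = 450 s.

**One-tissue compartment (1CM)** — per-segment bounded nonlinear least
squares of

    C_s(t) = (1 − f_v) · K1 · ∫₀ᵗ e^(−k2 (t−u)) C_b(u) du + f_v · C_b(t)

over K1 ∈ [0,5] ml/min/g, k2 ∈ [0,5] /min, f_v ∈ [0,1], with
duration-proportional weights, an analytic Jacobian and three fixed starts
(deterministic).

Uptake converts to flow through a Renkin–Crone extraction model
`u = MBF·(1 − e^(−PS/MBF))` (PS = 1 ml/min/g by default, invertible by
bisection); MFR is the segment-wise stress/rest ratio, aggregated to the
LAD/LCx/RCA territories and the whole myocardium (TOT).

On top of the estimators sit a synthetic cohort generator (gamma-variate
bolus input with pre-injection background, one-tissue forward simulation,
Poisson-surrogate noise, inferior scar in 44% of patients, bolus quality
control), a seeded simulated-operator perturbation model, and the
repeatability statistics used in inter-observer studies: Spearman rank
correlation, Bland–Altman limits of agreement, SD of percentage
difference, paired t and F tests, and Fisher-z comparisons of correlations
(independent and dependent). See `vignettes/methods.Rmd` for the full
model and design account.

## Worked example

```r
library(mfrkit)

# one synthetic patient: rest + stress studies with known kinetics
pair <- simulate_patient(population_config(), patient_id = "pat001", seed = 42)
fr  <- compute_flow(pair$rest,   "ret")   # net retention model
fs  <- compute_flow(pair$stress, "ret")
mfr <- compute_mfr(fs, fr)
mfr
#> <mfr_result> model RET
#> # A tibble: 4 × 3
#>   region   mfr n_used
#>   <chr>  <dbl>  <int>
#> 1 LAD     1.41      7
#> 2 LCx     1.35      5
#> 3 RCA     1.39      5
#> 4 TOT     1.39     17
```

The territory rows are weighted means of segment MFRs; `n_used` counts
segments surviving the low-rest-flow exclusion. This patient's true
simulated reserve is 1.61: the retention model's late-window washout bias,
compressed further by the steep extraction inversion, underestimates it —
the accuracy/repeatability trade-off the vignette discusses (the
compartment fit recovers 1.58 for the same patient). Comparing two correlation coefficients from
independent groups (n = 57 and n = 50):

```r
fisher_z_independent(0.954, 57, 0.942, 50)
#> # A tibble: 1 × 2
#>       z     p
#>   <dbl> <dbl>
#> 1 0.596 0.551
```

The full experiment — 200 simulated patients, two operators (one
processing every study twice), both models, inter- and intra-operator
reports:

```r
res <- run_repeatability_experiment(experiment_config(seed = 1))
res
#> <experiment_result> 200 simulated, 13 excluded, seed 1
#> # A tibble: 8 × 5
#>   model region r_spearman mean_diff sd_diff
#>   ...
autoplot(res)                    # Spearman r by model and territory
render_report(res, "report/")    # markdown + JSON twin
```

In the default configuration the retention model's inter-operator MFR
correlations (≈ 0.93–0.95 per territory) exceed the compartment model's
(≈ 0.80–0.89), with the compartment model weakest in the RCA territory —
the pattern reported for clinical dynamic SPECT.

A thin command-line wrapper over the same functions is installed at
`inst/cli/mfrkit.R` (subcommands `simulate`, `fit`, `compare-r`,
`repeatability`).

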