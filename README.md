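# musselpatch

Density-dependent cooperation and competition in seasonal blue-mussel
(*Mytilus edulis*) cage experiments.

Semi-sessile mussels aggregate into patches: dense packing protects
against dislodgement and burial (facilitation) but intensifies
competition for food. Whether grouping helps or hurts depends on the
season — food, temperature and hydrodynamic stress all cycle through
the year. `musselpatch` implements the statistical machinery for a
classic design probing this balance: ~30-day cage deployments at ten
biomass densities (1–19 kg m⁻², in triplicate, 0.09 m² plots), repeated
seven times across a year under continuously logged temperature,
chlorophyll-a and turbidity, with survival, condition and patch shape
as responses. It also ships a fully seeded synthetic-data generator
emulating that design, so every stage is testable end to end without
any field data.

## What the package computes

**Survival standardization.** Runs differ in length, so survival is
standardized to a 22-day horizon assuming a constant daily death rate
`(N₀ − N₁)/days`; standardized binomial failures `rate × 22` may be
non-integer and are left unrounded. End counts exceeding start counts
(counting errors; cages are closed) are clamped and flagged.

**Model 1 — survival.** Quasi-binomial GLM with logit link, fitted by
the package's own IRLS on the (possibly non-integer) standardized
counts with prior weights N₀:

```
logit(p) = β₀ + β_D·D₀ + β_T·Temp + β_C·Chl + β_U·Turb
         + β_TC·Temp:Chl + β_TU·Temp:Turb + β_CU·Chl:Turb
```

with Pearson dispersion φ, t-based inference on n − p df, and Holm
correction per model.

**Models 2 & 3 — patch shape and condition.** Linear models for
ln(PtoA) and ln(CI) (CI = AFDW/L³, mg cm⁻³; PtoA = patch circumference
/ patch area, aggregated per cage) with main effects only and
heteroskedasticity-robust sandwich standard errors (HC0–HC3, HC3
default). Model 3 uses a temperature-direction factor ("0" high and
stable = reference, "+" rising, "−" falling).

**Slope statistics.** Per run, the log-log OLS slope
`ln D_end = M·ln D₀ + b` (neutral at 1: above 1 means survival odds
rise with density — cooperation; below 1, competition) and
`ln CI = M·ln D₀ + b` (neutral at 0), each with a t-test against the
neutral value, plus a seasonal profile with a concavity (bell-shape)
indicator.

**Patch morphometry.** 8-connected labeling of binary cover masks,
calibrated areas (15.3 cm reference object) and a subpixel smoothed-
contour perimeter estimator accurate to ~3% on analytic shapes.

**Synthetic data.** Seasonal environment series (harmonic temperature
cycle with a late-winter cold-spell anomaly, spring chlorophyll bloom,
winter turbidity storms), beta-binomial overdispersed cage survival
(φ = 1 + (N−1)ρ, default calibrated to φ = 17.37), log-linear condition
and patch-shape draws, and rasterized clump masks. Everything is a pure
function of (config, seed).

## Worked example

```r
library(musselpatch)
cfg <- sim_config()                     # the full 7-run seasonal design
env <- gen_environment(cfg, seed = 42)
rec <- derive_survival(gen_cage_experiment(cfg, env, seed = 43))
fit_survival_model(rec)
```

```
Quasi-binomial GLM (logit), dispersion phi = 19.13, converged in 5 iter.
        Term  Estimate Std.error   p.value    p.holm
 (Intercept) 13.324976  1.976081 1.594e-10 6.374e-10
          D0 -0.000735  0.007271 9.196e-01 1.000e+00
        Temp -0.532957  0.077122 6.178e-11 3.089e-10
         Chl -8.643723  0.887609 1.285e-18 7.710e-18
        Turb  0.196043  0.384588 6.108e-01 1.000e+00
    Temp:Chl  0.564893  0.047976 1.046e-24 7.322e-24
   Temp:Turb -0.166106  0.011590 1.323e-32 1.059e-31
    Chl:Turb  0.311108  0.166248 6.274e-02 1.882e-01
```

The dispersion (≈19) flags strong within-cage overdispersion; the
environmental main effects and interactions dominate. Per-run slopes
then reveal the seasonal pattern the pooled density coefficient hides:

```r
slopes <- do.call(rbind, lapply(1:7, function(id)
  survival_slope(rec[rec$run_id == id, ])))
slopes[, c("run_id", "M", "se_M", "n", "classification")]
```

```
  run_id      M   se_M  n classification
1      1  1.029 0.2579 22        neutral
2      2  1.237 0.1251 30        neutral
3      3  1.487 0.0874 30    cooperative
4      4  1.489 0.1144 30    cooperative
5      5  1.133 0.0471 30    cooperative
6      6  0.960 0.0360 30        neutral
7      7 -0.294 0.3835 18    competitive
```

```r
seasonal_profile(slopes, cfg$runs)$concavity
#> [1] -0.1207
```

Slopes rise above 1 toward midsummer (density-dependent facilitation of
survival), fall back through autumn, and drop below 1 in the coldest
run (competition); the negative concavity quantifies the bell shape.
The full pipeline — simulation, metrics, masks, three model tables,
slope profiles, plots, manifest — runs with
`run_pipeline(cfg, seed = 42, out_dir = "out")`.

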