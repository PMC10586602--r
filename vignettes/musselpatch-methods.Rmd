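---
title: "Models and methods behind musselpatch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind musselpatch}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`musselpatch` analyses density-dependent cooperation and competition in
patches of blue mussels (*Mytilus edulis*) across a seasonal cycle, and
ships a seeded generator that emulates the field design the analysis was
built for: seven roughly month-long cage deployments spread over one
year, each with ten biomass densities (1-19 kg m^-2^) in triplicate on
0.09 m^2^ plots, under continuously logged temperature, chlorophyll-a
and turbidity. This vignette documents the models, the generator's
assumptions, the numerical choices, and what the synthetic data can and
cannot tell you about real experiments.

## Responses and their models

**Survival.** Each cage starts with `N0` mussels (derived from the
biomass treatment and the mean individual weight of a start subsample,
rounded to the nearest individual) and ends with `N1`. Because cage
retrieval dates shift with weather and tides, runs differ in length;
survival is standardized to a common 22-day horizon under a
constant-death-rate assumption:

- daily death rate = (N0 − N1) / days,
- binomial failures = daily death rate × 22,
- binomial successes = N0 − failures, p = successes / N0.

Failures may be non-integer and are deliberately left unrounded — the
quasi-binomial estimating equations only involve means and weights, so
non-integer "counts" are legitimate there. Standardized counts feed
**Model 1**, a quasi-binomial GLM with logit link:

logit(p) = β₀ + β_D D₀ + β_T Temp + β_C Chl + β_U Turb
        + β_TC Temp·Chl + β_TU Temp·Turb + β_CU Chl·Turb,

with prior weights N0 and Pearson-based dispersion φ. Environmental
covariates are run-window means, so they are run-level: the seven runs
exactly identify the seven run-level terms, and the density term is the
only within-run regressor. With fewer than seven runs the design is
rank deficient, which the engine reports by naming the collinear terms.

**Clamping.** Closed cages admit no recruitment, so an end count above
the start count is a counting error; `N1` is clamped to `N0` and
flagged. Clamping is applied *before* standardization — a negative
death count would otherwise produce negative failures and break the
binomial contract. If a short, lethal run extrapolates to more failures
than `N0`, failures are clipped to `N0` with a warning so p stays in
[0, 1].

**Condition.** The condition index CI = AFDW / L³ (mg cm^-3^) is an
instantaneous proxy for growth. **Model 3** is a linear model for
ln CI with main effects D₀, chlorophyll-a, turbidity and *temperature
direction*, a three-level factor ("0" = high and stable, the reference;
"+" rising; "−" falling; "low and stable" never occurs in this design).
The direction rule compares the mean of the first quarter of the run
window with the mean of the last quarter against a ±1.5 °C dead band.
The field definition of "direction" is verbal; the quarter comparison
and the 1.5 °C threshold are this package's operationalization and both
are configurable.

**Patch shape.** Binary cover masks yield the perimeter-to-area ratio
PtoA = total circumference / total covered area, aggregated over all
patches of a cage (one value per cage, not a per-patch average).
**Model 2** is a linear model for ln PtoA with main effects D₀, Temp,
Chl and Turb. A note on units: the fitted intercept of about 3.8 on the
log scale only makes sense if PtoA is expressed per metre (e^3.8 ≈ 46
m^-1^ ≈ 0.05 mm^-1^, i.e. 2 m of edge per 0.045 m² of cover), so the
model operates on PtoA in m^-1^; `patch_metrics()` reports both mm^-1^
and m^-1^.

Models 2 and 3 contain no interactions: with run-level covariates and
seven runs, interactions are collinear. Both are ratio responses with
multiplicative errors and expected heteroskedasticity, so inference
uses heteroskedasticity-consistent sandwich covariances; HC3 is the
default (the most conservative of HC0-HC3, discounting high-leverage
rows), and the variant is configurable. Within each model, p-values are
Holm-adjusted across that model's coefficients; the family is per model
because each model answers a separate question.

## Slope statistics

The strength and direction of density dependence per run is the OLS
slope of a log-log regression pooled over all 30 cages of the run:

- M_survival: ln D_end on ln D₀, neutral at 1. Proportional survival
  gives D_end ∝ D₀ and a slope of exactly 1; M > 1 means survival odds
  rise with density (facilitation), M < 1 the opposite. Because the
  regression is log-log, a multiplicative unit change (kg m^-2^ versus
  individuals m^-2^) shifts only the intercept, so both axes are kept
  in density units.
- M_CI: ln CI on ln D₀, neutral at 0; negative values mean condition
  falls with density (competition for food).

Classification uses a two-sided t-test of M against its neutral value
at α = 0.05 (configurable); the plotted-±SE convention of the original
figures names no test, so the t-test is this package's choice, with
plain OLS standard errors. Cages with zero end density are excluded
with a warning (their log is undefined); a run with fewer than three
usable condition values is reported as "unavailable" rather than an
error, so a seasonal profile can be assembled around a missing run.
`seasonal_profile()` orders runs by start date and summarizes curvature
by the quadratic coefficient of M against run index — negative
curvature is the "bell shape" (interactions strengthening towards
summer). That indicator is an operationalization of a qualitative
claim, not a published statistic.

## The synthetic-data generator

The generator's defaults are the study conditions; they are set once
and are not tuning knobs.

**Environment.** One series per channel at 10-minute resolution over
396 days (1 March to 31 March of the following year). Temperature is a
three-harmonic seasonal cycle (fundamental amplitude 6.1 °C; annual
span about 21 °C, matching the reported ~20 °C summer-winter contrast)
plus AR(1) noise. A single periodic sinusoid cannot reproduce the
observed design: the first run (March, year 1) and the last run
(February-March, year 2) overlap in calendar position yet differ by
6.6 °C, because the study's final deployment coincided with an
exceptional late-winter cold wave. The default therefore adds a
Gaussian cold-spell anomaly (depth ~10.6 °C, width ~13 days) centred in
late February of year 2 — which is what the region actually
experienced. Chlorophyll-a follows a periodic anchor curve with a
spring bloom (plus an early-bloom anomaly in year 2) and turbidity a
periodic baseline plus Poisson-timed storm pulses (rate 0.18 day^-1^
inside the 15 Oct - 31 Mar storm season, exponential peak amplitudes of
mean 5 FTU decaying over ~0.6 days) and a late-winter storm anomaly in
year 2. All anchor values and amplitudes were calibrated once so that
noise-free run-window means reproduce the reported per-run seasonal
means; the test suite checks generated window means against three times
the reported 95% CIs. Setting the higher harmonics, anomalies and noise
to zero recovers a pure sinusoid exactly, which the tests exploit.

**Survival draws.** The 22-day survival probability p\* is the inverse
logit of Model 1's linear predictor evaluated at the cage's density and
its run's generated window means. The reported dispersion of 17.37
states *that* counts are overdispersed but not *how*; the generator
uses beta-binomial failures with pairwise within-cage correlation ρ
because at common cage size N this reproduces the quasi-binomial
mean-variance relation exactly, with φ = 1 + (N − 1)ρ. The default ρ
(≈ 0.046) is calibrated so φ = 17.37 at the design's mean cage size;
this is an assumption, as no within-cage covariance information beyond
the global dispersion exists. The 22-day draw is rescaled to the run's
actual duration (constant death rate, rounded to the nearest count,
capped at N0) — counts must be integers at generation time even though
the analysis side accepts non-integers. Re-standardizing recovers the
22-day draw to within the rounding half-step. End density is
bookkept from count attrition only (D₁ = D₀·N1/N0); individual weight
change is not simulated because the survival model and slope analyses
need density bookkeeping, not growth in weight. With a small
probability (default 0.02) a cage's end count is replaced by an
overcount a few individuals past N0, exercising the clamping rule.

**The density-season interaction.** A single positive density
coefficient cannot produce the observed seasonal slope pattern — a
summer peak above 1 *and* a winter value below 1 — because a constant
positive β_D forces M > 1 in every run. The generator therefore adds
γ·D₀·(Temp_run − 13.37 °C) to the linear predictor. The default
γ = 0.008 was fixed once so that per-run mean slopes span roughly 0.6
(coldest run) to 1.4 (midsummer), the qualitative amplitude of the
reported seasonal profile. Refitting Model 1 (which omits this term) to
such data then redistributes the density effect into the environmental
terms, just as a real misspecified-but-useful field model would.
Parameter-recovery studies (`recover_model1()`) set γ = 0 and the
counting-error rate to 0, so generator truth and fitted model coincide;
unbiasedness of the recovery was verified at 500 replicates.

**Condition and patch shape.** Per-cage CI and PtoA are drawn from
exactly the log-linear laws of Models 3 and 2 with the reported
coefficients as defaults and lognormal residuals (default log-SDs 0.2
and 0.25; no residual scales accompany the design summaries, so these
are chosen to give realistic coefficients of variation of roughly
20-25%). Masks are
phenomenological: circular clumps whose count and radius grow with
density, so clumps coalesce and measured PtoA falls with density; a
mask can also be built to approximate a drawn PtoA value via the disc
relation r = 2/PtoA. Masks reproduce the geometry the morphometry
consumes, not mussel movement.

## Patch morphometry numerics

Area is foreground pixel count times the calibrated scale squared
(scale from a 15.3 cm reference object). Connectivity is 8-connected —
diagonal pixel contact is physical contact — and configurable.
Perimeter estimation is the one place where naive counting fails badly:
pixel-edge counting overestimates smooth boundaries by up to ~27%, and
an unweighted 4-direction line-intercept estimate underestimates
axis-aligned squares by ~6%. The package instead measures the length of
the subpixel boundary polygon (the 0.5-level contour of the padded
mask) after lightly smoothing each closed loop with a circular moving
average (window 3). Measured error is within about 3% for squares with
sides ≥ 32 px and discs with radii ≥ 20 px; the documented tolerance is
5%, and the suite asserts the closed forms 4/s and 2/r at those sizes.
Duplicating a mask far apart changes neither PtoA (both P and A double)
nor, to machine precision, the estimator's output. Interior hole
boundaries count toward the circumference by default (whether the
original hand-traced "circumference" included holes is unstated; a flag
excludes them).

## GLM engine numerics

The quasi-binomial fit is iteratively reweighted least squares with
working response and weights derived from the logit link, started from
the link-transformed adjusted response, converged when the largest
coefficient change falls below 1e-8 (cap 100 iterations;
non-convergence returns a flagged fit with a warning). Fitted means are
clamped away from 0/1 by 1e-10 for numerical safety. Dispersion is the
Pearson statistic over n − p; standard errors are model-based times
√φ; p-values use the t-distribution on n − p df, matching the
convention of standard quasi-binomial software. The engine is verified
against an independent direct maximization of the binomial
log-likelihood (agreement to 1e-6 on all fixtures up to 50 rows) and
against the stock GLM implementation. The sandwich covariance is
verified against a fully hand-computed three-point case and the
reference implementation for all HC variants; a simulation with
variance proportional to x² confirms that HC3 intervals hold ~95%
coverage where model-based intervals undercover.

## Problem sizes and determinism

Every generator is a pure function of (config, seed); the pipeline
derives per-stage child seeds from one global seed, and an
analysis-only rerun refits from the written cage table so its outputs
are byte-identical to the full run. The study sizes used by the checks:
parameter recovery averages 100 simulated years (21 000 cages);
dispersion recovery 100 replicates of 210 cages at N = 521; the
seasonal-profile study 100 years; mask monotonicity 50 seeded masks per
density; the robust-coverage simulation 2000 replicates of 40 rows.
These sizes keep Monte-Carlo error a small fraction of each check's
tolerance.

## Limitations

The generator emulates marginal seasonal structure and within-cage
overdispersion, not everything a field year contains: no spatial
correlation between neighbouring cages, no predation or recruitment
(the cages excluded both), no growth-in-weight or shell-growth model,
no food-quality effects, and masks are not produced by a behavioural
aggregation model. Passing recovery tests therefore demonstrates that
the estimators are correct for the stated data-generating mechanisms —
not that those mechanisms exhaust real mussel beds. The 22-day horizon
is kept as a parameter (`horizon_days`) rather than a constant, since
its only stated motivation is mathematical consistency across runs.
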