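test_that("generators are pure functions of (config, seed)", {
  cfg <- small_config()
  e1 <- gen_environment(cfg, seed = 7)
  e2 <- gen_environment(cfg, seed = 7)
  e3 <- gen_environment(cfg, seed = 8)
  expect_identical(e1, e2)
  expect_false(identical(e1$temperature_C, e3$temperature_C))
  r1 <- gen_cage_experiment(cfg, e1, seed = 9)
  r2 <- gen_cage_experiment(cfg, e1, seed = 9)
  expect_identical(r1, r2)
  m1 <- gen_patch_mask(9, cfg$mask, seed = 5)
  m2 <- gen_patch_mask(9, cfg$mask, seed = 5)
  expect_identical(m1, m2)
})

test_that("noise-free temperature equals the configured sinusoid", {
  cfg <- sim_config(environment = pure_sinusoid_env())
  env <- gen_environment(cfg, seed = 1)
  p <- cfg$environment
  doy <- (env$day + 59) %% 365.25 + 1
  expected <- p$temp_mean +
    p$temp_amplitude * cos(2 * pi * (doy - p$temp_peak_doy) / 365.25)
  expect_equal(env$temperature_C, expected, tolerance = 1e-12)
  # seasonal range equals twice the configured amplitude
  expect_equal(max(env$temperature_C) - min(env$temperature_C),
               2 * p$temp_amplitude, tolerance = 1e-3)
})

test_that("seasonal contrasts have the right sign", {
  cfg <- sim_config(environment = env_params(interval_min = 60))
  env <- gen_environment(cfg, seed = 12)
  # mid-summer (around day 150, late July) vs mid-winter (around day 300)
  summer <- env_window(env, 140, 30)
  winter <- env_window(env, 290, 30)
  expect_gt(mean(summer$temperature_C), mean(winter$temperature_C))
  # winter half-year is more turbid than the summer half-year
  half1 <- env$day >= 60 & env$day < 215     # May-Oct
  half2 <- env$day >= 245 & env$day < 365    # Nov-Feb
  expect_gt(mean(env$turbidity_FTU[half2]), mean(env$turbidity_FTU[half1]))
  expect_true(all(env$chlorophyll_ug_l >= 0))
  expect_true(all(env$turbidity_FTU >= 0))
  expect_error(gen_environment(sim_config(
    environment = env_params(interval_min = -5))),
    class = "musselpatch_config_error")
})

test_that("run-window means stay inside the seasonal envelope", {
  # 3x the observed 95% CIs of the per-run means (loose plausibility check)
  tab <- data.frame(
    Temp = c(8.89, 11.63, 19.08, 19.56, 15.51, 8.59, 2.30),
    Temp_ci = c(0.55, 0.31, 0.44, 0.10, 0.26, 0.59, 0.46),
    Chl = c(1.73, 2.96, 1.79, 2.46, 1.70, 1.08, 2.15),
    Chl_ci = c(0.09, 0.55, 0.14, 0.12, 0.11, 0.05, 0.46),
    Turb = c(3.57, 1.63, 2.57, 3.43, 1.97, 3.64, 7.64),
    Turb_ci = c(0.72, 0.32, 0.70, 0.20, 0.17, 0.87, 2.61))
  cfg <- sim_config(environment = env_params(interval_min = 60))
  for (seed in c(4, 99)) {
    cov <- run_covariates(gen_environment(cfg, seed = seed), cfg$runs)
    expect_true(all(abs(cov$Temp - tab$Temp) <= 3 * tab$Temp_ci))
    expect_true(all(abs(cov$Chl - tab$Chl) <= 3 * tab$Chl_ci))
    expect_true(all(abs(cov$Turb - tab$Turb) <= 3 * tab$Turb_ci))
  }
})

test_that("cage survival probabilities follow the linear predictor", {
  # constant environment pinned at the warm-run covariates; independent
  # scalar arithmetic for D0 = 10 (spelled out, not via a design matrix)
  env <- constant_env(19.56, 2.46, 3.43)
  eta <- 15.44 + 0.034 * 10 - 0.68 * 19.56 - 9.12 * 2.46 - 0.10 * 3.43 +
    0.58 * 19.56 * 2.46 - 0.16 * 19.56 * 3.43 + 0.42 * 2.46 * 3.43
  cfg <- sim_config(densities_kg_m2 = c(5, 10), density_season_coeff = 0)
  rec <- gen_cage_experiment(cfg, env, seed = 3)
  p10 <- rec$p22_true[rec$D0 == 10]
  expect_equal(p10, rep(plogis(eta), length(p10)), tolerance = 1e-9)
  # a broken predictor names the offending cage
  cfg_bad <- sim_config(survival_coeffs = c(
    `(Intercept)` = Inf, D0 = 0.034, Temp = -0.68, Chl = -9.12,
    Turb = -0.10, `Temp:Chl` = 0.58, `Temp:Turb` = -0.16, `Chl:Turb` = 0.42))
  expect_error(gen_cage_experiment(cfg_bad, env, seed = 3), "run 1")
})

test_that("no deaths occur when survival is forced to one", {
  env <- constant_env(10, 2, 3)
  cfg <- sim_config(
    survival_coeffs = c(`(Intercept)` = 50, D0 = 0, Temp = 0, Chl = 0,
                        Turb = 0, `Temp:Chl` = 0, `Temp:Turb` = 0,
                        `Chl:Turb` = 0),
    density_season_coeff = 0, count_error_rate = 0,
    intracage_correlation = 0)
  rec <- gen_cage_experiment(cfg, env, seed = 11)
  expect_true(all(rec$N1 == rec$N0))
  expect_true(all(rec$D1 == rec$D0))
})

test_that("beta-binomial draws match the binomial mean law and dispersion", {
  set.seed(1)
  # rho = 0: empirical mean within 3 Monte-Carlo SEs of the true mean
  n <- 50000; N <- 200; p_surv <- 0.65
  f <- rbetabinom(n, N, 1 - p_surv, 0)
  mc_se <- sqrt((1 - p_surv) * p_surv / (N * n))
  expect_lt(abs(mean(f / N) - (1 - p_surv)), 3 * mc_se)
  # rho > 0: Pearson dispersion within 10% of 1 + (N-1) rho
  rho <- 0.03
  f2 <- rbetabinom(10000, N, 0.3, rho)
  y <- f2 / N
  phi <- mean((y - mean(y))^2 * N / (mean(y) * (1 - mean(y))))
  expect_lt(abs(phi / (1 + (N - 1) * rho) - 1), 0.10)
})

test_that("duration rescaling round-trips the 22-day draw", {
  cfg <- small_config(count_error_rate = 0)
  env <- gen_environment(cfg, seed = 2)
  rec <- gen_cage_experiment(cfg, env, seed = 3)
  der <- derive_survival(rec)
  # re-standardizing recovers the generator's 22-day failures to within
  # the rounding half-step (scaled by 22/days), hence always within 0.5
  # for runs of 22+ days
  err <- abs(der$failures - rec$failures22_draw)
  tol <- 0.5 * 22 / rec$duration_days + 1e-9
  expect_true(all(err[!der$clipped & rec$N1 > 0] <=
                    tol[!der$clipped & rec$N1 > 0]))
})

test_that("counting errors occasionally push N1 above N0", {
  cfg <- small_config(count_error_rate = 0.5)
  env <- gen_environment(cfg, seed = 2)
  rec <- gen_cage_experiment(cfg, env, seed = 13)
  expect_gt(sum(rec$N1 > rec$N0), 0)
  der <- derive_survival(rec)
  expect_true(all(der$N1_clamped <= der$N0))
  expect_true(all(der$p <= 1 & der$p >= 0))
})

test_that("condition generator matches its log-linear law", {
  cfg <- small_config(ci_log_sd = 0)
  env <- gen_environment(cfg, seed = 2)
  rec <- gen_cage_experiment(cfg, env, seed = 3)
  # zero-noise, intercept-only: CI is exactly e^intercept
  cfg0 <- small_config(ci_log_sd = 0, ci_coeffs = c(
    `(Intercept)` = 1.5, D0 = 0, `TempDir-` = 0, `TempDir+` = 0,
    Chl = 0, Turb = 0))
  ci0 <- gen_condition(cfg0, rec, seed = 4)$CI
  expect_equal(ci0, rep(exp(1.5), nrow(rec)), tolerance = 1e-12)
  # zero-noise with the default negative density coefficient: CI strictly
  # decreases in D0 within each run
  ci <- gen_condition(cfg, rec, seed = 4)
  for (id in unique(ci$run_id)) {
    sub <- ci[ci$run_id == id & ci$replicate == 1, ]
    expect_true(all(diff(sub$CI[order(sub$D0)]) < 0))
  }
  expect_true(all(ci$CI > 0))
  # lognormal moment check: sample SD of ln CI within 5% of ci_log_sd
  cfgs <- small_config(ci_log_sd = 0.3)
  one <- rec[rep(1, 10000), ]
  draws <- gen_condition(cfgs, one, seed = 5)$CI
  expect_lt(abs(sd(log(draws)) / 0.3 - 1), 0.05)
})

test_that("mask generator respects its contracts", {
  expect_true(!any(gen_patch_mask(0, mask_params(), seed = 1)))
  expect_error(gen_patch_mask(5, mask_params(dim_px = 8), seed = 1),
               class = "musselpatch_config_error")
  # forced single clump of radius r px: PtoA within 15% of the analytic
  # disc value 2 / (r * scale)
  for (r_px in c(20, 30)) {
    m <- gen_patch_mask(1, mask_params(), seed = 2, n_clumps = 1,
                        radius_px = r_px)
    pm <- patch_metrics(m, 2)
    expect_lt(abs(pm$ptoa / (2 / (r_px * 2)) - 1), 0.15)
  }
})
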