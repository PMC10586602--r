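power_law_records <- function(m, a = 1, run_id = 1,
                              D0 = rep(seq(1, 19, by = 2), each = 3)) {
  data.frame(run_id = run_id, D0 = D0, D1 = a * D0^m)
}

test_that("noiseless power laws are recovered exactly", {
  # proportional attrition: D1 = c D0 => slope exactly 1
  s <- survival_slope(power_law_records(1, a = 0.8))
  expect_equal(s$M, 1, tolerance = 1e-12)
  expect_equal(s$b, log(0.8), tolerance = 1e-12)
  # exact power law
  s2 <- survival_slope(power_law_records(1.2))
  expect_equal(s2$M, 1.2, tolerance = 1e-12)
  expect_equal(s2$threshold, 1)
  # condition slope: constant CI => M = 0, neutral
  rec <- data.frame(run_id = 2, D0 = seq(1, 19, 2), CI = 2.5)
  s3 <- ci_slope(rec)
  expect_equal(s3$M, 0, tolerance = 1e-12)
  expect_identical(s3$classification, "neutral")
  # CI = c D0^-0.3 => M = -0.3
  rec$CI <- 4 * rec$D0^-0.3
  s4 <- ci_slope(rec)
  expect_equal(s4$M, -0.3, tolerance = 1e-12)
  expect_equal(s4$threshold, 0)
})

test_that("slopes are invariant to a multiplicative unit change", {
  rec <- power_law_records(1.15)
  set.seed(20)
  rec$D1 <- rec$D1 * exp(rnorm(nrow(rec), 0, 0.1))
  s <- survival_slope(rec)
  rec2 <- rec; rec2$D0 <- rec2$D0 * 537.9  # e.g. kg m^-2 -> individuals m^-2
  s2 <- survival_slope(rec2)
  expect_equal(s2$M, s$M, tolerance = 1e-9)
  expect_false(isTRUE(all.equal(s2$b, s$b)))
  rec3 <- rec; rec3$D1 <- rec3$D1 * 537.9
  expect_equal(survival_slope(rec3)$M, s$M, tolerance = 1e-9)
})

test_that("degenerate inputs are handled as contracts say", {
  rec <- power_law_records(1)
  rec$D1[5] <- 0
  expect_warning(s <- survival_slope(rec), "zero end density")
  expect_equal(s$n, nrow(rec) - 1)
  expect_error(survival_slope(data.frame(run_id = c(1, 2), D0 = 1, D1 = 1)),
               "single run")
  expect_error(suppressWarnings(survival_slope(
    data.frame(run_id = 1, D0 = c(1, 3), D1 = c(1, 3)))), "at least 3")
  # a run without condition data is unavailable, not an error
  s2 <- ci_slope(data.frame(run_id = 2, D0 = c(1, 3, 5), CI = NA_real_))
  expect_identical(s2$classification, "unavailable")
  expect_true(is.na(s2$M))
})

test_that("classification tests the slope against its neutral value", {
  set.seed(21)
  D0 <- rep(seq(1, 19, 2), each = 3)
  # strongly super-linear, low noise: cooperative
  rec <- data.frame(run_id = 1, D0 = D0, D1 = D0^1.5 * exp(rnorm(30, 0, 0.05)))
  expect_identical(survival_slope(rec)$classification, "cooperative")
  # strongly sub-linear: competitive
  rec$D1 <- D0^0.5 * exp(rnorm(30, 0, 0.05))
  expect_identical(survival_slope(rec)$classification, "competitive")
  # huge noise: neutral
  rec$D1 <- D0 * exp(rnorm(30, 0, 3))
  expect_identical(survival_slope(rec)$classification, "neutral")
})

test_that("seasonal profile orders runs and measures concavity", {
  designs <- data.frame(run_id = 1:5, start_day = c(10, 50, 100, 150, 200))
  slopes <- do.call(rbind, lapply(1:5, function(i)
    survival_slope(power_law_records(c(0.9, 1.1, 1.3, 1.1, 0.9)[i],
                                     run_id = i))))
  prof <- seasonal_profile(slopes, designs)
  expect_lt(prof$concavity, 0)
  expect_equal(prof$peak_run_id, 3)
  expect_equal(prof$profile$run_id, 1:5)
  # shuffled input order must not matter
  prof2 <- seasonal_profile(slopes[c(3, 1, 5, 2, 4), ], designs)
  expect_equal(prof2$profile$run_id, 1:5)
  # monotone slopes: concavity indistinguishable from zero
  slopes_m <- do.call(rbind, lapply(1:5, function(i)
    survival_slope(power_law_records(0.8 + 0.1 * i, run_id = i))))
  prof3 <- seasonal_profile(slopes_m, designs)
  expect_lt(abs(prof3$concavity), 2e-2)
  expect_error(seasonal_profile(rbind(slopes, slopes[1, ]), designs),
               "duplicate")
})

test_that("slope sign agrees with the generating density coefficient", {
  # single warm run, 300 cages; the sign of (M - 1) must track the sign
  # of the generating D0 coefficient in nearly all replicates
  base <- c(`(Intercept)` = 15.44, D0 = 0, Temp = -0.68, Chl = -9.12,
            Turb = -0.10, `Temp:Chl` = 0.58, `Temp:Turb` = -0.16,
            `Chl:Turb` = 0.42)
  runs1 <- default_run_designs()[4, ]
  agree <- function(b_d0, reps = 20) {
    cf <- base; cf["D0"] <- b_d0
    cfg <- sim_config(runs = runs1, replicates = 30, survival_coeffs = cf,
                      density_season_coeff = 0, count_error_rate = 0,
                      environment = env_params(interval_min = 60))
    hits <- 0
    for (r in seq_len(reps)) {
      env <- gen_environment(cfg, seed = 300 + r)
      rec <- derive_survival(gen_cage_experiment(cfg, env, seed = 600 + r))
      M <- suppressWarnings(survival_slope(rec))$M
      hits <- hits + (sign(M - 1) == sign(b_d0))
    }
    hits / reps
  }
  expect_gte(agree(0.05), 0.95)
  expect_gte(agree(-0.05), 0.95)
})
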