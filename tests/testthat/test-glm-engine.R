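test_that("Holm adjustment steps down correctly", {
  expect_equal(holm_adjust(0.03), 0.03)
  expect_equal(holm_adjust(c(0.01, 0.02, 0.04)), c(0.03, 0.04, 0.04))
  expect_equal(holm_adjust(c(1, 1, 1)), c(1, 1, 1))
  expect_error(holm_adjust(c(0.5, 1.2)), "0, 1")
  # properties against the stock implementation on random vectors
  set.seed(8)
  for (i in 1:20) {
    p <- runif(sample(1:12, 1))
    h <- holm_adjust(p)
    expect_equal(h, p.adjust(p, method = "holm"))
    expect_true(all(h >= p))
    expect_true(all(h <= pmin(1, length(p) * p)))
    expect_true(all(diff(h[order(p)]) >= -1e-15))
  }
})

test_that("intercept-only quasi-binomial fit is the logit of the pooled rate", {
  d <- data.frame(successes = rep(80, 6), failures = rep(20, 6))
  fit <- fit_quasibinomial(cbind(successes, failures) ~ 1, d)
  expect_equal(unname(fit$coefficients), qlogis(0.8), tolerance = 1e-8)
  expect_true(fit$converged)
})

test_that("IRLS agrees with stats::glm and with direct likelihood maximization", {
  for (seed in c(2, 5, 9)) {
    d <- make_qb_data(30, seed)
    fit <- fit_quasibinomial(cbind(successes, failures) ~ x1 + x2, d)
    ref <- glm(cbind(successes, failures) ~ x1 + x2, data = d,
               family = quasibinomial())
    expect_equal(fit$coefficients, coef(ref), tolerance = 1e-7)
    expect_equal(fit$dispersion, summary(ref)$dispersion, tolerance = 1e-6)
    expect_equal(fit$se, coef(summary(ref))[, 2], tolerance = 1e-6,
                 ignore_attr = TRUE)
    expect_equal(fit$p_raw, coef(summary(ref))[, 4], tolerance = 1e-5,
                 ignore_attr = TRUE)
    # independent optimizer oracle on the binomial log-likelihood
    X <- cbind(1, d$x1, d$x2)
    expect_equal(unname(fit$coefficients),
                 oracle_binomial_mle(X, d$successes, d$failures),
                 tolerance = 1e-6)
  }
  # non-integer counts: scale all rows by 1.37 -> same coefficients,
  # dispersion scales with the counts (quasi-likelihood invariance)
  d <- make_qb_data(25, 3)
  fit1 <- fit_quasibinomial(cbind(successes, failures) ~ x1 + x2, d)
  d2 <- transform(d, successes = successes * 1.37, failures = failures * 1.37)
  fit2 <- fit_quasibinomial(cbind(successes, failures) ~ x1 + x2, d2)
  expect_equal(fit2$coefficients, fit1$coefficients, tolerance = 1e-7)
  expect_equal(fit2$dispersion, 1.37 * fit1$dispersion, tolerance = 1e-6)
})

test_that("dispersion is near one for pure binomial data", {
  d <- make_qb_data(800, 17, rho = 0)
  fit <- fit_quasibinomial(cbind(successes, failures) ~ x1 + x2, d)
  expect_lt(abs(fit$dispersion - 1), 0.10)
})

test_that("rank-deficient designs fail loudly with the collinear terms named", {
  d <- make_qb_data(20, 4)
  d$x3 <- 2 * d$x1
  expect_error(fit_quasibinomial(cbind(successes, failures) ~ x1 + x2 + x3, d),
               "x3")
  d$y <- exp(1 + d$x1)
  expect_error(fit_loglinear(y ~ x1 + x3, d), "collinear")
})

test_that("log-linear fit recovers exact log-linear data and matches lm", {
  set.seed(6)
  d <- data.frame(x = runif(40, 0, 5))
  d$y <- exp(1.7 - 0.42 * d$x)
  fit <- fit_loglinear(y ~ x, d)
  expect_equal(unname(fit$coefficients), c(1.7, -0.42), tolerance = 1e-12)
  # with noise: equality with lm on the log scale
  d$y2 <- d$y * exp(rnorm(40, 0, 0.3))
  fit2 <- fit_loglinear(y2 ~ x, d)
  ref <- lm(log(y2) ~ x, d)
  expect_equal(fit2$coefficients, coef(ref), tolerance = 1e-10)
  expect_equal(fit2$se, coef(summary(ref))[, 2], tolerance = 1e-10,
               ignore_attr = TRUE)
  # duplicating every row leaves coefficients unchanged and shrinks
  # model SEs by about sqrt(2)
  fit3 <- fit_loglinear(y2 ~ x, rbind(d, d))
  expect_equal(fit3$coefficients, fit2$coefficients, tolerance = 1e-10)
  expect_equal(unname(fit2$se / fit3$se), rep(sqrt(2), 2), tolerance = 0.03)
  expect_error(fit_loglinear(y3 ~ x, transform(d, y3 = y2 - 2)), "positive")
})

test_that("sandwich covariance matches the hand-computed 3-point case", {
  # y on x = 0, 1, 2: fit y = a + b x by OLS, then HC0 by direct arithmetic
  d <- data.frame(x = c(0, 1, 2), y = exp(c(1.0, 2.4, 2.6)))
  fit <- robust_se(fit_loglinear(y ~ x, d), variant = "HC0")
  # hand computation: beta = (7/6, 4/5)... do it explicitly
  X <- cbind(1, c(0, 1, 2))
  b <- solve(t(X) %*% X, t(X) %*% log(d$y))
  e <- drop(log(d$y) - X %*% b)
  meat <- t(X) %*% diag(e^2) %*% X
  vc <- solve(t(X) %*% X) %*% meat %*% solve(t(X) %*% X)
  expect_equal(unname(fit$se_robust), sqrt(diag(vc)), tolerance = 1e-12)
})

test_that("all HC variants agree with the sandwich package", {
  skip_if_not_installed("sandwich")
  set.seed(13)
  d <- data.frame(x = runif(35), z = rnorm(35))
  d$y <- exp(0.5 + 0.8 * d$x - 0.3 * d$z + rnorm(35, 0, 0.4 * (1 + d$x)))
  ref <- lm(log(y) ~ x + z, d)
  base <- fit_loglinear(y ~ x + z, d)
  for (v in c("HC0", "HC1", "HC2", "HC3")) {
    fit <- robust_se(base, variant = v)
    expect_equal(unname(fit$vcov),
                 unname(sandwich::vcovHC(ref, type = v)), tolerance = 1e-10)
  }
})

test_that("robust SEs approach model SEs under homoskedasticity", {
  set.seed(14)
  d <- data.frame(x = runif(4000))
  d$y <- exp(1 + 0.5 * d$x + rnorm(4000, 0, 0.3))
  fit <- robust_se(fit_loglinear(y ~ x, d))
  expect_true(all(abs(fit$se_robust / fit$se_model - 1) < 0.10))
})

test_that("robust intervals keep coverage under x-proportional variance", {
  set.seed(15)
  n <- 40; reps <- 2000; slope <- 0.6
  cover_rob <- cover_mod <- logical(reps)
  for (r in seq_len(reps)) {
    x <- runif(n, 0.2, 3)
    d <- data.frame(x = x, y = exp(1 + slope * x + rnorm(n, 0, 0.35 * x)))
    f <- fit_loglinear(y ~ x, d)
    tq <- qt(0.975, f$df_residual)
    cover_mod[r] <- abs(f$coefficients[2] - slope) <= tq * f$se_model[2]
    fr <- robust_se(f, variant = "HC3")
    cover_rob[r] <- abs(fr$coefficients[2] - slope) <= tq * fr$se_robust[2]
  }
  expect_gte(mean(cover_rob), 0.93)
  expect_lte(mean(cover_rob), 0.975)
  expect_lt(mean(cover_mod), mean(cover_rob))
})

test_that("leverage-one rows make HC2/HC3 weighting undefined", {
  d <- data.frame(x = c(0, 0, 0, 5), y = exp(c(1, 1.2, 0.9, 3)))
  fit <- fit_loglinear(y ~ x, d)
  expect_error(robust_se(fit, variant = "HC3"), "leverage")
  expect_silent(robust_se(fit, variant = "HC0"))
})

test_that("model wrappers expose the study's term structure", {
  # all seven runs are needed: the environmental terms are run-level, so
  # the survival design is only full-rank with the full seasonal design
  cfg <- sim_config(environment = env_params(interval_min = 60),
                    count_error_rate = 0)
  env <- gen_environment(cfg, seed = 2)
  rec <- derive_survival(gen_cage_experiment(cfg, env, seed = 3))
  rec <- gen_condition(cfg, rec, seed = 4)
  rec <- gen_ptoa(cfg, rec, seed = 5)
  f1 <- fit_survival_model(rec)
  expect_named(f1$coefficients,
               c("(Intercept)", "D0", "Temp", "Chl", "Turb", "Temp:Chl",
                 "Temp:Turb", "Chl:Turb"))
  expect_gt(f1$dispersion, 1)
  f2 <- fit_ptoa_model(rec)
  expect_named(f2$coefficients, c("(Intercept)", "D0", "Temp", "Chl", "Turb"))
  expect_identical(f2$robust_variant, "HC3")
  f3 <- fit_ci_model(rec)
  expect_named(f3$coefficients,
               c("(Intercept)", "D0", "TempDir-", "TempDir+", "Chl", "Turb"))
  ct <- coef_table(f3)
  expect_true(all(ct$p.holm >= ct$p.value - 1e-15))
})
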