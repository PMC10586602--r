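# Shared fixtures, all generated in code.

# Reduced design for fast pipeline-level tests: three runs spanning the
# seasons, three densities, two replicates, hourly environment sampling.
small_config <- function(replicates = 2, densities_kg_m2 = c(1, 9, 19),
                         environment = env_params(interval_min = 60), ...) {
  runs <- default_run_designs()[c(1, 4, 7), ]
  sim_config(runs = runs, densities_kg_m2 = densities_kg_m2,
             replicates = replicates, environment = environment, ...)
}

# Environment parameters in the deterministic limit: no noise, no storms,
# no harmonics beyond the fundamental, no year-2 anomalies. Temperature is
# then exactly the configured sinusoid.
pure_sinusoid_env <- function(...) {
  env_params(temp_noise_sd = 0, chl_noise_sd = 0, turb_noise_sd = 0,
             temp_harm2_amp = 0, temp_harm3_amp = 0, coldspell_depth_C = 0,
             storm_rate_per_day = 0, storm2_amp = 0, chl_bloom2_amp = 0,
             interval_min = 60, ...)
}

# Hand-made constant environment covering the default runs, for forcing
# exact covariate values.
constant_env <- function(temp, chl, turb, n_days = 396) {
  day <- seq(0, n_days, by = 1 / 24)
  env <- data.frame(
    timestamp = as.POSIXct("2017-03-01", tz = "UTC") + day * 86400,
    day = day, temperature_C = temp, chlorophyll_ug_l = chl,
    turbidity_FTU = turb)
  class(env) <- c("mussel_env", "data.frame")
  env
}

# Overdispersed grouped-binomial test data for the GLM engine.
make_qb_data <- function(n, seed, rho = 0, beta = c(0.5, -0.8, 0.3)) {
  set.seed(seed)
  x1 <- rnorm(n); x2 <- runif(n, -1, 1)
  N <- sample(20:120, n, replace = TRUE)
  p <- plogis(beta[1] + beta[2] * x1 + beta[3] * x2)
  f <- rbetabinom(n, N, 1 - p, rho)
  data.frame(x1 = x1, x2 = x2, successes = N - f, failures = f)
}

# Brute-force connected-component count by label propagation (independent
# of the package's BFS labeling): repeatedly replace each foreground
# pixel's label by the minimum over its neighbourhood until fixed point.
oracle_n_components <- function(mask, connectivity = 8) {
  fg <- which(mask != 0, arr.ind = TRUE)
  if (nrow(fg) == 0) return(0L)
  lab <- seq_len(nrow(fg))
  adj <- if (connectivity == 8) {
    function(i, j) max(abs(fg[i, ] - fg[j, ])) <= 1
  } else {
    function(i, j) sum(abs(fg[i, ] - fg[j, ])) <= 1
  }
  repeat {
    changed <- FALSE
    for (i in seq_len(nrow(fg))) for (j in seq_len(nrow(fg))) {
      if (i != j && adj(i, j) && lab[j] < lab[i]) {
        lab[i] <- lab[j]; changed <- TRUE
      }
    }
    if (!changed) break
  }
  length(unique(lab))
}

# Direct maximization of the binomial log-likelihood (up to constants) on
# the logit scale: the optimizer oracle for the IRLS fit.
oracle_binomial_mle <- function(X, successes, failures) {
  nll <- function(beta) {
    eta <- drop(X %*% beta)
    -sum(successes * stats::plogis(eta, log.p = TRUE) +
           failures * stats::plogis(-eta, log.p = TRUE))
  }
  stats::optim(rep(0, ncol(X)), nll, method = "BFGS",
               control = list(maxit = 1000, reltol = 1e-14))$par
}
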