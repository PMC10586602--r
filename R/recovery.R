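#' Parameter-recovery study for the survival model
#'
#' Simulates `n_reps` independent experimental years (7 runs x 10
#' densities x 3 replicates under the default design), each with its own
#' seeded environment, with the survival generator truth set exactly to
#' the reported survival coefficients (the density-by-temperature
#' interaction and the counting-error perturbation are switched off so
#' the generating model and the fitted model coincide), and refits the
#' quasi-binomial survival model to every simulated year after survival
#' standardization. The Monte-Carlo mean of each recovered coefficient
#' estimates the generating value; the Monte-Carlo standard error
#' quantifies the simulation noise of that mean.
#'
#' @param n_reps number of simulated years (default 100).
#' @param seed integer base seed; replicate r uses seeds derived from
#'   `seed + 1000 * r`.
#' @param config optional base [sim_config()]; its interaction and
#'   counting-error settings are overridden to 0 for the protocol.
#' @return A list: `coefficients` (n_reps x 8 matrix), `mean`, `mc_se`,
#'   `generating` (the true coefficient vector), `dispersion` (per-rep
#'   Pearson dispersion estimates), `n_cages_total`.
#' @export
recover_model1 <- function(n_reps = 100, seed = 1L, config = NULL) {
  if (is.null(config)) config <- sim_config()
  config$density_season_coeff <- 0
  config$count_error_rate <- 0
  validate_config(config)
  coefs <- matrix(NA_real_, n_reps, length(config$survival_coeffs))
  disp <- numeric(n_reps)
  n_cages <- 0L
  for (r in seq_len(n_reps)) {
    env <- gen_environment(config, seed = seed + 1000L * r)
    rec <- gen_cage_experiment(config, env, seed = seed + 1000L * r + 500L)
    rec <- derive_survival(rec)
    fit <- fit_survival_model(rec)
    coefs[r, ] <- fit$coefficients
    disp[r] <- fit$dispersion
    n_cages <- n_cages + nrow(rec)
  }
  colnames(coefs) <- names(config$survival_coeffs)
  list(coefficients = coefs,
       mean = colMeans(coefs),
       mc_se = apply(coefs, 2, stats::sd) / sqrt(n_reps),
       generating = config$survival_coeffs,
       dispersion = disp,
       n_cages_total = n_cages)
}

#' Pearson-dispersion recovery at common cage size
#'
#' Checks the dispersion estimator of the quasi-binomial engine against
#' the beta-binomial theory: with common cage size N and correlation
#' rho = (phi - 1)/(N - 1), the Pearson dispersion of simulated counts
#' should estimate phi. Each replicate draws `n_cages` beta-binomial
#' cages at a fixed survival probability and fits an intercept-only
#' quasi-binomial model.
#'
#' @param n_reps number of replicates (default 100).
#' @param n_cages cages per replicate (default 210, one experimental
#'   year).
#' @param size common cage size N (default 521, the design's mean
#'   nominal plot count).
#' @param prob survival probability (default 0.7).
#' @param phi target dispersion (default 17.37).
#' @param seed integer seed.
#' @return A list: `dispersion` (per-rep estimates), `mean`, `mc_se`,
#'   `target`, `rho`.
#' @export
dispersion_study <- function(n_reps = 100, n_cages = 210, size = 521,
                             prob = 0.7, phi = 17.37, seed = 1L) {
  rho <- rho_from_dispersion(phi, size)
  set.seed(seed)
  disp <- numeric(n_reps)
  for (r in seq_len(n_reps)) {
    f <- rbetabinom(n_cages, size, 1 - prob, rho)
    d <- data.frame(successes = size - f, failures = f)
    disp[r] <- fit_quasibinomial(cbind(successes, failures) ~ 1, d)$dispersion
  }
  list(dispersion = disp, mean = mean(disp),
       mc_se = stats::sd(disp) / sqrt(n_reps), target = phi, rho = rho)
}

#' Seasonal slope-profile study
#'
#' Simulates `n_reps` experimental years under the full generating model
#' (including the density-by-temperature interaction, which makes the
#' density effect on survival summer-peaking and negative in the coldest
#' run), computes the per-run survival slopes M and the seasonal
#' profile, and tabulates how often the profile is concave (negative
#' quadratic coefficient), peaks in a summer run, shows M > 1 in summer
#' and M < 1 in the coldest run.
#'
#' @param n_reps number of simulated years (default 100).
#' @param seed integer base seed.
#' @param config a [sim_config()]; the default has the interaction on.
#' @param summer_runs run ids counted as summer (default 3 and 4, the
#'   June and July-August deployments).
#' @param coldest_run run id of the coldest deployment (default 7).
#' @return A list with the per-rep slope matrix `M`, `concavity`,
#'   `peak_run`, and the summary fractions `frac_concave`,
#'   `frac_peak_summer`, `frac_summer_coop`, `frac_cold_comp`.
#' @export
seasonal_slope_study <- function(n_reps = 100, seed = 1L,
                                 config = sim_config(),
                                 summer_runs = c(3, 4), coldest_run = 7) {
  validate_config(config)
  run_ids <- config$runs$run_id
  M <- matrix(NA_real_, n_reps, length(run_ids),
              dimnames = list(NULL, as.character(run_ids)))
  concavity <- numeric(n_reps)
  peak_run <- vector(mode(run_ids), n_reps)
  for (r in seq_len(n_reps)) {
    env <- gen_environment(config, seed = seed + 1000L * r)
    rec <- gen_cage_experiment(config, env, seed = seed + 1000L * r + 500L)
    rec <- derive_survival(rec)
    slopes <- do.call(rbind, lapply(run_ids, function(id)
      survival_slope(rec[rec$run_id == id, ])))
    prof <- seasonal_profile(slopes, config$runs)
    M[r, ] <- slopes$M[match(run_ids, slopes$run_id)]
    concavity[r] <- prof$concavity
    peak_run[r] <- prof$peak_run_id
  }
  summer_max <- apply(M[, as.character(summer_runs), drop = FALSE], 1, max)
  list(M = M, concavity = concavity, peak_run = peak_run,
       frac_concave = mean(concavity < 0),
       frac_peak_summer = mean(peak_run %in% summer_runs),
       frac_summer_coop = mean(summer_max > 1),
       frac_cold_comp = mean(M[, as.character(coldest_run)] < 1))
}
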