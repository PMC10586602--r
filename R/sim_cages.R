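#' Beta-binomial random draws
#'
#' Draws counts from the beta-binomial distribution parameterized by the
#' mean probability `prob` and the pairwise correlation `rho`: each
#' count is Binomial(size, q) with q ~ Beta(prob * t, (1 - prob) * t),
#' t = (1 - rho) / rho. With cages of common size N this yields exactly
#' the quasi-binomial mean-variance relation with dispersion
#' 1 + (N - 1) rho; rho = 0 reduces to the pure binomial.
#'
#' @param n number of draws.
#' @param size binomial size(s).
#' @param prob mean success probability(ies).
#' @param rho pairwise correlation in [0, 1).
#' @return Integer vector of counts.
#' @export
rbetabinom <- function(n, size, prob, rho) {
  stopifnot(rho >= 0, rho < 1, all(prob >= 0), all(prob <= 1))
  if (rho == 0) return(stats::rbinom(n, size, prob))
  theta <- (1 - rho) / rho
  q <- stats::rbeta(n, prob * theta, (1 - prob) * theta)
  # rbeta returns NaN when a shape is 0 (prob exactly 0 or 1): degenerate
  q[prob == 0] <- 0
  q[prob == 1] <- 1
  stats::rbinom(n, size, q)
}

# Linear predictor of the 22-day survival model for one cage.
.survival_eta <- function(coefs, D0, Temp, Chl, Turb, gamma = 0, temp_ref = 0) {
  drop(cbind(1, D0, Temp, Chl, Turb, Temp * Chl, Temp * Turb, Chl * Turb) %*%
         coefs) + gamma * D0 * (Temp - temp_ref)
}

#' Simulate the seasonal cage experiment
#'
#' For every run x density x replicate cell: the start count N0 comes
#' from the biomass treatment and the run's mean individual weight
#' ([count_per_plot()]); the 22-day survival probability p* is the
#' inverse logit of the survival linear predictor (starting density,
#' run-window environmental means and their pairwise interactions, plus
#' the optional density-by-temperature term); 22-day failures are drawn
#' beta-binomially with correlation rho; failures are rescaled to the
#' run's actual duration under the constant-death-rate assumption
#' (round to nearest, capped at N0), giving the end count N1 and end
#' density D1 = D0 * N1 / N0. With probability `count_error_rate` the
#' end count is replaced by an overcount a few individuals past N0,
#' emulating the counting errors the downstream clamping rule exists
#' for. Identical
#' `(config, env, seed)` give identical records.
#'
#' @param config a [sim_config()] object.
#' @param env environment series from [gen_environment()]; must cover
#'   every run window.
#' @param seed integer RNG seed; defaults to `config$seed`.
#' @return A cage-record data.frame: `run_id`, `replicate`,
#'   `density_treatment`, `D0`, `D1`, `N0`, `N1`, `duration_days`,
#'   `total_weight_start_g`, `total_weight_end_g`, `temp_direction`,
#'   `Temp`, `Chl`, `Turb`, `p22_true`.
#' @export
gen_cage_experiment <- function(config, env, seed = config$seed) {
  validate_config(config)
  cov <- run_covariates(env, config$runs)
  set.seed(seed)
  runs <- config$runs
  cells <- expand.grid(replicate = seq_len(config$replicates),
                       density = config$densities_kg_m2,
                       run = seq_len(nrow(runs)))
  r <- cells$run; dens <- cells$density; n <- nrow(cells)
  N0 <- count_per_plot(dens, runs$mean_start_weight_g[r], config$plot_area_m2)
  eta <- .survival_eta(config$survival_coeffs, dens,
                       cov$Temp[r], cov$Chl[r], cov$Turb[r],
                       config$density_season_coeff, config$temp_ref_C)
  if (any(!is.finite(eta))) {
    i <- which(!is.finite(eta))[1]
    stop(sprintf(
      "non-finite survival linear predictor for run %s, density %g, replicate %d",
      runs$run_id[r[i]], dens[i], cells$replicate[i]))
  }
  p22 <- stats::plogis(eta)
  f22 <- rbetabinom(n, N0, 1 - p22, config$intracage_correlation)
  days <- runs$duration_days[r]
  fdur <- pmin(N0, round(f22 * days / 22))
  N1 <- N0 - fdur
  if (config$count_error_rate > 0) {
    # counting errors overshoot the start count by a few individuals, the
    # situation the clamping rule of the survival proportion exists for
    err <- stats::runif(n) < config$count_error_rate
    N1[err] <- N0[err] + 1L + stats::rpois(sum(err), 1.5)
  }
  w0 <- dens * config$plot_area_m2 * 1000
  data.frame(
    run_id = runs$run_id[r], replicate = cells$replicate,
    density_treatment = dens, D0 = dens, D1 = dens * N1 / N0,
    N0 = N0, N1 = as.integer(N1), duration_days = days,
    total_weight_start_g = w0, total_weight_end_g = w0 * N1 / N0,
    temp_direction = runs$temp_direction[r],
    Temp = cov$Temp[r], Chl = cov$Chl[r], Turb = cov$Turb[r],
    p22_true = p22, failures22_draw = f22, stringsAsFactors = FALSE)
}

#' Simulate per-cage condition indices
#'
#' Draws the condition index of each cage from the log-linear condition
#' model: ln CI = c0 + cD * D0 + c- 1{dir = -} + c+ 1{dir = +} +
#' cChl * Chl + cTurb * Turb + Normal(0, ci_log_sd). CI is therefore
#' always positive and, with the default negative density coefficient,
#' declines with starting density.
#'
#' @param config a [sim_config()] object.
#' @param records cage records from [gen_cage_experiment()].
#' @param seed integer RNG seed; defaults to `config$seed + 1`.
#' @return `records` with a `CI` column (mg cm^-3) appended.
#' @export
gen_condition <- function(config, records, seed = config$seed + 1L) {
  validate_config(config)
  set.seed(seed)
  b <- config$ci_coeffs
  mu <- b[1] + b[2] * records$D0 +
    b[3] * (records$temp_direction == "-") +
    b[4] * (records$temp_direction == "+") +
    b[5] * records$Chl + b[6] * records$Turb
  records$CI <- exp(mu + stats::rnorm(nrow(records), 0, config$ci_log_sd))
  records
}

#' Simulate per-cage perimeter-to-area ratios
#'
#' Draws each cage's perimeter-to-area ratio (m^-1) from the log-linear
#' patch-shape model: ln PtoA = b0 + bD * D0 + bT * Temp + bC * Chl +
#' bU * Turb + Normal(0, ptoa_log_sd). The default coefficients make
#' PtoA decline with density (patches coalesce) and rise with turbidity
#' (storms break patches up). [gen_patch_mask()] can rasterize a mask
#' whose geometry approximates a drawn value.
#'
#' @param config a [sim_config()] object.
#' @param records cage records.
#' @param seed integer RNG seed; defaults to `config$seed + 2`.
#' @return `records` with a `PtoA` column (m^-1) appended.
#' @export
gen_ptoa <- function(config, records, seed = config$seed + 2L) {
  validate_config(config)
  set.seed(seed)
  b <- config$ptoa_coeffs
  mu <- b[1] + b[2] * records$D0 + b[3] * records$Temp +
    b[4] * records$Chl + b[5] * records$Turb
  records$PtoA <- exp(mu + stats::rnorm(nrow(records), 0, config$ptoa_log_sd))
  records
}
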