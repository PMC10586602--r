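#' Experimental design of the seven seasonal runs
#'
#' Returns the default run designs: seven ~30-day cage deployments spread
#' over one year (March to the following March), each with its observed
#' start date, duration, mean individual start weight and the direction in
#' which water temperature moved over the run ("0" = high and stable,
#' "+" = rising, "-" = falling; "0" is the reference level and
#' "low and stable" never occurs in this design).
#'
#' @return A data.frame with columns `run_id`, `start_date`, `start_day`
#'   (days since the simulation origin, 1 March of the first year),
#'   `duration_days`, `mean_start_weight_g` and `temp_direction`.
#' @export
default_run_designs <- function() {
  data.frame(
    run_id = 1:7,
    start_date = as.Date(c(
      "2017-03-10", "2017-04-18", "2017-06-01", "2017-07-27",
      "2017-09-20", "2017-11-09", "2018-02-21")),
    start_day = c(9, 48, 92, 148, 203, 253, 357),
    duration_days = c(30, 26, 28, 32, 29, 32, 37),
    mean_start_weight_g = c(1.33, 3.35, 3.20, 3.46, 3.75, 4.95, 1.51),
    temp_direction = c("+", "+", "+", "0", "-", "-", "-"),
    stringsAsFactors = FALSE
  )
}

#' Default environment-generator parameters
#'
#' The annual cycle of the shallow subtidal study system: water temperature
#' as a seasonal harmonic series (annual span about 21 degrees C) with a
#' late-winter cold-spell anomaly in the second calendar year, chlorophyll-a
#' as a smooth annual curve with a spring bloom plus an early-bloom anomaly
#' in the second year, and turbidity as a smooth annual baseline plus
#' Poisson-timed storm pulses restricted to the winter half-year and a
#' late-winter storm anomaly. Noise on each channel is AR(1).
#'
#' Amplitudes, phases and anchor values were calibrated once so that
#' noise-free run-window means reproduce the observed per-run seasonal
#' means; see the methods vignette.
#'
#' @param ... named overrides of any default element.
#' @return A list of environment parameters.
#' @export
env_params <- function(...) {
  p <- list(
    interval_min = 10,
    n_days = 396,                      # 1 Mar year 1 .. 31 Mar year 2
    # temperature: mean + three cosine harmonics of the day-of-year
    temp_mean = 13.3747,
    temp_amplitude = 6.0995,          # fundamental; seasonal range = 2 * this
    temp_peak_doy = 207.516,
    temp_harm2_amp = 1.7504, temp_harm2_peak = 28.2534,
    temp_harm3_amp = -1.2346, temp_harm3_peak = 100.3304,
    # late-winter cold spell (year 2), Gaussian in simulation days
    coldspell_depth_C = 10.5797,
    coldspell_center_day = 365.9,
    coldspell_width_days = 13.3653,
    temp_noise_sd = 0.45, temp_noise_ar = 0.995,
    # chlorophyll-a: periodic anchor curve (day-of-year, ug/l)
    chl_anchor_doy = c(15, 46, 84, 121, 166, 224, 277, 329),
    chl_anchor_val = c(1.00, 1.30, 1.73, 3.10, 1.76, 2.47, 1.70, 1.05),
    chl_bloom2_amp = 0.883,           # early-bloom anomaly, year 2
    chl_bloom2_center_day = 374, chl_bloom2_width_days = 13,
    chl_noise_sd = 0.25, chl_noise_ar = 0.99,
    # turbidity: periodic anchor baseline + winter storms
    turb_anchor_doy = c(15, 84, 121, 166, 224, 277, 329),
    turb_anchor_val = c(3.30, 3.19, 1.58, 2.60, 3.47, 1.92, 3.10),
    storm_rate_per_day = 0.18,        # Poisson rate inside the storm season
    storm_season_doy = c(288, 90),    # 15 Oct .. 31 Mar (wraps over new year)
    storm_amp_mean_FTU = 5,           # exponential peak amplitude
    storm_decay_days = 0.6,
    storm2_amp = 5.189,               # late-winter storm anomaly, year 2
    storm2_center_day = 369, storm2_width_days = 13,
    turb_noise_sd = 0.30, turb_noise_ar = 0.98
  )
  override <- list(...)
  stopifnot(all(names(override) %in% names(p)))
  p[names(override)] <- override
  p
}

#' Default patch-mask generator parameters
#'
#' Masks emulate top-view binary mussel-cover images of the 0.3 x 0.3 m
#' seeded plot. Clump count and clump radius both grow with density, so
#' clumps increasingly coalesce and the perimeter-to-area ratio falls as
#' density rises.
#'
#' @param ... named overrides of any default element.
#' @return A list of mask parameters.
#' @export
mask_params <- function(...) {
  p <- list(
    dim_px = 150,
    scale_mm_per_px = 2,              # 150 px x 2 mm = 300 mm plot
    clump_base = 3, clump_per_density = 0.8,
    radius_base_mm = 12, radius_per_density_mm = 2.2,
    radius_cv = 0.25,
    margin_px = 8
  )
  override <- list(...)
  stopifnot(all(names(override) %in% names(p)))
  p[names(override)] <- override
  p
}

#' Simulation configuration for the seasonal cage experiment
#'
#' Bundles the experimental design (runs, treatment densities, replication,
#' plot area), the generating coefficients of the three response models
#' (22-day survival on the logit scale, log condition index, log
#' perimeter-to-area ratio), the within-cage overdispersion, and the
#' environment and mask generator parameters.
#'
#' Default coefficients are the fitted values reported for this design:
#' survival operates on the logit scale with terms (intercept, D0, Temp,
#' Chl-a, Turb, Temp:Chl, Temp:Turb, Chl:Turb) where D0 is the starting
#' density in kg m^-2 and the environmental terms are run-window means.
#' `density_season_coeff` adds an optional density-by-temperature
#' interaction, gamma * D0 * (Temp_run - temp_ref), which makes the
#' density effect summer-peaking and winter-negative as observed in the
#' per-run slope profiles; set it to 0 to simulate from the survival
#' model exactly.
#'
#' @param runs run design data.frame, see [default_run_designs()].
#' @param densities_kg_m2 strictly increasing positive treatment densities.
#' @param replicates cages per density per run.
#' @param plot_area_m2 seeded plot area (m^2).
#' @param survival_coeffs named numeric vector of length 8 (logit scale).
#' @param density_season_coeff density-by-temperature interaction
#'   (logit per kg m^-2 per degree C); 0 disables it.
#' @param temp_ref_C centring temperature for the interaction.
#' @param intracage_correlation beta-binomial pairwise correlation rho in
#'   [0, 1); the default is calibrated so that the Pearson dispersion at
#'   the design's mean cage size equals 17.37, see [rho_from_dispersion()].
#' @param ci_coeffs named numeric vector of length 6 for log condition
#'   index: (intercept, D0, TempDir-, TempDir+, Chl, Turb).
#' @param ci_log_sd residual SD of log CI.
#' @param ptoa_coeffs named numeric vector of length 5 for log
#'   perimeter-to-area ratio in m^-1: (intercept, D0, Temp, Chl, Turb).
#' @param ptoa_log_sd residual SD of log PtoA.
#' @param count_error_rate probability that an end count is overstated
#'   past the start count by a counting error, exercising the survival
#'   clamping rule.
#' @param environment list from [env_params()].
#' @param mask list from [mask_params()].
#' @param seed default integer seed used when generator functions are not
#'   given one explicitly.
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(runs = default_run_designs(),
                       densities_kg_m2 = seq(1, 19, by = 2),
                       replicates = 3,
                       plot_area_m2 = 0.09,
                       survival_coeffs = c(
                         `(Intercept)` = 15.44, D0 = 0.034, Temp = -0.68,
                         Chl = -9.12, Turb = -0.10, `Temp:Chl` = 0.58,
                         `Temp:Turb` = -0.16, `Chl:Turb` = 0.42),
                       density_season_coeff = 0.008,
                       temp_ref_C = 13.37,
                       intracage_correlation = NULL,
                       ci_coeffs = c(
                         `(Intercept)` = 1.82, D0 = -0.007,
                         `TempDir-` = -0.30, `TempDir+` = -0.33,
                         Chl = 0.12, Turb = -0.09),
                       ci_log_sd = 0.2,
                       ptoa_coeffs = c(
                         `(Intercept)` = 3.83, D0 = -0.02, Temp = 0.01,
                         Chl = -0.24, Turb = 0.19),
                       ptoa_log_sd = 0.25,
                       count_error_rate = 0.02,
                       environment = env_params(),
                       mask = mask_params(),
                       seed = 1L) {
  cfg <- list(
    runs = runs, densities_kg_m2 = densities_kg_m2,
    replicates = replicates, plot_area_m2 = plot_area_m2,
    survival_coeffs = survival_coeffs,
    density_season_coeff = density_season_coeff, temp_ref_C = temp_ref_C,
    intracage_correlation = intracage_correlation,
    ci_coeffs = ci_coeffs, ci_log_sd = ci_log_sd,
    ptoa_coeffs = ptoa_coeffs, ptoa_log_sd = ptoa_log_sd,
    count_error_rate = count_error_rate,
    environment = environment, mask = mask, seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  if (is.null(cfg$intracage_correlation)) {
    # validate the design first; the default rho needs the mean cage size
    cfg$intracage_correlation <- 0
    validate_config(cfg)
    n_bar <- mean(vapply(runs$mean_start_weight_g, function(w)
      mean(count_per_plot(densities_kg_m2, w, plot_area_m2)), 0))
    cfg$intracage_correlation <- rho_from_dispersion(17.37, n_bar)
  }
  validate_config(cfg)
  cfg
}

#' Validate a simulation configuration
#'
#' Checks the structural invariants: positive, strictly increasing
#' treatment densities; at least one replicate; positive plot area;
#' correlation in [0, 1); positive run durations and start weights; a
#' positive sampling interval.
#'
#' @param config a `sim_config` object.
#' @return The config, invisibly; errors with class
#'   `musselpatch_config_error` describe the first violated invariant.
#' @export
validate_config <- function(config) {
  fail <- function(msg) stop(errorCondition(
    msg, class = c("musselpatch_config_error", "error")))
  d <- config$densities_kg_m2
  if (length(d) < 1 || any(d <= 0)) fail("treatment densities must be strictly positive")
  if (length(d) > 1 && any(diff(d) <= 0)) fail("treatment densities must be strictly increasing")
  if (config$replicates < 1) fail("replicates must be >= 1")
  if (config$plot_area_m2 <= 0) fail("plot_area_m2 must be positive")
  rho <- config$intracage_correlation
  if (rho < 0 || rho >= 1) fail("intracage_correlation must lie in [0, 1)")
  r <- config$runs
  need <- c("run_id", "start_day", "duration_days", "mean_start_weight_g",
            "temp_direction")
  if (!all(need %in% names(r))) fail(paste(
    "runs is missing columns:", paste(setdiff(need, names(r)), collapse = ", ")))
  if (anyDuplicated(r$run_id)) fail("duplicate run ids")
  if (any(r$duration_days < 1)) fail("run durations must be >= 1 day")
  if (any(r$mean_start_weight_g <= 0)) fail("mean start weights must be positive")
  if (!all(r$temp_direction %in% c("-", "0", "+"))) fail(
    "temp_direction must be one of '-', '0', '+'")
  if (config$environment$interval_min <= 0) fail("sampling interval must be positive")
  if (length(config$survival_coeffs) != 8) fail("survival_coeffs must have length 8")
  if (length(config$ci_coeffs) != 6) fail("ci_coeffs must have length 6")
  if (length(config$ptoa_coeffs) != 5) fail("ptoa_coeffs must have length 5")
  invisible(config)
}

#' Beta-binomial correlation for a target quasi-binomial dispersion
#'
#' With cages of common size N and pairwise within-cage correlation rho,
#' beta-binomial counts have variance N p (1-p) (1 + (N-1) rho), i.e. the
#' quasi-binomial mean-variance relation with dispersion
#' phi = 1 + (N-1) rho. Inverting gives rho = (phi - 1) / (N - 1).
#'
#' @param phi target Pearson dispersion (> 1 for overdispersion).
#' @param n_mean (mean) cage size N.
#' @return The correlation rho.
#' @export
rho_from_dispersion <- function(phi, n_mean) {
  stopifnot(phi >= 1, n_mean > 1)
  (phi - 1) / (n_mean - 1)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  %d runs x %d densities (%g-%g kg m^-2) x %d replicates\n",
              nrow(x$runs), length(x$densities_kg_m2),
              min(x$densities_kg_m2), max(x$densities_kg_m2), x$replicates))
  cat(sprintf("  plot area %.2f m^2; intra-cage correlation rho = %.4f\n",
              x$plot_area_m2, x$intracage_correlation))
  cat(sprintf("  density-season interaction gamma = %g (ref %.2f C)\n",
              x$density_season_coeff, x$temp_ref_C))
  invisible(x)
}
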