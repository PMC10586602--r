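# Day-of-year of a simulation day (day 0 = 1 March of the first year).
.doy <- function(simday) (simday + 59) %% 365.25 + 1

# Periodic interpolation through (day-of-year, value) anchors: anchors are
# replicated one period to each side and passed through a cubic spline, so
# the curve is smooth across the year boundary.
.periodic_anchor_curve <- function(anchor_doy, anchor_val, simday) {
  P <- 365.25
  xs <- c(anchor_doy - P, anchor_doy, anchor_doy + P)
  stats::spline(xs, rep(anchor_val, 3), xout = .doy(simday), method = "fmm")$y
}

.gaussian_bump <- function(simday, center, width) {
  exp(-0.5 * ((simday - center) / width)^2)
}

# Noise-free temperature curve: three-harmonic seasonal cycle minus the
# year-2 cold-spell anomaly.
.temp_curve <- function(p, simday) {
  d <- .doy(simday)
  p$temp_mean +
    p$temp_amplitude * cos(2 * pi * (d - p$temp_peak_doy) / 365.25) +
    p$temp_harm2_amp * cos(4 * pi * (d - p$temp_harm2_peak) / 365.25) +
    p$temp_harm3_amp * cos(6 * pi * (d - p$temp_harm3_peak) / 365.25) -
    p$coldspell_depth_C *
      .gaussian_bump(simday, p$coldspell_center_day, p$coldspell_width_days)
}

.chl_curve <- function(p, simday) {
  .periodic_anchor_curve(p$chl_anchor_doy, p$chl_anchor_val, simday) +
    p$chl_bloom2_amp *
      .gaussian_bump(simday, p$chl_bloom2_center_day, p$chl_bloom2_width_days)
}

.turb_curve <- function(p, simday) {
  .periodic_anchor_curve(p$turb_anchor_doy, p$turb_anchor_val, simday) +
    p$storm2_amp *
      .gaussian_bump(simday, p$storm2_center_day, p$storm2_width_days)
}

# Stationary AR(1) noise with marginal standard deviation sd.
.ar1_noise <- function(n, sd, ar) {
  if (sd == 0 || n == 0) return(numeric(n))
  innov_sd <- sd * sqrt(1 - ar^2)
  as.numeric(stats::filter(stats::rnorm(n, 0, innov_sd), ar,
                           method = "recursive"))
}

.in_storm_season <- function(simday, season_doy) {
  d <- .doy(simday)
  if (season_doy[1] > season_doy[2]) d >= season_doy[1] | d <= season_doy[2]
  else d >= season_doy[1] & d <= season_doy[2]
}

#' Generate one year of environmental logger data
#'
#' Simulates the site's logger series (temperature, chlorophyll-a,
#' turbidity) at a fixed sampling interval over the experimental year.
#' Temperature follows a seasonal harmonic cycle plus a late-winter
#' cold-spell anomaly in the second calendar year; chlorophyll-a follows
#' an annual curve with a spring bloom (non-negative); turbidity is an
#' annual baseline plus exponentially decaying storm pulses whose onsets
#' are a Poisson process restricted to the winter storm season
#' (non-negative). All channels carry AR(1) noise. The output is a pure
#' function of `(config, seed)`.
#'
#' @param config a [sim_config()] object (its `environment` element holds
#'   the channel parameters).
#' @param seed integer RNG seed; defaults to `config$seed`.
#' @return A data.frame of class `mussel_env` with columns `timestamp`
#'   (POSIXct, UTC), `day` (fractional simulation days), `temperature_C`,
#'   `chlorophyll_ug_l` and `turbidity_FTU`.
#' @export
gen_environment <- function(config, seed = config$seed) {
  validate_config(config)
  p <- config$environment
  if (p$interval_min <= 0) stop(errorCondition(
    "sampling interval must be positive",
    class = c("musselpatch_config_error", "error")))
  set.seed(seed)
  per_day <- 24 * 60 / p$interval_min
  n <- round(p$n_days * per_day)
  day <- (seq_len(n) - 1) / per_day
  origin <- as.POSIXct("2017-03-01 00:00:00", tz = "UTC")
  ts <- origin + day * 86400

  temp <- .temp_curve(p, day) + .ar1_noise(n, p$temp_noise_sd, p$temp_noise_ar)
  chl <- pmax(0, .chl_curve(p, day) +
                .ar1_noise(n, p$chl_noise_sd, p$chl_noise_ar))

  turb <- .turb_curve(p, day) + .ar1_noise(n, p$turb_noise_sd, p$turb_noise_ar)
  if (p$storm_rate_per_day > 0) {
    storm_days <- which(.in_storm_season(0:(p$n_days - 1), p$storm_season_doy))
    counts <- stats::rpois(length(storm_days), p$storm_rate_per_day)
    onsets <- rep(storm_days - 1, counts) + stats::runif(sum(counts))
    amps <- stats::rexp(length(onsets), rate = 1 / p$storm_amp_mean_FTU)
    horizon <- 8 * p$storm_decay_days
    for (k in seq_along(onsets)) {
      i0 <- max(1L, ceiling(onsets[k] * per_day))
      i1 <- min(n, ceiling((onsets[k] + horizon) * per_day))
      if (i0 > n) next
      idx <- i0:i1
      dt <- day[idx] - onsets[k]
      turb[idx] <- turb[idx] + amps[k] * exp(-dt / p$storm_decay_days)
    }
  }
  turb <- pmax(0, turb)

  env <- data.frame(timestamp = ts, day = day, temperature_C = temp,
                    chlorophyll_ug_l = chl, turbidity_FTU = turb)
  attr(env, "interval_min") <- p$interval_min
  attr(env, "origin") <- origin
  class(env) <- c("mussel_env", "data.frame")
  env
}

#' Extract the slice of an environment series covering a run window
#'
#' @param env a `mussel_env` data.frame from [gen_environment()].
#' @param start_day first day of the window (simulation days).
#' @param duration_days window length in days.
#' @return The rows of `env` with `start_day <= day < start_day + duration`.
#' @export
env_window <- function(env, start_day, duration_days) {
  out <- env[env$day >= start_day & env$day < start_day + duration_days, ]
  if (nrow(out) == 0) stop("environment series does not cover the window")
  out
}

#' Run-window means of the environmental covariates
#'
#' Computes, for every run in the design, the mean temperature,
#' chlorophyll-a and turbidity over that run's window. These are the
#' environmental covariates entering the survival, condition and
#' patch-shape models.
#'
#' @param env a `mussel_env` data.frame.
#' @param runs a run-design data.frame (see [default_run_designs()]).
#' @return A data.frame with columns `run_id`, `Temp`, `Chl`, `Turb`.
#' @export
run_covariates <- function(env, runs) {
  end_day <- max(runs$start_day + runs$duration_days)
  if (max(env$day) < end_day - 1) stop(
    "environment series does not cover every run window")
  out <- lapply(seq_len(nrow(runs)), function(i) {
    w <- env_window(env, runs$start_day[i], runs$duration_days[i])
    data.frame(run_id = runs$run_id[i],
               Temp = mean(w$temperature_C),
               Chl = mean(w$chlorophyll_ug_l),
               Turb = mean(w$turbidity_FTU))
  })
  do.call(rbind, out)
}
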