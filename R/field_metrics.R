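#' Number of mussels seeded per plot
#'
#' Converts a biomass density treatment (kg m^-2) into a count of
#' individuals per plot using the mean individual wet weight from the
#' start subsample: round(density * area * 1000 / weight). Rounding is to
#' the nearest integer; this reproduces the printed per-plot counts of
#' the standard design (52, 156, ..., 988), including the
#' rounding-sensitive 155.7 -> 156.
#'
#' @param density_kg_m2 biomass density (kg m^-2), > 0.
#' @param mean_individual_weight_g mean wet weight of one mussel (g), > 0.
#' @param plot_area_m2 plot area (m^2), > 0.
#' @return Integer count(s) of mussels per plot.
#' @seealso [count_per_plot_from_density()] for numeric densities given
#'   directly in individuals m^-2.
#' @export
count_per_plot <- function(density_kg_m2, mean_individual_weight_g,
                           plot_area_m2) {
  if (any(density_kg_m2 <= 0)) stop("density_kg_m2 must be positive")
  if (any(mean_individual_weight_g <= 0)) stop("mean individual weight must be positive")
  if (any(plot_area_m2 <= 0)) stop("plot_area_m2 must be positive")
  as.integer(round(density_kg_m2 * plot_area_m2 * 1000 / mean_individual_weight_g))
}

#' @rdname count_per_plot
#' @param individuals_m2 numeric density (individuals m^-2), > 0.
#' @export
count_per_plot_from_density <- function(individuals_m2, plot_area_m2) {
  if (any(individuals_m2 <= 0)) stop("individuals_m2 must be positive")
  if (any(plot_area_m2 <= 0)) stop("plot_area_m2 must be positive")
  as.integer(round(individuals_m2 * plot_area_m2))
}

#' Start/end subsample summary of a cage
#'
#' Validated container for the homogenized subsample measured at the
#' start and end of a deployment: the measurements that translate cage
#' biomass into individual counts and yield the condition index.
#'
#' @param n_individuals number of mussels in the subsample, >= 1.
#' @param mean_wet_weight_g mean individual wet weight (g), > 0.
#' @param mean_shell_length_cm mean shell length (cm), > 0.
#' @param mean_afdw_mg mean ash-free dry weight (mg), > 0.
#' @return A one-row data.frame of class `subsample_summary`, with a
#'   `condition_index` column derived from the means.
#' @export
subsample_summary <- function(n_individuals, mean_wet_weight_g,
                              mean_shell_length_cm, mean_afdw_mg) {
  if (n_individuals < 1) stop("n_individuals must be >= 1")
  if (any(c(mean_wet_weight_g, mean_shell_length_cm, mean_afdw_mg) <= 0))
    stop("subsample means must be positive")
  out <- data.frame(n_individuals = as.integer(n_individuals),
                    mean_wet_weight_g = mean_wet_weight_g,
                    mean_shell_length_cm = mean_shell_length_cm,
                    mean_afdw_mg = mean_afdw_mg,
                    condition_index = condition_index(mean_afdw_mg,
                                                      mean_shell_length_cm))
  class(out) <- c("subsample_summary", "data.frame")
  out
}

#' Condition index of a mussel
#'
#' CI = AFDW / L^3 (mg cm^-3), the ash-free dry weight divided by the
#' cube of the shell length: an instantaneous proxy for growth and
#' fitness in bivalves.
#'
#' @param afdw_mg ash-free dry weight (mg), > 0.
#' @param shell_length_cm shell length (cm), > 0.
#' @return Condition index (mg cm^-3).
#' @export
condition_index <- function(afdw_mg, shell_length_cm) {
  if (any(afdw_mg <= 0)) stop("afdw_mg must be positive")
  if (any(shell_length_cm <= 0)) stop("shell_length_cm must be positive")
  afdw_mg / shell_length_cm^3
}

#' Survival proportion with end-count clamping
#'
#' p = N1 / N0, with N1 clamped to N0 whenever the end count exceeds the
#' start count. In a closed cage without recruitment an end count above
#' the start count is a counting error, so the clamp is applied and
#' flagged rather than treated as real growth in numbers.
#'
#' @param N0 start count(s), >= 1.
#' @param N1 end count(s), >= 0.
#' @return A list with elements `p` (proportion in [0, 1]), `N1_clamped`
#'   and `clamped` (logical flag per element).
#' @export
survival_proportion <- function(N0, N1) {
  if (any(N0 < 1)) stop("N0 must be >= 1")
  if (any(N1 < 0)) stop("N1 must be >= 0")
  clamped <- N1 > N0
  n1 <- pmin(N1, N0)
  list(p = n1 / N0, N1_clamped = n1, clamped = clamped)
}

#' Standardize survival to a common horizon
#'
#' Corrects for unequal run durations under a constant-death-rate
#' assumption. The daily death rate (N0 - N1) / days is multiplied by the
#' horizon (22 days by default) to give standardized binomial failures;
#' successes are N0 minus failures and p = successes / N0. Failures may
#' be non-integer and are deliberately not rounded: the quasi-binomial
#' model downstream accepts non-integer counts. If a run is shorter than
#' the horizon and mortality heavy, extrapolated failures can exceed N0;
#' they are then clipped to N0 and flagged so that p stays in [0, 1].
#'
#' @param N0 start count(s); N1 end count(s), already clamped to <= N0.
#' @param N1 end count(s).
#' @param duration_days run duration(s) in days, >= 1.
#' @param horizon_days standardization horizon (days), default 22.
#' @return A data.frame with columns `daily_death_rate`, `failures`,
#'   `successes`, `p` and `clipped`.
#' @export
standardize_survival <- function(N0, N1, duration_days, horizon_days = 22) {
  if (any(N0 < 1)) stop("N0 must be >= 1")
  if (any(duration_days < 1)) stop("duration_days must be >= 1")
  if (any(N1 > N0)) stop("N1 must be clamped to <= N0 first; see survival_proportion()")
  if (any(N1 < 0)) stop("N1 must be >= 0")
  rate <- (N0 - N1) / duration_days
  failures <- rate * horizon_days
  clipped <- failures > N0
  if (any(clipped)) {
    warning(sprintf(
      "%d cage(s) had extrapolated failures exceeding N0; clipped to N0",
      sum(clipped)))
    failures[clipped] <- N0[clipped]
  }
  successes <- N0 - failures
  data.frame(daily_death_rate = rate, failures = failures,
             successes = successes, p = successes / N0, clipped = clipped)
}

#' Temperature direction over a run window
#'
#' Classifies how temperature moved over an experimental window by
#' comparing the mean of the first quarter of the window with the mean of
#' the last quarter: "+" if the change exceeds `threshold_C`, "-" if it
#' falls below `-threshold_C`, "0" otherwise. The 1.5 degree C default
#' threshold is a configurable convention, not a measured constant.
#'
#' @param temperature_C numeric temperature series covering the window,
#'   in time order; length >= 2.
#' @param threshold_C dead-band half-width (degrees C).
#' @return One of "-", "0", "+".
#' @export
temp_direction <- function(temperature_C, threshold_C = 1.5) {
  n <- length(temperature_C)
  if (n < 2) stop("window must contain at least 2 observations")
  q <- max(1L, floor(n / 4))
  delta <- mean(temperature_C[(n - q + 1):n]) - mean(temperature_C[1:q])
  if (delta > threshold_C) "+" else if (delta < -threshold_C) "-" else "0"
}

#' Add derived survival columns to a cage table
#'
#' Applies the clamping rule and the constant-death-rate standardization
#' to every cage record, appending the columns `clamp_flag`,
#' `N1_clamped`, `daily_death_rate`, `failures`, `successes`, `p` and
#' `clipped` without mutating the input columns. `D1_clamped` is the end
#' density recomputed from the clamped end count.
#'
#' @param records cage-record data.frame with columns `N0`, `N1`,
#'   `duration_days` and `D0`.
#' @param horizon_days standardization horizon (days), default 22.
#' @return The records with derived columns appended.
#' @export
derive_survival <- function(records, horizon_days = 22) {
  need <- c("N0", "N1", "duration_days", "D0")
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("records is missing columns: ",
                         paste(miss, collapse = ", "))
  sp <- survival_proportion(records$N0, records$N1)
  st <- standardize_survival(records$N0, sp$N1_clamped,
                             records$duration_days, horizon_days)
  records$clamp_flag <- sp$clamped
  records$N1_clamped <- sp$N1_clamped
  records$D1_clamped <- records$D0 * sp$N1_clamped / records$N0
  records$daily_death_rate <- st$daily_death_rate
  records$failures <- st$failures
  records$successes <- st$successes
  records$p <- st$p
  records$clipped <- st$clipped
  records
}
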