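# Log-log OLS slope with a t-test against a neutral threshold.
.loglog_slope <- function(x, y, threshold, alpha, run_id, n_dropped = 0L) {
  n <- length(x)
  if (n < 3) stop("need at least 3 cages with positive values in run ", run_id)
  lx <- log(x); ly <- log(y)
  X <- cbind(1, lx)
  qx <- qr(X)
  beta <- qr.coef(qx, ly)
  res <- ly - drop(X %*% beta)
  sigma2 <- sum(res^2) / (n - 2)
  XtXinv <- chol2inv(chol(crossprod(X)))
  se <- sqrt(sigma2 * diag(XtXinv))
  M <- beta[2]; se_M <- se[2]
  tstat <- (M - threshold) / se_M
  p <- 2 * stats::pt(-abs(tstat), n - 2)
  classification <- if (is.nan(p) || p >= alpha) "neutral"
                    else if (M > threshold) "cooperative" else "competitive"
  data.frame(run_id = run_id, M = unname(M), b = unname(beta[1]),
             se_M = unname(se_M), n = n, n_dropped = n_dropped,
             threshold = threshold, p_vs_threshold = unname(p),
             classification = classification, stringsAsFactors = FALSE)
}

#' Per-run density-dependence slope of survival
#'
#' Pools all cages of one run (all densities and replicates) and fits the
#' log-log regression ln(D_end) = M * ln(D_0) + b by OLS. M = 1 is the
#' neutral value: with density-independent survival, end density is
#' proportional to start density and the slope is exactly 1. M
#' significantly above 1 indicates that the odds of survival rise with
#' density (cooperation/facilitation); significantly below 1, that they
#' fall (competition). Start and end densities are taken on the same
#' units (kg m^-2), which leaves the slope and the threshold-1 logic
#' invariant to the count-vs-density unit choice. Cages with a zero end
#' density are excluded with a warning (their log is undefined).
#'
#' @param run_records cage records of a single run, containing `D0` and
#'   either `D1_clamped` (preferred, see [derive_survival()]) or `D1`.
#' @param alpha two-sided significance level for the classification.
#' @return A one-row data.frame of class `slope_estimate`: `run_id`, `M`,
#'   `b`, `se_M`, `n`, `threshold`, `p_vs_threshold`, `classification`.
#' @export
survival_slope <- function(run_records, alpha = 0.05) {
  run_id <- unique(run_records$run_id)
  if (length(run_id) != 1) stop("survival_slope() expects records of a single run")
  # clamping is the metrics stage's job (derive_survival); raw D1 is used
  # as-is so that analytic inputs are not silently altered here
  d_end <- if ("D1_clamped" %in% names(run_records)) run_records$D1_clamped
           else run_records$D1
  keep <- d_end > 0
  if (any(!keep)) warning(sprintf(
    "run %s: excluded %d cage(s) with zero end density", run_id, sum(!keep)))
  out <- .loglog_slope(run_records$D0[keep], d_end[keep], threshold = 1,
                       alpha = alpha, run_id = run_id,
                       n_dropped = sum(!keep))
  class(out) <- c("slope_estimate", "data.frame")
  out
}

#' Per-run density-dependence slope of the condition index
#'
#' Fits ln(CI) = M * ln(D_0) + b by OLS over the cages of one run. The
#' neutral value is M = 0: negative M means condition declines with
#' density (competition for food), positive M would mean facilitation.
#' A run without usable condition data (fewer than 3 cages with CI > 0)
#' returns an "unavailable" row with NA slope rather than an error, so a
#' seasonal profile can still be assembled around a missing run.
#'
#' @param run_records cage records of a single run with columns `D0`, `CI`.
#' @param alpha two-sided significance level for the classification.
#' @return A one-row `slope_estimate` data.frame (see [survival_slope()]);
#'   `classification` is `"unavailable"` when data are insufficient.
#' @export
ci_slope <- function(run_records, alpha = 0.05) {
  run_id <- unique(run_records$run_id)
  if (length(run_id) != 1) stop("ci_slope() expects records of a single run")
  ci <- run_records$CI
  keep <- !is.na(ci) & ci > 0
  if (sum(keep) < 3) {
    out <- data.frame(run_id = run_id, M = NA_real_, b = NA_real_,
                      se_M = NA_real_, n = sum(keep), n_dropped = sum(!keep),
                      threshold = 0, p_vs_threshold = NA_real_,
                      classification = "unavailable", stringsAsFactors = FALSE)
    class(out) <- c("slope_estimate", "data.frame")
    return(out)
  }
  out <- .loglog_slope(run_records$D0[keep], ci[keep], threshold = 0,
                       alpha = alpha, run_id = run_id, n_dropped = sum(!keep))
  class(out) <- c("slope_estimate", "data.frame")
  out
}

#' Seasonal profile of density-dependence slopes
#'
#' Orders per-run slope estimates by run start date and summarizes the
#' shape of the seasonal trajectory with a concavity indicator: the
#' quadratic coefficient of an OLS fit of M against the run index. A
#' negative quadratic coefficient indicates the bell shape (interaction
#' strength rising towards summer and falling towards winter); its
#' standard error conveys how well-determined the curvature is.
#'
#' @param slopes a data.frame of per-run slope estimates (rows from
#'   [survival_slope()] or [ci_slope()], rbind-ed).
#' @param run_designs run-design data.frame with `run_id` and `start_day`.
#' @return A list with `profile` (slopes ordered by start date, with
#'   `season_index`), `concavity`, `concavity_se` and `peak_run_id` (the
#'   run with the largest finite M).
#' @export
seasonal_profile <- function(slopes, run_designs) {
  if (anyDuplicated(slopes$run_id)) stop("duplicate run ids in slopes")
  if (nrow(slopes) < 3) stop("need at least 3 runs for a seasonal profile")
  ord <- order(run_designs$start_day[match(slopes$run_id, run_designs$run_id)])
  prof <- slopes[ord, ]
  prof$season_index <- seq_len(nrow(prof))
  usable <- is.finite(prof$M)
  idx <- prof$season_index[usable]; m <- prof$M[usable]
  X <- cbind(1, idx, idx^2)
  qx <- qr(X)
  beta <- qr.coef(qx, m)
  res <- m - drop(X %*% beta)
  df <- length(m) - 3
  se2 <- if (df > 0) sum(res^2) / df * diag(chol2inv(chol(crossprod(X))))
         else rep(NA_real_, 3)
  peak <- prof$run_id[usable][which.max(m)]
  list(profile = prof, concavity = unname(beta[3]),
       concavity_se = unname(sqrt(se2[3])), peak_run_id = peak)
}
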