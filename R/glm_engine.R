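# Shared helpers for the model-fitting engine.

.check_full_rank <- function(X) {
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    stop("design matrix is rank deficient; collinear terms: ",
         paste(bad, collapse = ", "))
  }
  qx
}

.t_pvalues <- function(est, se, df) 2 * stats::pt(-abs(est / se), df)

#' Holm step-down adjustment of p-values
#'
#' Sorts the p-values ascending, multiplies the i-th smallest of m by
#' (m - i + 1), enforces the running maximum so adjusted values are
#' monotone in the raw ordering, caps at 1, and restores the input order.
#' Holm's procedure controls the family-wise error rate and dominates
#' Bonferroni (elementwise p_holm <= min(1, m * p_raw)).
#'
#' @param p numeric vector of p-values in [0, 1]; NAs are passed through
#'   and do not count towards the family size.
#' @return The adjusted p-values, in the input order.
#' @export
holm_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  out <- rep(NA_real_, length(p))
  ok <- which(!is.na(p))
  m <- length(ok)
  if (m == 0) return(out)
  o <- order(p[ok])
  adj <- pmin(1, (m - seq_len(m) + 1) * p[ok][o])
  adj <- cummax(adj)
  out[ok][o] <- adj
  out
}

#' Quasi-binomial GLM with logit link on (possibly non-integer) counts
#'
#' Fits mean model logit(p_i) = x_i' beta by iteratively reweighted least
#' squares with prior weights N_i = successes_i + failures_i and response
#' y_i = successes_i / N_i. Successes and failures may be non-integer, as
#' produced by survival standardization to a common horizon: the
#' quasi-likelihood estimating equations only involve means and weights.
#' The dispersion is estimated from Pearson residuals,
#' phi = sum(N (y - mu)^2 / (mu (1 - mu))) / (n - p), standard errors are
#' model-based times sqrt(phi), and p-values use the t-distribution on
#' n - p degrees of freedom (the usual quasi-binomial convention).
#' Holm-adjusted p-values are computed across this model's coefficients.
#'
#' @param formula model formula whose left-hand side is
#'   `cbind(successes, failures)`.
#' @param data data.frame holding the variables.
#' @param tol convergence tolerance on max |delta beta| (default 1e-8).
#' @param max_iter iteration cap (default 100); non-convergence returns
#'   the fit with `converged = FALSE` and a warning.
#' @return An object of class `qb_fit`: coefficients, vcov, dispersion,
#'   se, p_raw, p_holm, fitted values, residual df, convergence info.
#' @export
fit_quasibinomial <- function(formula, data, tol = 1e-8, max_iter = 100) {
  mf <- stats::model.frame(formula, data)
  Y <- stats::model.response(mf)
  if (is.null(dim(Y)) || ncol(Y) != 2) stop(
    "response must be a two-column matrix cbind(successes, failures)")
  if (any(Y < 0)) stop("successes and failures must be non-negative")
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  w <- rowSums(Y)
  if (any(w <= 0)) stop("each row needs successes + failures > 0")
  y <- Y[, 1] / w
  .check_full_rank(X)
  n <- nrow(X); p <- ncol(X)

  # starting values: link-transformed adjusted response
  mu <- (w * y + 0.5) / (w + 1)
  eta <- stats::qlogis(mu)
  beta <- rep(0, p)
  converged <- FALSE
  iter <- 0
  eps <- 1e-10
  while (iter < max_iter) {
    iter <- iter + 1
    mu <- stats::plogis(eta)
    mu <- pmin(pmax(mu, eps), 1 - eps)
    v <- mu * (1 - mu)
    W <- w * v
    z <- eta + (y - mu) / v
    sw <- sqrt(W)
    fit <- qr(sw * X)
    beta_new <- qr.coef(fit, sw * z)
    if (max(abs(beta_new - beta)) < tol) {
      beta <- beta_new
      converged <- TRUE
      eta <- drop(X %*% beta)
      break
    }
    beta <- beta_new
    eta <- drop(X %*% beta)
  }
  if (!converged) warning("IRLS did not converge in ", max_iter, " iterations")
  mu <- pmin(pmax(stats::plogis(eta), eps), 1 - eps)
  pearson <- w * (y - mu)^2 / (mu * (1 - mu))
  df_res <- n - p
  dispersion <- sum(pearson) / df_res
  XtWX <- crossprod(sqrt(w * mu * (1 - mu)) * X)
  vcov_model <- solve(XtWX)
  vcov <- dispersion * vcov_model
  se <- sqrt(diag(vcov))
  est <- as.numeric(beta); names(est) <- colnames(X)
  p_raw <- .t_pvalues(est, se, df_res)
  structure(list(
    coefficients = est, se = se, vcov = vcov, dispersion = dispersion,
    p_raw = p_raw, p_holm = holm_adjust(p_raw),
    fitted = mu, linear_predictor = eta, prior_weights = w, response = y,
    X = X, df_residual = df_res, converged = converged, n_iter = iter,
    family = "quasibinomial(logit)"),
    class = "qb_fit")
}

#' Log-linear model for a positive ratio response
#'
#' Ordinary least squares on the log-transformed response: responses such
#' as the perimeter-to-area ratio and the condition index are positive
#' ratios whose errors act multiplicatively, so the linear model is fitted
#' to ln(response). Model-based standard errors, t-based p-values on the
#' residual df, Holm-adjusted p-values and the ingredients for
#' heteroskedasticity-robust covariance ([robust_se()]) are stored.
#'
#' @param formula model formula; the left-hand side is the response on
#'   its natural (untransformed, strictly positive) scale.
#' @param data data.frame holding the variables.
#' @return An object of class `ll_fit`.
#' @export
fit_loglinear <- function(formula, data) {
  mf <- stats::model.frame(formula, data)
  yraw <- stats::model.response(mf)
  if (!is.numeric(yraw)) stop("response must be numeric and positive")
  if (any(yraw <= 0)) stop(
    "response must be strictly positive for the log transform; offending rows: ",
    paste(utils::head(which(yraw <= 0), 10), collapse = ", "))
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  .check_full_rank(X)
  y <- log(yraw)
  n <- nrow(X); p <- ncol(X)
  qx <- qr(X)
  beta <- qr.coef(qx, y)
  res <- y - drop(X %*% beta)
  df_res <- n - p
  sigma2 <- sum(res^2) / df_res
  XtXinv <- chol2inv(chol(crossprod(X)))
  dimnames(XtXinv) <- list(colnames(X), colnames(X))
  vcov_model <- sigma2 * XtXinv
  se <- sqrt(diag(vcov_model))
  hat <- rowSums((X %*% XtXinv) * X)
  est <- as.numeric(beta); names(est) <- colnames(X)
  p_raw <- .t_pvalues(est, se, df_res)
  structure(list(
    coefficients = est, se = se, se_model = se, vcov = vcov_model,
    vcov_model = vcov_model, sigma2 = sigma2, residuals = res, hat = hat,
    X = X, df_residual = df_res, p_raw = p_raw,
    p_holm = holm_adjust(p_raw), robust_variant = NULL,
    family = "gaussian on log(response)"),
    class = "ll_fit")
}

#' Heteroskedasticity-robust (sandwich) standard errors
#'
#' Replaces a log-linear fit's covariance with the sandwich estimator
#' bread %*% meat %*% bread, where bread = (X'X)^-1 and
#' meat = sum_i w_i e_i^2 x_i x_i'. The HC weighting w_i is 1 (HC0),
#' n/(n-p) (HC1), 1/(1-h_i) (HC2) or 1/(1-h_i)^2 (HC3, the default, which
#' discounts high-leverage rows most strongly). Raw and Holm-adjusted
#' p-values are recomputed from the robust standard errors using the
#' t-distribution on the residual df.
#'
#' @param fit an `ll_fit` from [fit_loglinear()].
#' @param variant one of "HC0", "HC1", "HC2", "HC3".
#' @return The fit, updated with `vcov`, `se`, `se_robust`, `p_raw`,
#'   `p_holm` and `robust_variant`.
#' @export
robust_se <- function(fit, variant = c("HC3", "HC2", "HC1", "HC0")) {
  if (!inherits(fit, "ll_fit")) stop(
    "robust_se() applies to linear-model fits (class 'll_fit')")
  variant <- match.arg(variant)
  X <- fit$X
  e <- fit$residuals
  h <- fit$hat
  n <- nrow(X); p <- ncol(X)
  if (variant %in% c("HC2", "HC3") && any(h >= 1 - 1e-12)) stop(
    "leverage of 1 encountered; ", variant, " weighting is undefined")
  wts <- switch(variant,
    HC0 = rep(1, n),
    HC1 = rep(n / (n - p), n),
    HC2 = 1 / (1 - h),
    HC3 = 1 / (1 - h)^2)
  bread <- fit$vcov_model / fit$sigma2      # (X'X)^-1
  meat <- crossprod(X * sqrt(wts) * abs(e)) # sum w e^2 x x'
  vc <- bread %*% meat %*% bread
  dimnames(vc) <- dimnames(fit$vcov_model)
  fit$vcov <- vc
  fit$se <- fit$se_robust <- sqrt(diag(vc))
  fit$p_raw <- .t_pvalues(fit$coefficients, fit$se, fit$df_residual)
  fit$p_holm <- holm_adjust(fit$p_raw)
  fit$robust_variant <- variant
  fit
}

#' Coefficient table of a fitted model
#'
#' @param fit a `qb_fit` or `ll_fit`.
#' @return A data.frame with columns `Term`, `Estimate`, `Std.error`,
#'   `p.value`, `p.holm`, mirroring the summary tables of the three
#'   response models.
#' @export
coef_table <- function(fit) {
  data.frame(Term = names(fit$coefficients),
             Estimate = unname(fit$coefficients),
             Std.error = unname(fit$se),
             p.value = unname(fit$p_raw),
             p.holm = unname(fit$p_holm),
             stringsAsFactors = FALSE)
}

#' @export
print.qb_fit <- function(x, ...) {
  cat(sprintf("Quasi-binomial GLM (logit), dispersion phi = %.2f, %s in %d iter.\n",
              x$dispersion, if (x$converged) "converged" else "NOT converged",
              x$n_iter))
  print(coef_table(x), digits = 4, row.names = FALSE)
  invisible(x)
}

#' @export
print.ll_fit <- function(x, ...) {
  cat(sprintf("Log-linear model (OLS on ln response), sigma = %.3f%s\n",
              sqrt(x$sigma2),
              if (is.null(x$robust_variant)) ""
              else paste0(", robust SEs (", x$robust_variant, ")")))
  print(coef_table(x), digits = 4, row.names = FALSE)
  invisible(x)
}

# ---- convenience fits for the three response models --------------------

#' Fit the three response models of the cage experiment
#'
#' `fit_survival_model()` fits the quasi-binomial survival model: the
#' 22-day standardized successes/failures against starting density and
#' the run-window environmental means with all pairwise environment
#' interactions. `fit_ptoa_model()` and `fit_ci_model()` fit the
#' log-linear patch-shape and condition models (main effects only;
#' interactions are excluded there because they are collinear at the
#' run-level design) with heteroskedasticity-robust standard errors.
#'
#' @param records cage table containing the derived survival columns
#'   (see [derive_survival()]) and covariate columns `D0`, `Temp`, `Chl`,
#'   `Turb` (and `PtoA`, `CI`, `temp_direction` where required).
#' @param robust_variant HC variant for the log-linear models.
#' @return A `qb_fit` or `ll_fit`.
#' @export
fit_survival_model <- function(records) {
  fit_quasibinomial(
    cbind(successes, failures) ~ D0 + Temp + Chl + Turb +
      Temp:Chl + Temp:Turb + Chl:Turb,
    data = records)
}

#' @rdname fit_survival_model
#' @export
fit_ptoa_model <- function(records, robust_variant = "HC3") {
  robust_se(fit_loglinear(PtoA ~ D0 + Temp + Chl + Turb, data = records),
            variant = robust_variant)
}

#' @rdname fit_survival_model
#' @export
fit_ci_model <- function(records, robust_variant = "HC3") {
  records$temp_direction <- factor(records$temp_direction,
                                   levels = c("0", "-", "+"))
  if (any(is.na(records$temp_direction))) stop(
    "temp_direction must be one of '0', '-', '+'")
  fit <- fit_loglinear(CI ~ D0 + temp_direction + Chl + Turb, data = records)
  names(fit$coefficients) <- sub("temp_direction", "TempDir",
                                 names(fit$coefficients))
  colnames(fit$X) <- names(fit$coefficients)
  dimnames(fit$vcov_model) <- dimnames(fit$vcov) <-
    list(names(fit$coefficients), names(fit$coefficients))
  names(fit$se) <- names(fit$se_model) <- names(fit$p_raw) <-
    names(fit$p_holm) <- names(fit$coefficients)
  robust_se(fit, variant = robust_variant)
}
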