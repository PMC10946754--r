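#' Build the segmented-regression design matrix
#'
#' Constructs the design for the segmented linear model
#' \deqn{Y_t = \beta_0 + \beta_1 t + \beta_2 D_t + \beta_3 (t - T_I) D_t + \varepsilon_t}
#' on the integer grid: an intercept column, the grid index `t`, the
#' interruption indicator `D` (0 before the interruption index, 1 at and
#' after it), and the post-interruption trend `(t - TI) * D`. Rows exist
#' only for observed grid indices — interior missing points are simply
#' omitted, not imputed.
#'
#' @param series An `extracted_series` with `interruption_index` set, or a
#'   `provided_series`.
#' @return An object of class `its_design`: list with matrix `X`
#'   (columns `beta0`, `beta1`, `beta2`, `beta3`), response `y`, grid
#'   indices `t`, and interruption index `ti`.
#' @export
build_design <- function(series) {
  if (inherits(series, "provided_series")) series <- as_extracted_series(series)
  stopifnot(inherits(series, "extracted_series"))
  ti <- series$interruption_index
  if (is.na(ti)) stop("build_design: interruption_index not set; ",
                      "call resolve_interruption() first")
  t <- series$times
  n_pre <- sum(t < ti)
  n_post <- sum(t >= ti)
  if (n_pre < 2L || n_post < 2L)
    stop("build_design: segment with < 2 points (", n_pre, " pre, ",
         n_post, " post)")
  if (n_pre < 3L || n_post < 3L)
    stop("build_design: under-identified segment with < 3 points (",
         n_pre, " pre, ", n_post, " post)")
  d <- as.numeric(t >= ti)
  X <- cbind(beta0 = 1, beta1 = t, beta2 = d, beta3 = (t - ti) * d)
  structure(list(X = X, y = series$values, t = t, ti = ti,
                 source_id = series$source_id,
                 extractor_id = series$extractor_id),
            class = "its_design")
}

new_segmented_fit <- function(beta, se, df, rho_hat, sigma2_hat, estimator,
                              converged, n_obs, ci_level = 0.95) {
  names(beta) <- names(se) <- c("beta0", "beta1", "beta2", "beta3")
  if (is.finite(df)) {
    crit <- stats::qt(1 - (1 - ci_level) / 2, df = df)
    p <- 2 * stats::pt(abs(beta / se), df = df, lower.tail = FALSE)
  } else {
    crit <- stats::qnorm(1 - (1 - ci_level) / 2)
    p <- 2 * stats::pnorm(abs(beta / se), lower.tail = FALSE)
  }
  p <- pmax(p, .Machine$double.xmin)  # keep p in (0, 1] under underflow
  structure(
    list(beta_hat = beta, se = se,
         ci_low = beta - crit * se, ci_high = beta + crit * se,
         p = p, rho_hat = rho_hat, sigma2_hat = sigma2_hat,
         estimator = estimator, converged = converged,
         n_obs = n_obs, df = df, ci_level = ci_level),
    class = "segmented_fit")
}

#' @export
print.segmented_fit <- function(x, digits = 4, ...) {
  cat(sprintf("Segmented ITS fit (%s%s), n = %d\n", x$estimator,
              if (x$converged) "" else ", NOT converged", x$n_obs))
  tab <- cbind(estimate = x$beta_hat, se = x$se, ci_low = x$ci_low,
               ci_high = x$ci_high, p = x$p)
  print(round(tab, digits))
  if (!is.null(x$rho_hat) && !is.na(x$rho_hat))
    cat(sprintf("rho_hat = %.4f, sigma2_hat = %.4f\n", x$rho_hat, x$sigma2_hat))
  invisible(x)
}

check_full_rank <- function(X) {
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(dropped, collapse = ", "))
  }
  qrX
}

#' Fit the segmented model by ordinary least squares
#'
#' Least-squares coefficients with standard errors from
#' \eqn{\hat\sigma^2 (X'X)^{-1}}, \eqn{\hat\sigma^2 = RSS/(n - 4)}, and
#' confidence intervals and two-sided p-values from a t reference with
#' n - 4 degrees of freedom.
#'
#' @param design An `its_design` from [build_design()].
#' @param ci_level Confidence level (default 0.95).
#' @return A `segmented_fit` with `estimator = "OLS"`.
#' @export
fit_ols <- function(design, ci_level = 0.95) {
  stopifnot(inherits(design, "its_design"))
  X <- design$X; y <- design$y
  n <- length(y); p <- ncol(X)
  qrX <- check_full_rank(X)
  beta <- as.numeric(qr.coef(qrX, y))
  rss <- sum((y - as.numeric(X %*% beta))^2)
  sigma2 <- rss / (n - p)
  xtx_inv <- chol2inv(qr.R(qrX))[order(qrX$pivot), order(qrX$pivot)]
  se <- sqrt(pmax(sigma2 * diag(xtx_inv), 0))
  new_segmented_fit(beta, se, df = n - p, rho_hat = NA_real_,
                    sigma2_hat = sigma2, estimator = "OLS",
                    converged = TRUE, n_obs = n, ci_level = ci_level)
}

# Restricted log-likelihood of the linear model with stationary AR(1)
# errors, profiled over the marginal error variance. Correlation between
# rows i, j is rho^|t_i - t_j| on the grid-index distance, so interior
# missing points widen the effective lag. Returns the criterion plus the
# GLS quantities at this rho.
reml_ar1_profile <- function(rho, X, y, t) {
  n <- length(y); p <- ncol(X)
  R <- rho^abs(outer(t, t, "-"))
  ch <- tryCatch(chol(R), error = function(e) NULL)
  if (is.null(ch)) return(list(logrl = -Inf))
  # whiten: solve L' z = v  with R = L'L (chol gives upper triangular)
  Xw <- backsolve(ch, X, transpose = TRUE)
  yw <- backsolve(ch, y, transpose = TRUE)
  xtx <- crossprod(Xw)
  beta <- tryCatch(solve(xtx, crossprod(Xw, yw)), error = function(e) NULL)
  if (is.null(beta)) return(list(logrl = -Inf))
  resid <- yw - Xw %*% beta
  rss <- sum(resid^2)
  sigma2 <- rss / (n - p)                     # REML variance estimate
  logdetR <- 2 * sum(log(diag(ch)))
  logdetXtX <- determinant(xtx, logarithm = TRUE)$modulus[1L]
  logrl <- -0.5 * ((n - p) * log(sigma2) + logdetR + logdetXtX + (n - p))
  list(logrl = as.numeric(logrl), beta = as.numeric(beta), sigma2 = sigma2,
       cov_unscaled = solve(xtx))
}

#' Fit the segmented model by REML with stationary AR(1) errors
#'
#' Maximises the restricted likelihood of the segmented linear model under
#' a stationary lag-1 autocorrelated error process. The marginal error
#' variance is profiled out analytically and the autocorrelation `rho` is
#' optimised numerically over (-0.99, 0.99); coefficients are the GLS
#' estimates at the optimum, with standard errors from
#' \eqn{\hat\sigma^2 (X' R^{-1} X)^{-1}}. Intervals and p-values use a
#' normal reference. Non-convergence — an optimiser failure, a non-finite
#' criterion, or `rho` pinned at the search boundary — is not an error but
#' a flagged result, because it drives the group-level fallback policy of
#' [fit_series_group()].
#'
#' @param design An `its_design`.
#' @param ci_level Confidence level (default 0.95).
#' @param rho_bound Search bound for `|rho|` (default 0.99).
#' @return A `segmented_fit` with `estimator = "REML_AR1"` and a
#'   `converged` flag.
#' @export
fit_reml_ar1 <- function(design, ci_level = 0.95, rho_bound = 0.99) {
  stopifnot(inherits(design, "its_design"))
  X <- design$X; y <- design$y; t <- design$t
  n <- length(y); p <- ncol(X)
  if (n < 6L) stop("fit_reml_ar1: need at least 6 observations")
  check_full_rank(X)

  opt <- tryCatch(
    stats::optimize(function(r) reml_ar1_profile(r, X, y, t)$logrl,
                    interval = c(-rho_bound, rho_bound),
                    maximum = TRUE, tol = 1e-8),
    error = function(e) NULL)
  converged <- TRUE
  if (is.null(opt) || !is.finite(opt$objective)) {
    converged <- FALSE
    rho_hat <- 0
  } else {
    rho_hat <- opt$maximum
    # optimize() never returns the exact endpoint; treat the outermost
    # 0.005 of the search range as boundary-pinned (non-converged).
    if (abs(rho_hat) >= rho_bound - 0.005) converged <- FALSE
  }
  prof <- reml_ar1_profile(rho_hat, X, y, t)
  if (!is.finite(prof$logrl)) {
    converged <- FALSE
    prof <- reml_ar1_profile(0, X, y, t)
  }
  se <- sqrt(pmax(prof$sigma2 * diag(prof$cov_unscaled), 0))
  new_segmented_fit(prof$beta, se, df = Inf, rho_hat = rho_hat,
                    sigma2_hat = prof$sigma2, estimator = "REML_AR1",
                    converged = converged, n_obs = n, ci_level = ci_level)
}

#' Fit every dataset of a series group under the fallback policy
#'
#' A group is one provided series together with the extracted versions of
#' it. Every dataset is first fitted by REML with AR(1) errors; if REML
#' fails to converge for at least one dataset in the group, *all* datasets
#' in the group are refitted with OLS, so that within a group the
#' comparison of effect estimates always uses a common estimator.
#'
#' @param datasets List of `extracted_series` (and/or `provided_series`)
#'   objects sharing an interruption specification. Elements may also be
#'   prebuilt `its_design` objects.
#' @param estimator Fitting policy: `"reml_with_ols_fallback"` (default),
#'   `"reml"` (no fallback; non-converged fits are returned flagged), or
#'   `"ols"`.
#' @param ci_level Confidence level.
#' @return Named list of `segmented_fit`s (one per dataset), with attribute
#'   `"estimator_used"` (`"REML_AR1"` or `"OLS"`).
#' @export
fit_series_group <- function(datasets,
                             estimator = c("reml_with_ols_fallback",
                                           "reml", "ols"),
                             ci_level = 0.95) {
  estimator <- match.arg(estimator)
  designs <- lapply(datasets, function(d) {
    if (inherits(d, "its_design")) d else build_design(d)
  })
  nm <- names(designs)
  if (is.null(nm) || any(!nzchar(nm)))
    names(designs) <- vapply(designs, function(d)
      paste0(d$source_id, ":", d$extractor_id), character(1L))

  if (estimator == "ols") {
    fits <- lapply(designs, fit_ols, ci_level = ci_level)
    return(structure(fits, estimator_used = "OLS"))
  }
  fits <- lapply(designs, fit_reml_ar1, ci_level = ci_level)
  any_failed <- any(!vapply(fits, `[[`, logical(1L), "converged"))
  if (estimator == "reml_with_ols_fallback" && any_failed) {
    fits <- lapply(designs, fit_ols, ci_level = ci_level)
    return(structure(fits, estimator_used = "OLS"))
  }
  structure(fits, estimator_used = "REML_AR1")
}

#' Extract the interruption effect estimates from a fit
#'
#' The effect measures of interest are the immediate level change
#' (`beta2`) and the slope change (`beta3`), each with its standard error,
#' confidence interval and two-sided p-value.
#'
#' @param fit A `segmented_fit`.
#' @return A data frame with one row per effect
#'   (`level_change`, `slope_change`) and columns `estimate`, `se`,
#'   `ci_low`, `ci_high`, `p`, `estimator`.
#' @export
effect_estimates <- function(fit) {
  stopifnot(inherits(fit, "segmented_fit"))
  idx <- c(level_change = 3L, slope_change = 4L)
  data.frame(
    effect = names(idx),
    estimate = unname(fit$beta_hat[idx]),
    se = unname(fit$se[idx]),
    ci_low = unname(fit$ci_low[idx]),
    ci_high = unname(fit$ci_high[idx]),
    p = unname(fit$p[idx]),
    estimator = fit$estimator,
    row.names = NULL)
}
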