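# Shared fixtures and independent oracles, built in code at test time.

# a small deterministic spec: noise-free step (level change 1, no trend)
step_spec <- function() {
  series_spec(n_pre = 3, n_post = 4, beta0 = 1, beta1 = 0, beta2 = 1,
              beta3 = 0, rho = 0, sigma_w = 0)
}

# noisy spec for fitting tests
noisy_spec <- function(n_pre = 20, n_post = 20, rho = 0.2, sigma_w = 1,
                       beta = c(10, 0.5, -3, 0.2)) {
  series_spec(n_pre = n_pre, n_post = n_post, beta0 = beta[1],
              beta1 = beta[2], beta2 = beta[3], beta3 = beta[4],
              rho = rho, sigma_w = sigma_w)
}

# build an extracted_series directly from vectors (bypassing ingest)
make_extracted <- function(times, values, ti, native = times) {
  structure(
    list(times = as.integer(times), values = values,
         native_times = as.numeric(native),
         n_duplicates_collapsed = 0L, missing_indices = integer(0),
         n_missing_vs_reference = NA_integer_,
         interruption_index = as.integer(ti),
         grid_origin = 0, grid_step = 1,
         source_id = "fx", extractor_id = "fx",
         provided_index = seq_along(times)),
    class = "extracted_series")
}

# independent OLS oracle: explicit normal equations
ols_oracle <- function(X, y) as.numeric(solve(t(X) %*% X, t(X) %*% y))

# independent profiled-REML criterion for the AR(1) model, written from
# the restricted-likelihood definition (dense inverse, no whitening) so it
# shares no code path with the implementation
reml_criterion_oracle <- function(rho, Xm, yv, tv) {
  X <- Xm; y <- yv; t <- tv
  n <- length(y); p <- ncol(X)
  R <- rho^abs(outer(t, t, "-"))
  Ri <- solve(R)
  XtRiX <- t(X) %*% Ri %*% X
  beta <- solve(XtRiX, t(X) %*% Ri %*% y)
  r <- y - X %*% beta
  s2 <- as.numeric(t(r) %*% Ri %*% r) / (n - p)
  -0.5 * ((n - p) * log(s2) +
            as.numeric(determinant(R, logarithm = TRUE)$modulus) +
            as.numeric(determinant(XtRiX, logarithm = TRUE)$modulus) +
            (n - p))
}

# rank-based quantile oracle: 25th/75th centiles, linear interpolation
quantile_oracle <- function(x, p) {
  x <- sort(x); n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h); hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

# write a two-column x,y csv (digitizer dialect) to a temp file
write_xy_tmp <- function(x, y, ..., header = NULL) {
  f <- withr::local_tempfile(fileext = ".csv", .local_envir = parent.frame())
  lines <- paste(x, y, sep = ",")
  if (!is.null(header)) lines <- c(header, lines)
  writeLines(lines, f)
  f
}

# smooth curvature leaves residuals that look perfectly autocorrelated;
# the REML rho search pins at the boundary, a deterministic
# non-convergence trigger
quadratic_series <- function(n = 20, ti = 11) {
  t <- seq_len(n)
  make_extracted(t, (t / 3)^2, ti = ti)
}
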