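test_that("the design matrix encodes the segmented parameterisation", {
  es <- make_extracted(1:6, c(1, 1, 1, 2, 2, 2), ti = 4)
  d <- build_design(es)
  expect_equal(unname(d$X[, "beta2"]), c(0, 0, 0, 1, 1, 1))
  expect_equal(unname(d$X[, "beta3"]), c(0, 0, 0, 0, 1, 2))
  expect_equal(unname(d$X[, "beta1"]), 1:6)

  # interior missing point: row omitted, grid index kept
  es2 <- make_extracted(c(1, 3, 4, 5, 6, 7), rnorm(6), ti = 5)
  d2 <- build_design(es2)
  expect_equal(nrow(d2$X), 6)
  expect_equal(unname(d2$X[, "beta1"]), c(1, 3, 4, 5, 6, 7))

  # no pre segment
  es3 <- make_extracted(1:6, rnorm(6), ti = 1)
  expect_error(build_design(es3), "< 2 points")
  # under-identified (2-point) segment
  es4 <- make_extracted(1:6, rnorm(6), ti = 3)
  expect_error(build_design(es4), "under-identified")
})

test_that("OLS reproduces exact fits and the normal-equations oracle", {
  # noise-free step: exact interpolation, zero residual variance
  fit <- fit_ols(build_design(make_extracted(1:6, c(1, 1, 1, 2, 2, 2), ti = 4)))
  expect_equal(unname(fit$beta_hat), c(1, 0, 1, 0), tolerance = 1e-12)
  expect_equal(fit$sigma2_hat, 0, tolerance = 1e-20)

  # noise-free slope change
  sp <- series_spec(n_pre = 3, n_post = 4, beta1 = 1, beta3 = 1, sigma_w = 0)
  fit2 <- fit_ols(build_design(simulate_true_series(sp)))
  expect_equal(unname(fit2$beta_hat[3:4]), c(0, 1), tolerance = 1e-12)

  # random series vs brute-force normal equations
  for (seed in 1:5) {
    s <- simulate_true_series(noisy_spec(), seed = seed)
    d <- build_design(s)
    fit <- fit_ols(d)
    expect_equal(unname(fit$beta_hat), ols_oracle(d$X, d$y), tolerance = 1e-10)
  }
})

test_that("OLS inference matches the t(n-4) distribution oracle", {
  s <- simulate_true_series(noisy_spec(), seed = 3)
  d <- build_design(s)
  fit <- fit_ols(d)
  n <- length(d$y)
  # independent route: sigma2 and covariance from explicit matrices
  bhat <- ols_oracle(d$X, d$y)
  r <- d$y - d$X %*% bhat
  s2 <- sum(r^2) / (n - 4)
  se <- sqrt(diag(s2 * solve(t(d$X) %*% d$X)))
  expect_equal(unname(fit$se), unname(se), tolerance = 1e-10)
  expect_equal(unname(fit$p),
               unname(2 * pt(abs(bhat / se), df = n - 4, lower.tail = FALSE)),
               tolerance = 1e-12)
  expect_equal(unname(fit$ci_high - fit$ci_low),
               unname(2 * qt(0.975, n - 4) * se), tolerance = 1e-12)
})

test_that("rank-deficient designs are rejected with the offending column", {
  es <- make_extracted(1:8, rnorm(8), ti = 4)
  d <- build_design(es)
  d$X[, "beta3"] <- d$X[, "beta2"]   # force collinearity
  expect_error(fit_ols(d), "beta3")
})

test_that("the REML criterion at rho = 0 reproduces OLS coefficients", {
  for (seed in 1:5) {
    s <- simulate_true_series(noisy_spec(rho = 0.3), seed = seed)
    d <- build_design(s)
    prof <- itsagree:::reml_ar1_profile(0, d$X, d$y, d$t)
    expect_equal(prof$beta, unname(fit_ols(d)$beta_hat), tolerance = 1e-8)
  }
})

test_that("REML rho estimate matches a fine grid search of the criterion", {
  sp <- series_spec(n_pre = 6, n_post = 6, beta0 = 5, beta1 = 0.3,
                    beta2 = -2, beta3 = 0.1, rho = 0.4, sigma_w = 1)
  d <- build_design(simulate_true_series(sp, seed = 20))
  fit <- fit_reml_ar1(d)
  expect_true(fit$converged)

  grid <- seq(-0.99, 0.99, by = 1e-4)
  crit <- vapply(grid, function(r)
    reml_criterion_oracle(r, d$X, d$y, d$t), numeric(1))
  rho_star <- grid[which.max(crit)]
  expect_equal(fit$rho_hat, rho_star, tolerance = 2e-4)
  ora <- itsagree:::reml_ar1_profile(rho_star, d$X, d$y, d$t)
  expect_equal(unname(fit$beta_hat), ora$beta, tolerance = 1e-6)
  # and the two criterion implementations agree pointwise
  expect_equal(reml_criterion_oracle(0.3, d$X, d$y, d$t),
               itsagree:::reml_ar1_profile(0.3, d$X, d$y, d$t)$logrl,
               tolerance = 1e-8)
})

test_that("REML agrees with an independent generalized least squares fitter", {
  skip_if_not_installed("nlme")
  s <- simulate_true_series(noisy_spec(n_pre = 25, n_post = 25, rho = 0.3),
                            seed = 8)
  d <- build_design(s)
  fit <- fit_reml_ar1(d)
  df <- data.frame(y = d$y, t = d$t,
                   D = d$X[, "beta2"], tD = d$X[, "beta3"])
  g <- nlme::gls(y ~ t + D + tD, data = df,
                 correlation = nlme::corAR1(form = ~ t), method = "REML")
  expect_equal(unname(fit$beta_hat), unname(coef(g)), tolerance = 1e-4)
  expect_equal(fit$rho_hat,
               as.numeric(coef(g$modelStruct$corStruct, unconstrained = FALSE)),
               tolerance = 1e-3)
  expect_equal(unname(fit$se),
               unname(sqrt(diag(vcov(g)))), tolerance = 1e-3)
})

test_that("simulated rho is recovered with the expected small-sample bias", {
  rhos <- vapply(1:300, function(seed) {
    s <- simulate_true_series(noisy_spec(n_pre = 50, n_post = 50, rho = 0.4),
                              seed = 400 + seed)
    fit_reml_ar1(build_design(s))$rho_hat
  }, numeric(1))
  # mean estimate close to, and (if anything) below, the true value
  expect_lt(abs(mean(rhos) - 0.4), 0.05)
  expect_lt(mean(rhos), 0.42)
})

test_that("boundary-pinned rho is flagged as non-convergence, not an error", {
  fit <- fit_reml_ar1(build_design(quadratic_series()))
  expect_s3_class(fit, "segmented_fit")
  expect_false(fit$converged)
  expect_gte(abs(fit$rho_hat), 0.985)
})

test_that("group fallback refits every dataset with OLS on any failure", {
  prov <- simulate_true_series(noisy_spec(), seed = 31)
  good1 <- make_extracted(prov$times, prov$values + 0.01,
                          ti = prov$interruption_index)
  good2 <- make_extracted(prov$times, prov$values - 0.01,
                          ti = prov$interruption_index)
  fits <- fit_series_group(list(p = prov, a = good1, b = good2))
  expect_identical(attr(fits, "estimator_used"), "REML_AR1")
  expect_true(all(vapply(fits, `[[`, character(1), "estimator") == "REML_AR1"))

  # a boundary-pinned dataset fails -> whole group falls back to OLS
  degen <- quadratic_series(n = 40, ti = 21)
  fits2 <- fit_series_group(list(p = prov, a = good1, d = degen))
  expect_identical(attr(fits2, "estimator_used"), "OLS")
  expect_true(all(vapply(fits2, `[[`, character(1), "estimator") == "OLS"))

  # no-fallback policy keeps the flagged REML fits
  fits3 <- fit_series_group(list(p = prov, d = degen), estimator = "reml")
  expect_identical(attr(fits3, "estimator_used"), "REML_AR1")
  expect_false(fits3$d$converged)

  # a single provided-only dataset that converges stays REML
  fits4 <- fit_series_group(list(p = prov))
  expect_identical(attr(fits4, "estimator_used"), "REML_AR1")
})

test_that("fits are equivariant to outcome scaling and time shifts", {
  s <- simulate_true_series(noisy_spec(), seed = 17)
  for (fitter in list(fit_ols, fit_reml_ar1)) {
    f1 <- fitter(build_design(s))
    s2 <- s; s2$values <- 10 * s$values
    f2 <- fitter(build_design(s2))
    expect_equal(unname(f2$beta_hat), 10 * unname(f1$beta_hat),
                 tolerance = 1e-6)
    expect_equal(unname(f2$se), 10 * unname(f1$se), tolerance = 1e-6)
    expect_equal(unname(f2$p), unname(f1$p), tolerance = 1e-6)
  }
  # shifting the whole grid by an integer leaves the changes untouched
  es <- make_extracted(s$times + 7, s$values, ti = s$interruption_index + 7)
  f1 <- fit_ols(build_design(s))
  f3 <- fit_ols(build_design(es))
  expect_equal(unname(f3$beta_hat[3:4]), unname(f1$beta_hat[3:4]),
               tolerance = 1e-9)
  expect_equal(unname(f3$se[3:4]), unname(f1$se[3:4]), tolerance = 1e-9)
})

test_that("effect estimates copy the level and slope change rows verbatim", {
  s <- simulate_true_series(noisy_spec(), seed = 23)
  fit <- fit_ols(build_design(s))
  eff <- effect_estimates(fit)
  expect_identical(eff$effect, c("level_change", "slope_change"))
  expect_equal(eff$estimate, unname(fit$beta_hat[3:4]))
  expect_equal(eff$se, unname(fit$se[3:4]))
  expect_equal(eff$p, unname(fit$p[3:4]))
  # CI half-width is exactly the critical value times the SE
  expect_equal(eff$ci_high - eff$ci_low,
               2 * qt(0.975, fit$df) * eff$se, tolerance = 1e-12)

  # noise-free step fit: level change 1, slope change 0
  eff0 <- effect_estimates(fit_ols(build_design(simulate_true_series(step_spec()))))
  expect_equal(eff0$estimate, c(1, 0), tolerance = 1e-12)
})
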