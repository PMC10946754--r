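test_that("points pair by rank with unmatched provided points counted", {
  prov <- simulate_true_series(noisy_spec(n_pre = 3, n_post = 4), seed = 2)
  ex <- apply_extraction_error(prov, extraction_error_model(), seed = 1)
  pp <- pair_points(prov, ex, axis = "time")
  expect_equal(nrow(pp$pairs), 7)
  expect_identical(pp$n_unmatched_provided, 0L)
  expect_equal(pp$pairs$provided, pp$pairs$extracted)

  # drop grid point 3 of 7
  ex2 <- ex
  ex2$x <- ex$x[-3]; ex2$y <- ex$y[-3]; ex2$provided_index <- c(1:2, 4:7)
  pp2 <- pair_points(prov, ex2, axis = "outcome")
  expect_equal(nrow(pp2$pairs), 6)
  expect_identical(pp2$n_unmatched_provided, 1L)
  expect_equal(pp2$pairs$extracted, prov$values[-3])
})

test_that("calibration regression recovers offsets and drift exactly", {
  prov <- simulate_true_series(noisy_spec(), seed = 4)

  off <- apply_extraction_error(prov, extraction_error_model(x_offset = 0.5),
                                seed = 1)
  cal <- calibration_regression(pair_points(prov, off, "time"))
  cal <- standardize_calibration(cal,
                                 series_length_native = diff(range(prov$times)),
                                 n_periods = length(prov$times) - 1)
  expect_equal(cal$intercept_std, 0.5, tolerance = 1e-10)
  expect_equal(cal$slope_std, 1, tolerance = 1e-10)

  drift <- apply_extraction_error(prov, extraction_error_model(x_drift = 1.08),
                                  seed = 1)
  cal2 <- calibration_regression(pair_points(prov, drift, "time"))
  cal2 <- standardize_calibration(cal2,
                                  series_length_native = diff(range(prov$times)),
                                  n_periods = length(prov$times) - 1)
  expect_equal(cal2$slope_std, 1.08, tolerance = 1e-10)
  expect_equal(cal2$intercept_std, 0, tolerance = 1e-8)
})

test_that("calibration estimates match the lm oracle on noisy pairings", {
  set.seed(55)
  for (i in 1:4) {
    x <- 1:25
    y <- 0.3 + 1.02 * x + rnorm(25, 0, 0.2)
    pp <- structure(list(pairs = data.frame(provided = x, extracted = y),
                         n_unmatched_provided = 0L, axis = "time"),
                    class = "paired_points")
    cal <- calibration_regression(pp)
    ora <- unname(coef(lm(y ~ x)))
    expect_equal(cal$intercept_raw, ora[1], tolerance = 1e-12)
    expect_equal(cal$slope_raw, ora[2], tolerance = 1e-12)
  }
  expect_error(calibration_regression(structure(
    list(pairs = data.frame(provided = 1:2, extracted = 1:2),
         n_unmatched_provided = 0L, axis = "time"),
    class = "paired_points")), ">= 3 pairs")
})

test_that("standardisation converts units as the axis rules require", {
  # 1 month intercept on a 24-month series observed over 24 periods
  cal <- structure(list(intercept_raw = 1, slope_raw = 1,
                        intercept_std = NA_real_, slope_std = NA_real_,
                        important_error = NA, axis = "time",
                        n_pairs = 25L, n_unmatched_provided = 0L,
                        series_id = "s", extractor_id = "e"),
                   class = "calibration_result")
  out <- standardize_calibration(cal, series_length_native = 24, n_periods = 24)
  expect_equal(out$intercept_std, 1.0)

  # outcome axis: intercept scaled by the provided range
  cal$axis <- "outcome"; cal$intercept_raw <- 0.1
  out2 <- standardize_calibration(cal, provided_range = 20)
  expect_equal(out2$intercept_std, 0.005)
  expect_error(standardize_calibration(cal, provided_range = 0), "> 0")

  # identical series standardise to exactly (0, 1)
  prov <- simulate_true_series(noisy_spec(), seed = 9)
  idn <- apply_extraction_error(prov, extraction_error_model(), seed = 1)
  for (axis in c("time", "outcome")) {
    cal3 <- calibration_regression(pair_points(prov, idn, axis))
    cal3 <- if (axis == "time")
      standardize_calibration(cal3, series_length_native = 39, n_periods = 39)
    else standardize_calibration(cal3,
                                 provided_range = diff(range(prov$values)))
    expect_equal(cal3$intercept_std, 0, tolerance = 1e-10)
    expect_equal(cal3$slope_std, 1, tolerance = 1e-10)
  }
})

test_that("important-error flags follow the half-period rule", {
  mk <- function(a, b) structure(
    list(intercept_raw = a, slope_raw = b, intercept_std = a, slope_std = b,
         important_error = NA, axis = "time", n_pairs = 40L,
         n_unmatched_provided = 0L, series_id = "s", extractor_id = "e"),
    class = "calibration_result")
  span <- 1:40
  expect_true(flag_important_error(mk(0.6, 1), span)$important_error)
  expect_false(flag_important_error(mk(0.2, 1), span)$important_error)
  # drift alone accumulates to 0.8 periods at t = 40
  expect_true(flag_important_error(mk(0, 1.02), span)$important_error)
  # intercept-only variant ignores the drift
  expect_false(
    flag_important_error(mk(0, 1.02), span,
                         rule = "intercept_only")$important_error)

  # monotone in |offset| for pure-offset errors: flips once, at 0.5
  offsets <- seq(0, 1, by = 0.1)
  flags <- vapply(offsets, function(o)
    flag_important_error(mk(o, 1), span)$important_error, logical(1))
  expect_identical(flags, offsets >= 0.5)
  expect_true(all(diff(as.numeric(flags)) >= 0))
})

test_that("extractor summaries match independent quantile arithmetic", {
  mk <- function(i, s, ex, miss = 0L) structure(
    list(intercept_raw = i, slope_raw = s, intercept_std = i, slope_std = s,
         important_error = abs(i) >= 0.5, axis = "time", n_pairs = 10L,
         n_unmatched_provided = miss, series_id = "s", extractor_id = ex),
    class = "calibration_result")
  res <- list(mk(0.1, 1, "e1"), mk(0.2, 1.01, "e1"), mk(0.3, 0.99, "e1"),
              mk(0.6, 1, "e2", miss = 2L), mk(0.0, 1, "e2"), mk(-0.1, 1, "e2"),
              mk(0.05, 1, "e2"))
  tab <- summarize_extractor(res)
  e1 <- tab[tab$extractor_id == "e1", ]
  expect_equal(e1$intercept_mean, 0.2)
  expect_equal(e1$intercept_median, 0.2)
  expect_equal(e1$n_important_errors, 0L)

  e2 <- tab[tab$extractor_id == "e2", ]
  expect_equal(e2$n_important_errors, 1L)
  expect_equal(e2$n_with_missing, 1L)
  vals <- c(0.6, 0.0, -0.1, 0.05)
  expect_equal(e2$intercept_q25, quantile_oracle(vals, 0.25))
  expect_equal(e2$intercept_q75, quantile_oracle(vals, 0.75))
  expect_equal(e2$intercept_median, quantile_oracle(vals, 0.5))

  # perfect extractions: medians exactly (0, 1), no flags
  perfect <- list(mk(0, 1, "p"), mk(0, 1, "p"), mk(0, 1, "p"))
  tp <- summarize_extractor(perfect)
  expect_equal(tp$intercept_median, 0)
  expect_equal(tp$slope_median, 1)
  expect_equal(tp$n_important_errors, 0L)
})

test_that("outcome calibration is invariant to shared affine rescaling", {
  prov <- simulate_true_series(noisy_spec(), seed = 13)
  ex <- apply_extraction_error(prov,
                               extraction_error_model(y_noise_frac = 0.01),
                               seed = 3)
  cal <- function(p, e) {
    r <- calibration_regression(pair_points(p, e, "outcome"))
    standardize_calibration(r, provided_range = diff(range(p$values)))
  }
  base <- cal(prov, ex)
  prov2 <- prov; prov2$values <- 3 * prov$values
  ex2 <- ex; ex2$y <- 3 * ex$y
  resc <- cal(prov2, ex2)
  expect_equal(resc$intercept_std, base$intercept_std, tolerance = 1e-10)
  expect_equal(resc$slope_std, base$slope_std, tolerance = 1e-10)
})
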