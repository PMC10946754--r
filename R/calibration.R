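#' Pair provided and extracted coordinates on one axis
#'
#' Matches points of an extracted series to the provided ground truth by
#' rank order on the grid: each retained extracted point is paired with the
#' provided point it survived from when that bookkeeping exists, and by
#' grid index otherwise. Provided points with no extracted counterpart are
#' counted as unmatched. The time axis pairs provided integer times against
#' extracted *native* times (so offsets and drift remain visible); the
#' outcome axis pairs outcome values.
#'
#' @param provided A `provided_series`.
#' @param extracted An `extracted_series` (or a `raw_extraction` with a
#'   `provided_index` field, as produced by [apply_extraction_error()]).
#' @param axis `"time"` or `"outcome"`.
#' @return An object of class `paired_points`: data frame `pairs` with
#'   columns `provided` and `extracted` in time order, plus
#'   `n_unmatched_provided` and `axis`.
#' @export
pair_points <- function(provided, extracted, axis = c("time", "outcome")) {
  axis <- match.arg(axis)
  stopifnot(inherits(provided, "provided_series"))
  if (inherits(extracted, "raw_extraction")) {
    ex_x <- extracted$x; ex_y <- extracted$y
    pidx <- extracted$provided_index
  } else if (inherits(extracted, "extracted_series")) {
    ex_x <- extracted$native_times; ex_y <- extracted$values
    pidx <- extracted$provided_index
  } else stop("pair_points: unsupported extracted object")
  if (length(ex_x) == 0L) stop("pair_points: extracted series is empty")

  if (is.null(pidx)) {
    # no survival bookkeeping: rank-order pairing of sorted points
    k <- min(length(provided$times), length(ex_x))
    pidx <- seq_len(k)
    ex_x <- ex_x[seq_len(k)]; ex_y <- ex_y[seq_len(k)]
  }
  prov_vals <- if (axis == "time") provided$times[pidx]
               else provided$values[pidx]
  ex_vals <- if (axis == "time") ex_x else ex_y
  structure(
    list(pairs = data.frame(provided = prov_vals,
                            extracted = ex_vals),
         n_unmatched_provided = length(provided$times) - length(pidx),
         axis = axis),
    class = "paired_points")
}

#' Calibration regression of extracted on provided coordinates
#'
#' Ordinary least squares of the extracted coordinates on the provided
#' coordinates for one axis. For a perfect extraction the intercept is 0
#' and the slope 1; a non-zero intercept reflects a constant offset (e.g.
#' points drawn between tick marks), and a slope away from 1 reflects
#' error that grows or shrinks over the series (mis-calibrated axis).
#'
#' @param paired A `paired_points` object with >= 3 pairs.
#' @param series_id,extractor_id Identifiers carried into the result.
#' @return An object of class `calibration_result` with `intercept_raw`,
#'   `slope_raw` (native units; `intercept_std`, `slope_std` and the
#'   important-error flag are filled by [standardize_calibration()] /
#'   [flag_important_error()]).
#' @export
calibration_regression <- function(paired, series_id = NA_character_,
                                   extractor_id = NA_character_) {
  stopifnot(inherits(paired, "paired_points"))
  x <- paired$pairs$provided; y <- paired$pairs$extracted
  if (length(x) < 3L)
    stop("calibration_regression: need >= 3 pairs, got ", length(x))
  sxx <- sum((x - mean(x))^2)
  if (sxx == 0) stop("calibration_regression: provided coordinates constant")
  slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
  intercept <- mean(y) - slope * mean(x)
  structure(
    list(intercept_raw = intercept, slope_raw = slope,
         intercept_std = NA_real_, slope_std = NA_real_,
         important_error = NA, axis = paired$axis,
         n_pairs = length(x), n_unmatched_provided = paired$n_unmatched_provided,
         series_id = series_id, extractor_id = extractor_id),
    class = "calibration_result")
}

#' Standardise a calibration result for cross-series comparison
#'
#' Time axis: the intercept is converted to fractions of a time period by
#' dividing by the native length of the provided series and multiplying by
#' its number of time periods — equivalently, the regression is expressed
#' on the grid-index scale — and the slope is already dimensionless on
#' that scale. Outcome axis: the intercept is divided by the provided
#' series' outcome range so standardised values are comparable across
#' studies; the slope, being a ratio of like units, is left as is.
#'
#' @param result A `calibration_result`.
#' @param series_length_native Native duration of the provided series
#'   (time axis; e.g. 24 months).
#' @param n_periods Number of time periods spanned (time axis).
#' @param provided_range Outcome range, max - min, of the provided series
#'   (outcome axis).
#' @return The result with `intercept_std` and `slope_std` filled in.
#' @export
standardize_calibration <- function(result, series_length_native = NULL,
                                    n_periods = NULL, provided_range = NULL) {
  stopifnot(inherits(result, "calibration_result"))
  if (result$axis == "time") {
    if (is.null(series_length_native) || is.null(n_periods))
      stop("standardize_calibration: time axis needs series_length_native and n_periods")
    if (series_length_native <= 0)
      stop("standardize_calibration: series_length_native must be > 0")
    # equivalent to regressing with both coordinates on the grid-index
    # scale: the intercept becomes fractions of a period, the slope is a
    # ratio of like units and is already dimensionless
    result$intercept_std <- result$intercept_raw * n_periods / series_length_native
    result$slope_std <- result$slope_raw
  } else {
    if (is.null(provided_range))
      stop("standardize_calibration: outcome axis needs provided_range")
    if (provided_range <= 0)
      stop("standardize_calibration: provided_range must be > 0")
    result$intercept_std <- result$intercept_raw / provided_range
    result$slope_std <- result$slope_raw
  }
  result
}

#' Flag an important time-extraction error
#'
#' An extracted time point more than half a time period away from the
#' provided one can move the interruption to the wrong period; calibration
#' results whose fitted discrepancy reaches 0.5 periods anywhere over the
#' observed span are therefore flagged as important errors. The fitted
#' discrepancy at grid time t is |(a + b t) - t| with (a, b) the
#' standardised intercept and slope, so both a constant offset and
#' accumulated drift can trigger the flag. Set
#' `rule = "intercept_only"` to flag on |a| >= 0.5 alone.
#'
#' @param result A standardised time-axis `calibration_result`.
#' @param observed_span Grid indices at which the series was observed
#'   (the discrepancy is evaluated at each).
#' @param threshold Flag threshold in periods (default 0.5).
#' @param rule `"max_discrepancy"` (default) or `"intercept_only"`.
#' @return The result with `important_error` set.
#' @export
flag_important_error <- function(result, observed_span,
                                 threshold = 0.5,
                                 rule = c("max_discrepancy", "intercept_only")) {
  rule <- match.arg(rule)
  stopifnot(inherits(result, "calibration_result"))
  if (result$axis != "time")
    stop("flag_important_error: important-error rule applies to the time axis")
  if (is.na(result$intercept_std))
    stop("flag_important_error: standardise the result first")
  a <- result$intercept_std; b <- result$slope_std
  result$important_error <- if (rule == "intercept_only") {
    abs(a) >= threshold
  } else {
    max(abs(a + b * observed_span - observed_span)) >= threshold
  }
  result
}

# 25th/75th centiles with linear interpolation (stats::quantile type 7)
iqr_quantiles <- function(x) stats::quantile(x, c(0.25, 0.75), type = 7,
                                             names = FALSE)

#' Summarise calibration results by extractor
#'
#' For each extractor and axis, the mean (SD) and median (IQR as 25th and
#' 75th centiles, linear interpolation) of standardised intercepts and
#' slopes across series, the number of series flagged with important time
#' errors, and the number of series with at least one missing point.
#'
#' @param results List of standardised (and, for the time axis, flagged)
#'   `calibration_result`s.
#' @return A data frame with one row per extractor x axis.
#' @export
summarize_extractor <- function(results) {
  stopifnot(length(results) >= 1L)
  df <- do.call(rbind, lapply(results, function(r) {
    data.frame(extractor_id = r$extractor_id, axis = r$axis,
               intercept_std = r$intercept_std, slope_std = r$slope_std,
               important_error = isTRUE(r$important_error),
               any_missing = r$n_unmatched_provided > 0)
  }))
  out <- do.call(rbind, lapply(split(df, list(df$extractor_id, df$axis),
                                     drop = TRUE), function(g) {
    qi <- iqr_quantiles(g$intercept_std)
    qs <- iqr_quantiles(g$slope_std)
    data.frame(
      extractor_id = g$extractor_id[1L], axis = g$axis[1L],
      n_series = nrow(g),
      intercept_mean = mean(g$intercept_std),
      intercept_sd = stats::sd(g$intercept_std),
      intercept_median = stats::median(g$intercept_std),
      intercept_q25 = qi[1L], intercept_q75 = qi[2L],
      slope_mean = mean(g$slope_std),
      slope_sd = stats::sd(g$slope_std),
      slope_median = stats::median(g$slope_std),
      slope_q25 = qs[1L], slope_q75 = qs[2L],
      n_important_errors = sum(g$important_error),
      n_with_missing = sum(g$any_missing))
  }))
  rownames(out) <- NULL
  out[order(out$extractor_id, out$axis), ]
}
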