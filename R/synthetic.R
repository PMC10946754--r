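#' Specification of a segmented interrupted time series
#'
#' Defines the data-generating process for one interrupted time series (ITS):
#' a segmented linear trend with an immediate level change and a slope change
#' at the interruption, and stationary lag-1 autocorrelated (AR(1)) errors,
#'
#' \deqn{Y_t = \beta_0 + \beta_1 t + \beta_2 D_t + \beta_3 (t - T_I) D_t + \varepsilon_t,
#'       \quad \varepsilon_t = \rho \varepsilon_{t-1} + w_t,}
#'
#' where \eqn{D_t} is 0 before the interruption time \eqn{T_I} and 1 at and
#' after it, and \eqn{w_t \sim N(0, \sigma_w^2)} is white noise.
#'
#' @param n_pre Number of pre-interruption points (integer, >= 3).
#' @param n_post Number of post-interruption points (integer, >= 3).
#' @param beta0 Intercept (outcome units).
#' @param beta1 Pre-interruption slope (outcome units per period).
#' @param beta2 Immediate level change at the interruption (outcome units).
#' @param beta3 Slope change (outcome units per period).
#' @param rho Lag-1 autocorrelation of the error process, in (-1, 1).
#' @param sigma_w White-noise standard deviation, >= 0 (0 gives a noise-free
#'   series lying exactly on the two segments).
#' @param time_unit_label Free-text label for the time unit (e.g. "month").
#'
#' @return An object of class `its_series_spec`.
#' @seealso [simulate_true_series()], [generate_cohort()]
#' @export
series_spec <- function(n_pre, n_post, beta0 = 0, beta1 = 0, beta2 = 0,
                        beta3 = 0, rho = 0, sigma_w = 1,
                        time_unit_label = "period") {
  spec <- structure(
    list(n_pre = as.integer(n_pre), n_post = as.integer(n_post),
         beta0 = beta0, beta1 = beta1, beta2 = beta2, beta3 = beta3,
         rho = rho, sigma_w = sigma_w, time_unit_label = time_unit_label),
    class = "its_series_spec")
  validate_series_spec(spec)
  spec
}

validate_series_spec <- function(spec) {
  num1 <- function(field) {
    v <- spec[[field]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("series_spec: field '", field, "' must be a finite numeric scalar",
           call. = FALSE)
  }
  for (f in c("n_pre", "n_post", "beta0", "beta1", "beta2", "beta3",
              "rho", "sigma_w")) num1(f)
  if (spec$n_pre < 3L)
    stop("series_spec: field 'n_pre' must be >= 3", call. = FALSE)
  if (spec$n_post < 3L)
    stop("series_spec: field 'n_post' must be >= 3", call. = FALSE)
  if (spec$n_pre + spec$n_post < 7L)
    stop("series_spec: total length n_pre + n_post must be >= 7", call. = FALSE)
  if (abs(spec$rho) >= 1)
    stop("series_spec: field 'rho' must lie in (-1, 1)", call. = FALSE)
  if (spec$sigma_w < 0)
    stop("series_spec: field 'sigma_w' must be >= 0", call. = FALSE)
  invisible(spec)
}

#' Digitization error model
#'
#' Parameterises the error processes seen when time series points are
#' digitally extracted from published graphs: a constant time offset (points
#' drawn between tick marks), a multiplicative time-scale drift (mis-defined
#' axis calibration), a constant outcome offset and outcome jitter (both as
#' fractions of the provided series' outcome range), per-point dropout
#' (points missed during extraction), and per-point collision (a point's
#' time rounding onto its neighbour's time so that two outcome values land
#' on one time point).
#'
#' The identity model (all zeros, drift 1) reproduces the provided series
#' exactly.
#'
#' @param x_offset Constant time shift, in period units.
#' @param x_drift Multiplicative time-scale factor (> 0; 1 = no drift).
#' @param y_offset_frac Constant outcome shift as a fraction of the provided
#'   series' outcome range.
#' @param y_noise_frac SD of outcome jitter as a fraction of the provided
#'   series' outcome range.
#' @param dropout_prob Per-point probability that the point is missed, in
#'   \[0, 1).
#' @param collide_prob Per-point probability that the point's time collides
#'   with (is set equal to) its left neighbour's time, in \[0, 1).
#'
#' @return An object of class `extraction_error_model`.
#' @seealso [apply_extraction_error()]
#' @export
extraction_error_model <- function(x_offset = 0, x_drift = 1,
                                   y_offset_frac = 0, y_noise_frac = 0,
                                   dropout_prob = 0, collide_prob = 0) {
  err <- structure(
    list(x_offset = x_offset, x_drift = x_drift,
         y_offset_frac = y_offset_frac, y_noise_frac = y_noise_frac,
         dropout_prob = dropout_prob, collide_prob = collide_prob),
    class = "extraction_error_model")
  for (f in names(err)) {
    v <- err[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("extraction_error_model: field '", f,
           "' must be a finite numeric scalar", call. = FALSE)
  }
  if (err$x_drift <= 0)
    stop("extraction_error_model: field 'x_drift' must be > 0", call. = FALSE)
  for (f in c("dropout_prob", "collide_prob")) {
    if (err[[f]] < 0 || err[[f]] >= 1)
      stop("extraction_error_model: field '", f, "' must lie in [0, 1)",
           call. = FALSE)
  }
  err
}

#' @export
print.extraction_error_model <- function(x, ...) {
  cat("Digitization error model:\n")
  cat(sprintf("  time:    offset %+g periods, drift x%g, collide_prob %g\n",
              x$x_offset, x$x_drift, x$collide_prob))
  cat(sprintf("  outcome: offset %+g of range, jitter SD %g of range\n",
              x$y_offset_frac, x$y_noise_frac))
  cat(sprintf("  dropout: %g per point\n", x$dropout_prob))
  invisible(x)
}

#' Simulate a ground-truth interrupted time series
#'
#' Draws one series from the segmented-regression model with stationary AR(1)
#' errors described in [series_spec()]. Points sit at consecutive integer
#' times 1..n; the interruption indicator is 0 for the first `n_pre` points
#' and 1 from point `n_pre + 1` onward, so the interruption time is
#' `n_pre + 1`. The AR(1) error is initialised from its stationary
#' distribution (variance \eqn{\sigma_w^2 / (1 - \rho^2)}) so that every
#' point shares the same marginal error variance.
#'
#' @param spec An [series_spec()] object.
#' @param seed Integer seed; the function is deterministic given
#'   `(spec, seed)`.
#' @return An object of class `provided_series`: a list with `times`
#'   (1..n), `values`, `n_pre`, `interruption_index` (= n_pre + 1), and
#'   the generating `spec`.
#' @export
simulate_true_series <- function(spec, seed = NULL) {
  validate_series_spec(spec)
  if (!is.null(seed)) set.seed(as.integer(seed))
  n <- spec$n_pre + spec$n_post
  t <- seq_len(n)
  ti <- spec$n_pre + 1L
  d <- as.numeric(t >= ti)
  mu <- spec$beta0 + spec$beta1 * t + spec$beta2 * d + spec$beta3 * (t - ti) * d
  eps <- ar1_noise(n, spec$rho, spec$sigma_w)
  structure(
    list(times = t, values = mu + eps, n_pre = spec$n_pre,
         interruption_index = ti, spec = spec),
    class = "provided_series")
}

# Stationary AR(1) path: eps_1 ~ N(0, sigma_w^2/(1-rho^2)),
# eps_t = rho*eps_{t-1} + w_t. Degenerate sigma_w = 0 gives all zeros.
ar1_noise <- function(n, rho, sigma_w) {
  if (sigma_w == 0) return(numeric(n))
  eps <- numeric(n)
  eps[1L] <- stats::rnorm(1L, sd = sigma_w / sqrt(1 - rho^2))
  if (n > 1L) {
    w <- stats::rnorm(n - 1L, sd = sigma_w)
    for (i in 2:n) eps[i] <- rho * eps[i - 1L] + w[i - 1L]
  }
  eps
}

#' @export
print.provided_series <- function(x, ...) {
  cat(sprintf("Provided ITS series: %d points (%d pre, %d post), interruption at t = %d\n",
              length(x$times), x$n_pre, length(x$times) - x$n_pre,
              x$interruption_index))
  invisible(x)
}

#' Apply a digitization error model to a provided series
#'
#' Simulates the act of digitally extracting a plotted series: extracted
#' times are `x_offset + x_drift * t` with, optionally, collisions in which
#' a point's time is set equal to its left neighbour's extracted time
#' (mimicking software rounding two observations onto one time point);
#' extracted outcome values are the provided values plus a constant offset
#' and Gaussian jitter, both expressed as fractions of the provided outcome
#' range; dropped-out points are removed. The result records which provided
#' point indices survived.
#'
#' @param series A `provided_series`.
#' @param err An [extraction_error_model()].
#' @param seed Integer seed; deterministic given `(series, err, seed)`.
#' @param source_id,extractor_id Identifiers carried through to downstream
#'   bookkeeping.
#' @return An object of class `raw_extraction` (see [read_xy_csv()]) with an
#'   additional `provided_index` field (which provided points survived) and
#'   an `all_dropped` flag set when every point was dropped.
#' @export
apply_extraction_error <- function(series, err, seed = NULL,
                                   source_id = "sim", extractor_id = "e1") {
  stopifnot(inherits(series, "provided_series"))
  if (length(series$times) == 0L) stop("apply_extraction_error: empty series")
  if (!inherits(err, "extraction_error_model"))
    stop("apply_extraction_error: 'err' must be an extraction_error_model")
  if (!is.null(seed)) set.seed(as.integer(seed))
  t <- series$times
  y <- series$values
  n <- length(t)
  rng <- diff(range(y))

  x_new <- err$x_offset + err$x_drift * t
  if (err$collide_prob > 0 && n > 1L) {
    collide <- stats::runif(n) < err$collide_prob
    collide[1L] <- FALSE
    for (i in which(collide)) x_new[i] <- x_new[i - 1L]
  }
  y_new <- y + err$y_offset_frac * rng
  if (err$y_noise_frac > 0)
    y_new <- y_new + stats::rnorm(n, sd = err$y_noise_frac * rng)

  keep <- if (err$dropout_prob > 0) stats::runif(n) >= err$dropout_prob
          else rep(TRUE, n)
  structure(
    list(x = x_new[keep], y = y_new[keep],
         provided_index = which(keep),
         all_dropped = !any(keep),
         source_id = source_id, extractor_id = extractor_id),
    class = "raw_extraction")
}

#' Default cohort samplers
#'
#' `default_spec_sampler()` draws series specifications whose lengths span
#' the kind of cohort seen in published ITS studies (total length roughly
#' log-normal around a median of 40 points, truncated to 7..188, with the
#' interruption placed between 30% and 70% of the way through), moderate
#' positive autocorrelation, and interruption effects of a few noise SDs.
#' `default_extractor_errors()` returns four digitization error profiles of
#' increasing severity: a near-perfect extractor; a small-jitter extractor;
#' one with a constant half-period time offset; and one with time-scale
#' drift, a half-period offset, dropout and collisions — the spread of
#' behaviour reported for human extractors.
#'
#' @param seed Integer seed for the sampled spec.
#' @return `default_spec_sampler()`: a function `(seed) -> its_series_spec`;
#'   `default_extractor_errors()`: a named list of
#'   [extraction_error_model()]s.
#' @export
default_spec_sampler <- function() {
  function(seed) {
    set.seed(as.integer(seed))
    n <- round(exp(stats::rnorm(1L, mean = log(40), sd = 0.75)))
    n <- max(7L, min(188L, as.integer(n)))
    frac_pre <- stats::runif(1L, 0.3, 0.7)
    n_pre <- max(3L, min(n - 3L, as.integer(round(frac_pre * n))))
    series_spec(
      n_pre = n_pre, n_post = n - n_pre,
      beta0 = stats::runif(1L, 5, 20),
      beta1 = stats::runif(1L, -0.5, 0.5),
      beta2 = stats::runif(1L, -4, 4),
      beta3 = stats::runif(1L, -0.3, 0.3),
      rho = stats::runif(1L, 0, 0.4),
      sigma_w = 1)
  }
}

#' @rdname default_spec_sampler
#' @export
default_extractor_errors <- function() {
  # Per-series samplers. Each draws, for one series, the error model of a
  # human extractor: a half-period time offset in a minority of series
  # (the important-error rates observed across extractors span roughly
  # 10-35%), otherwise a small offset; a time scale that is correct
  # except for an occasional 1.08-style axis mis-calibration by the
  # weakest extractor; outcome jitter well under 1% of range; and rare
  # per-point dropout sized so that a minority of series (about 2-16%
  # at typical series lengths) have any missing point. Collisions (two
  # points rounding onto one time unit) affect only the weakest profile.
  mk <- function(p_offset, y_noise, dropout, collide = 0, p_big_drift = 0) {
    function(seed) {
      set.seed(as.integer(seed))
      off <- if (stats::runif(1L) < p_offset) sample(c(-0.5, 0.5), 1L)
             else stats::rnorm(1L, 0, 0.02)
      drift <- if (stats::runif(1L) < p_big_drift) 1.08 else 1
      extraction_error_model(
        x_offset = off, x_drift = drift,
        y_noise_frac = y_noise, dropout_prob = dropout,
        collide_prob = collide)
    }
  }
  list(
    e1 = mk(p_offset = 0.10, y_noise = 0.002, dropout = 0.001),
    e2 = mk(p_offset = 0.20, y_noise = 0.003, dropout = 0.0005),
    e3 = mk(p_offset = 0.30, y_noise = 0.005, dropout = 0.001),
    e4 = mk(p_offset = 0.35, y_noise = 0.008, dropout = 0.004,
            collide = 0.005, p_big_drift = 0.025))
}

# Child-seed scheme: master seed plus a large odd stride times a counter,
# reduced modulo 2^31 - 1 so streams stay valid 32-bit seeds.
child_seed <- function(master, counter) {
  as.integer((as.double(master) + 1000003 * as.double(counter)) %% 2147483647)
}

#' Generate a paired provided/extracted synthetic cohort
#'
#' Simulates `n_series` ground-truth series and, for each, one digitized
#' extraction per error profile in `err_models`. Per-series and
#' per-extraction seeds are derived from the master seed by a counter
#' scheme, so the whole cohort is reproducible and individual series are
#' independent streams.
#'
#' @param n_series Number of provided series (>= 1).
#' @param spec_sampler Function `(seed) -> its_series_spec`; defaults to
#'   [default_spec_sampler()].
#' @param err_models One entry per simulated extractor, each either a
#'   fixed [extraction_error_model()] or a sampler function
#'   `(seed) -> extraction_error_model` drawn anew for every series;
#'   defaults to [default_extractor_errors()].
#' @param seed Master integer seed.
#' @return An object of class `its_cohort`: a list of groups, each with
#'   `series_id`, `provided` (a `provided_series`) and `extractions` (a
#'   named list of `raw_extraction`s).
#' @export
generate_cohort <- function(n_series = 43L,
                            spec_sampler = default_spec_sampler(),
                            err_models = default_extractor_errors(),
                            seed = 1L) {
  n_series <- as.integer(n_series)
  if (n_series < 1L) stop("generate_cohort: n_series must be >= 1")
  if (length(err_models) < 1L) stop("generate_cohort: need >= 1 error model")
  if (is.null(names(err_models)))
    names(err_models) <- paste0("e", seq_along(err_models))
  groups <- vector("list", n_series)
  k <- length(err_models)
  for (i in seq_len(n_series)) {
    base <- (i - 1L) * (2L * k + 2L)
    spec <- spec_sampler(child_seed(seed, base))
    prov <- simulate_true_series(spec, seed = child_seed(seed, base + 1L))
    extr <- vector("list", k)
    names(extr) <- names(err_models)
    for (j in seq_len(k)) {
      em <- err_models[[j]]
      if (is.function(em)) em <- em(child_seed(seed, base + 1L + k + j))
      extr[[j]] <- apply_extraction_error(
        prov, em, seed = child_seed(seed, base + 1L + j),
        source_id = sprintf("s%02d", i), extractor_id = names(err_models)[j])
    }
    groups[[i]] <- list(series_id = sprintf("s%02d", i),
                        provided = prov, extractions = extr)
  }
  structure(groups, class = "its_cohort")
}

#' @export
print.its_cohort <- function(x, ...) {
  n_ex <- if (length(x)) length(x[[1L]]$extractions) else 0L
  cat(sprintf("Synthetic ITS cohort: %d provided series x %d extractors (%d extractions)\n",
              length(x), n_ex, length(x) * n_ex))
  invisible(x)
}

#' Write a cohort to disk in the digitizer export dialect
#'
#' Each provided series and each extraction is written as a headerless
#' two-column x,y CSV (the dialect digital plot-extraction software
#' exports), and a JSON manifest records series ids, extractor ids, file
#' paths, interruption specifications and true generating parameters.
#'
#' @param cohort An `its_cohort`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the manifest path.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "its_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  entries <- list()
  for (g in cohort) {
    pfile <- file.path(dir, paste0(g$series_id, "_provided.csv"))
    utils::write.table(
      data.frame(x = g$provided$times, y = g$provided$values),
      pfile, sep = ",", row.names = FALSE, col.names = FALSE)
    files <- list(provided = basename(pfile))
    for (ex in names(g$extractions)) {
      efile <- file.path(dir, paste0(g$series_id, "_", ex, ".csv"))
      utils::write.table(
        data.frame(x = g$extractions[[ex]]$x, y = g$extractions[[ex]]$y),
        efile, sep = ",", row.names = FALSE, col.names = FALSE)
      files[[ex]] <- basename(efile)
    }
    sp <- g$provided$spec
    entries[[g$series_id]] <- list(
      series_id = g$series_id,
      n_pre = sp$n_pre, n_post = sp$n_post,
      interruption = list(mode = "pre_count", n_pre = sp$n_pre),
      grid = list(origin = 0, step = 1),
      truth = list(beta = c(sp$beta0, sp$beta1, sp$beta2, sp$beta3),
                   rho = sp$rho, sigma_w = sp$sigma_w),
      files = files)
  }
  manifest <- file.path(dir, "manifest.json")
  jsonlite::write_json(list(series = entries), manifest,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
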