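#' Study configuration
#'
#' Bundles every knob of a full agreement study: either simulate a
#' synthetic cohort (`mode = "simulate"`) or load digitized series from a
#' manifest on disk (`mode = "load"`), the estimator policy, the
#' interruption mode, the confidence level, the p-value categorisation
#' scheme, the master seed, and the output directory.
#'
#' @param mode `"simulate"` or `"load"`.
#' @param n_series,spec_sampler,err_models Cohort parameters (simulate
#'   mode); see [generate_cohort()].
#' @param manifest Path to a cohort manifest JSON (load mode), as written
#'   by [write_cohort()].
#' @param estimator Fitting policy, see [fit_series_group()].
#' @param interruption_mode `"pre_count"` or `"date"`.
#' @param count_gaps Under `pre_count`, count grid slots so that detected
#'   gaps (noted missing points, collapsed duplicates) still count as time
#'   points, as an analyst aware of them would (default TRUE); see
#'   [resolve_interruption()].
#' @param ci_level Confidence level.
#' @param p_scheme `"dichotomous"` or `"fine"` (both are always computed;
#'   this selects which drives the headline concordance).
#' @param seed Master seed.
#' @param out_dir Output directory for the report bundle, or `NULL` to
#'   skip writing files.
#' @return An object of class `study_config`.
#' @export
study_config <- function(mode = c("simulate", "load"),
                         n_series = 43L,
                         spec_sampler = default_spec_sampler(),
                         err_models = default_extractor_errors(),
                         manifest = NULL,
                         estimator = "reml_with_ols_fallback",
                         interruption_mode = "pre_count",
                         count_gaps = TRUE,
                         ci_level = 0.95,
                         p_scheme = "dichotomous",
                         seed = 1L,
                         out_dir = NULL) {
  structure(
    list(mode = match.arg(mode), n_series = as.integer(n_series),
         spec_sampler = spec_sampler, err_models = err_models,
         manifest = manifest, estimator = estimator,
         interruption_mode = interruption_mode, count_gaps = isTRUE(count_gaps),
         ci_level = ci_level,
         p_scheme = p_scheme, seed = as.integer(seed), out_dir = out_dir),
    class = "study_config")
}

#' Validate a study configuration
#'
#' Checks every invariant and returns the full list of violations at once
#' (an empty character vector means the configuration is valid).
#'
#' @param config A [study_config()].
#' @return Character vector of error messages (possibly empty).
#' @export
validate_config <- function(config) {
  errs <- character(0)
  if (!inherits(config, "study_config"))
    return("config must be created by study_config()")
  if (!config$mode %in% c("simulate", "load"))
    errs <- c(errs, "mode must be 'simulate' or 'load'")
  if (config$mode == "simulate") {
    if (!is.null(config$manifest))
      errs <- c(errs, "manifest must not be set in simulate mode")
    if (is.na(config$n_series) || config$n_series < 1L)
      errs <- c(errs, "n_series must be >= 1")
    if (!is.function(config$spec_sampler))
      errs <- c(errs, "spec_sampler must be a function")
    if (length(config$err_models) < 1L)
      errs <- c(errs, "need at least one extractor error model")
  } else {
    if (is.null(config$manifest))
      errs <- c(errs, "manifest path required in load mode")
    else if (!file.exists(config$manifest))
      errs <- c(errs, paste0("manifest not found: ", config$manifest))
  }
  if (!config$estimator %in% c("reml_with_ols_fallback", "reml", "ols"))
    errs <- c(errs, "unknown estimator policy")
  if (!config$interruption_mode %in% c("pre_count", "date"))
    errs <- c(errs, "interruption_mode must be 'pre_count' or 'date'")
  if (!is.numeric(config$ci_level) || config$ci_level <= 0 || config$ci_level >= 1)
    errs <- c(errs, "ci_level must lie in (0, 1)")
  if (!config$p_scheme %in% c("dichotomous", "fine"))
    errs <- c(errs, "p_scheme must be 'dichotomous' or 'fine'")
  if (is.na(config$seed))
    errs <- c(errs, "seed must be an integer")
  errs
}

# Load a cohort written by write_cohort() (or hand-written in the same
# layout) back into the in-memory group structure.
load_cohort <- function(manifest_path) {
  man <- jsonlite::read_json(manifest_path, simplifyVector = FALSE)
  dir <- dirname(manifest_path)
  groups <- lapply(man$series, function(e) {
    praw <- read_xy_csv(file.path(dir, e$files$provided),
                        source_id = e$series_id, extractor_id = "provided")
    n <- length(praw$x)
    prov <- structure(
      list(times = seq_len(n), values = praw$y, n_pre = e$n_pre,
           interruption_index = e$n_pre + 1L, spec = NULL),
      class = "provided_series")
    ex_names <- setdiff(names(e$files), "provided")
    extr <- lapply(ex_names, function(ex)
      read_xy_csv(file.path(dir, e$files[[ex]]),
                  source_id = e$series_id, extractor_id = ex))
    names(extr) <- ex_names
    list(series_id = e$series_id, provided = prov, extractions = extr,
         grid = e$grid, interruption = e$interruption)
  })
  names(groups) <- NULL
  structure(groups, class = "its_cohort")
}

# Ingest + fit + calibrate one group; returns per-source standardized
# effects, calibration results and fit metadata.
analyze_group <- function(group, estimator, interruption_mode, ci_level,
                          count_gaps = TRUE) {
  prov <- group$provided
  grid <- group$grid %||% list(origin = 0, step = 1)
  n_pre <- if (!is.null(group$interruption)) group$interruption$n_pre else prov$n_pre
  prov_range <- diff(range(prov$values))

  datasets <- list(provided = as_extracted_series(prov))
  calibs <- list()
  for (ex in names(group$extractions)) {
    raw <- group$extractions[[ex]]
    snapped <- snap_to_grid(raw, grid_origin = grid$origin,
                            grid_step = grid$step)
    ispec <- if (interruption_mode == "pre_count")
      interruption_spec("pre_count", n_pre = n_pre)
    else
      interruption_spec("date", interruption_time = n_pre + 1)
    snapped <- resolve_interruption(snapped, ispec, count_gaps = count_gaps)
    snapped$n_missing_vs_reference <-
      length(prov$times) - length(snapped$times)
    datasets[[ex]] <- snapped

    for (axis in c("time", "outcome")) {
      paired <- pair_points(prov, raw, axis = axis)
      cal <- calibration_regression(paired, series_id = group$series_id,
                                    extractor_id = ex)
      cal <- if (axis == "time")
        standardize_calibration(cal,
                                series_length_native = diff(range(prov$times)),
                                n_periods = length(prov$times) - 1L)
      else
        standardize_calibration(cal, provided_range = prov_range)
      if (axis == "time")
        cal <- flag_important_error(cal, observed_span = prov$times)
      calibs[[paste(ex, axis, sep = ".")]] <- cal
    }
  }

  fits <- fit_series_group(datasets, estimator = estimator,
                           ci_level = ci_level)
  effects <- do.call(rbind, lapply(names(fits), function(src) {
    eff <- standardize_effect(effect_estimates(fits[[src]]), prov_range,
                              source_id = src)
    eff$series_id <- group$series_id
    eff
  }))
  list(series_id = group$series_id, effects = effects, calibrations = calibs,
       estimator_used = attr(fits, "estimator_used"),
       converged = vapply(fits, `[[`, logical(1L), "converged"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run a full digitization-agreement study
#'
#' Simulates (or loads) a cohort of provided series with per-extractor
#' digitized versions, fits the segmented AR(1) model to every dataset
#' under the configured estimator policy, quantifies extraction errors by
#' calibration regression, and computes all pairwise agreement statistics
#' (Bland-Altman limits of agreement for range-standardised level and
#' slope changes, geometric-mean SE ratios, CI width ratios, p-category
#' concordance). A failure in one series is recorded and the run continues
#' for the remaining series.
#'
#' Orientation conventions: effect differences are `row source - column
#' source`; SE ratios are `row / column`, reported as computed with the
#' provided data as the comparator in headline tables. These are recorded
#' in the returned `meta`.
#'
#' @param config A [study_config()]; validated before running.
#' @return An object of class `its_study`: list with `effects` (per-series
#'   standardized effects, all sources), `error_summary` (per-extractor
#'   calibration summary), `agreement` (per comparison x effect),
#'   `concordance` (per comparison x effect x scheme), `ci_widths`
#'   (per-series scaled width ratios), `failures`, `meta`. If
#'   `config$out_dir` is set the bundle is also written as CSV/JSON.
#' @export
run_study <- function(config) {
  errs <- validate_config(config)
  if (length(errs) > 0L)
    stop("invalid study config:\n  - ", paste(errs, collapse = "\n  - "))

  cohort <- if (config$mode == "simulate") {
    generate_cohort(config$n_series, config$spec_sampler,
                    config$err_models, seed = config$seed)
  } else {
    load_cohort(config$manifest)
  }

  results <- list(); failures <- list()
  for (g in cohort) {
    res <- tryCatch(
      analyze_group(g, config$estimator, config$interruption_mode,
                    config$ci_level, count_gaps = config$count_gaps),
      error = function(e) e)
    if (inherits(res, "error")) {
      failures[[g$series_id]] <- conditionMessage(res)
    } else {
      results[[g$series_id]] <- res
    }
  }
  if (length(results) == 0L) stop("run_study: every series failed")

  effects <- do.call(rbind, lapply(results, `[[`, "effects"))
  rownames(effects) <- NULL
  calibs <- unlist(lapply(results, `[[`, "calibrations"), recursive = FALSE)
  error_summary <- summarize_extractor(calibs)

  sources <- unique(effects$source_id)
  agreement <- list(); conc <- list(); ci_rows <- list()
  # pairwise limits of agreement are undefined for fewer than two series
  # and are reported as absent
  eff_types <- if (length(results) >= 2L) unique(effects$effect) else character(0)
  for (eff_type in eff_types) {
    sub <- effects[effects$effect == eff_type, ]
    wide <- function(col) {
      m <- tapply(sub[[col]], list(sub$series_id, sub$source_id), identity)
      m[, sources, drop = FALSE]
    }
    est <- wide("estimate_std"); se <- wide("se_std")
    cil <- wide("ci_low_std"); cih <- wide("ci_high_std"); pv <- wide("p")
    for (i in seq_along(sources)) for (j in seq_along(sources)) {
      if (i >= j) next
      a <- sources[i]; b <- sources[j]
      cmp <- paste(a, "vs", b)
      ba <- bland_altman(est[, a], est[, b], comparison = cmp)
      sr <- se_ratio_stats(se[, a], se[, b], comparison = cmp)
      agreement[[length(agreement) + 1L]] <- data.frame(
        effect = eff_type, comparison = cmp, n_series = ba$n_series,
        mean_diff = ba$mean_diff, sd_diff = ba$sd_diff,
        loa_low = ba$loa_low, loa_high = ba$loa_high,
        median_diff = ba$median_diff,
        iqr_low = ba$iqr_low, iqr_high = ba$iqr_high,
        gm_se_ratio = sr$gm_ratio,
        gm_se_loa_low = sr$loa_low, gm_se_loa_high = sr$loa_high)
      for (scheme in c("dichotomous", "fine")) {
        cc <- concordance(categorize_p(pv[, a], scheme),
                          categorize_p(pv[, b], scheme))
        conc[[length(conc) + 1L]] <- data.frame(
          effect = eff_type, comparison = cmp, scheme = scheme,
          percent_agree = cc$percent_agree,
          n_discordant = cc$n_discordant)
      }
      for (s in rownames(est)) {
        cr <- ci_ratio_scaled(c(cil[s, a], cih[s, a]),
                              c(cil[s, b], cih[s, b]),
                              est[s, a], est[s, b])
        ci_rows[[length(ci_rows) + 1L]] <- data.frame(
          effect = eff_type, comparison = cmp, series_id = s,
          width_ratio = cr$width_ratio,
          ci_low_scaled = cr$ci_a_scaled[1L],
          ci_high_scaled = cr$ci_a_scaled[2L])
      }
    }
  }

  study <- structure(
    list(effects = effects,
         error_summary = error_summary,
         agreement = if (length(agreement)) do.call(rbind, agreement),
         concordance = if (length(conc)) do.call(rbind, conc),
         ci_widths = if (length(ci_rows)) do.call(rbind, ci_rows),
         estimator_used = vapply(results, `[[`, character(1L),
                                 "estimator_used"),
         failures = failures,
         meta = list(
           mode = config$mode, seed = config$seed,
           estimator_policy = config$estimator,
           interruption_mode = config$interruption_mode,
           count_gaps = config$count_gaps,
           ci_level = config$ci_level, p_scheme = config$p_scheme,
           n_series_analyzed = length(results),
           n_series_failed = length(failures),
           orientation = list(
             effect_diff = "row source - column source",
             se_ratio = "row source / column source"),
           package_version = as.character(utils::packageVersion("itsagree")))),
    class = "its_study")

  if (!is.null(config$out_dir)) write_study(study, config$out_dir)
  study
}

#' @export
print.its_study <- function(x, ...) {
  cat(sprintf("ITS digitization agreement study: %d series analyzed (%d failed), policy %s\n",
              x$meta$n_series_analyzed, x$meta$n_series_failed,
              x$meta$estimator_policy))
  n_reml <- sum(x$estimator_used == "REML_AR1")
  cat(sprintf("  %d series groups fitted with REML(AR1), %d with OLS fallback\n",
              n_reml, length(x$estimator_used) - n_reml))
  vs_prov <- x$agreement[grepl("provided", x$agreement$comparison), ]
  if (nrow(vs_prov)) {
    hw <- (vs_prov$loa_high - vs_prov$loa_low) / 2
    cat(sprintf("  largest LoA half-width vs provided: %.4f (%s, %s)\n",
                max(hw), vs_prov$effect[which.max(hw)],
                vs_prov$comparison[which.max(hw)]))
  }
  invisible(x)
}

# Write the report bundle: tidy CSVs plus a JSON manifest.
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wcsv <- function(df, name)
    utils::write.csv(df, file.path(dir, name), row.names = FALSE)
  wcsv(study$effects, "effects.csv")
  wcsv(study$error_summary, "error_summary.csv")
  wcsv(study$agreement, "agreement.csv")
  wcsv(study$concordance, "concordance.csv")
  wcsv(study$ci_widths, "ci_widths.csv")
  jsonlite::write_json(
    c(study$meta, list(failures = study$failures,
                       estimator_used = as.list(study$estimator_used))),
    file.path(dir, "study_manifest.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
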