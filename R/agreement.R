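#' Range-standardise interruption effect estimates
#'
#' Different series measure different outcomes, so level and slope changes
#' are made comparable by dividing estimate, standard error and confidence
#' bounds by the outcome range (max - min) of the *provided* series —
#' always the provided series' range, for every data source in a group, so
#' sources remain on a common scale. P-values are untouched.
#'
#' @param effects Data frame from [effect_estimates()].
#' @param provided_range Outcome range of the provided series (> 0).
#' @param source_id Label for the data source (e.g. `"provided"`, `"e1"`).
#' @return Data frame with columns `effect`, `estimate_std`, `se_std`,
#'   `ci_low_std`, `ci_high_std`, `p`, `source_id`.
#' @export
standardize_effect <- function(effects, provided_range, source_id = NA_character_) {
  if (!is.finite(provided_range) || provided_range <= 0)
    stop("standardize_effect: provided_range must be > 0")
  data.frame(
    effect = effects$effect,
    estimate_std = effects$estimate / provided_range,
    se_std = effects$se / provided_range,
    ci_low_std = effects$ci_low / provided_range,
    ci_high_std = effects$ci_high / provided_range,
    p = effects$p,
    source_id = source_id,
    row.names = NULL)
}

#' Bland-Altman agreement statistics for paired per-series values
#'
#' For one pairwise comparison of data sources across a set of series,
#' computes the per-series differences `a - b`, their mean, SD (n - 1
#' denominator), 95% limits of agreement (mean +/- 1.96 SD), median and
#' interquartile range (25th/75th centiles), together with the per-series
#' averages `(a + b)/2` used as the x-axis of a Bland-Altman plot.
#'
#' @param a,b Numeric vectors of per-series values from sources A and B,
#'   aligned element-wise (same series in the same order). Named vectors
#'   are checked for matching names.
#' @param comparison Label, e.g. `"e1 vs provided"`.
#' @return An object of class `agreement_stats`.
#' @export
bland_altman <- function(a, b, comparison = NA_character_) {
  if (length(a) != length(b))
    stop("bland_altman: length mismatch (", length(a), " vs ", length(b), ")")
  if (length(a) < 2L) stop("bland_altman: need >= 2 paired series")
  if (!is.null(names(a)) && !is.null(names(b)) && !identical(names(a), names(b)))
    stop("bland_altman: series sets differ: ",
         paste(union(setdiff(names(a), names(b)),
                     setdiff(names(b), names(a))), collapse = ", "))
  d <- a - b
  m <- mean(d); s <- stats::sd(d)
  q <- iqr_quantiles(d)
  structure(
    list(comparison = comparison, n_series = length(d),
         mean_diff = m, sd_diff = s,
         loa_low = m - 1.96 * s, loa_high = m + 1.96 * s,
         median_diff = stats::median(d), iqr_low = q[1L], iqr_high = q[2L],
         differences = d, averages = (a + b) / 2),
    class = "agreement_stats")
}

#' @export
print.agreement_stats <- function(x, digits = 4, ...) {
  cat(sprintf("Agreement (%s), n = %d series\n", x$comparison, x$n_series))
  cat(sprintf("  mean difference %.*f, 95%% LoA (%.*f, %.*f)\n",
              digits, x$mean_diff, digits, x$loa_low, digits, x$loa_high))
  cat(sprintf("  median %.*f, IQR (%.*f, %.*f)\n",
              digits, x$median_diff, digits, x$iqr_low, digits, x$iqr_high))
  invisible(x)
}

#' Geometric-mean ratio of standard errors with limits of agreement
#'
#' Standard errors are compared on the log scale (removing the dependence
#' of difference variability on SE magnitude): the per-series
#' `log(a) - log(b)` differences are summarised as in [bland_altman()] and
#' then exponentiated, giving the geometric mean ratio of standard errors
#' and ratio-scale limits of agreement.
#'
#' @param a_se,b_se Positive per-series standard errors, aligned.
#' @param comparison Label.
#' @return List with `gm_ratio`, `loa_low`, `loa_high` (ratio scale),
#'   `median_ratio`, `iqr_low`, `iqr_high`, `n_series`, and the underlying
#'   log-scale `agreement_stats` as `log_stats`.
#' @export
se_ratio_stats <- function(a_se, b_se, comparison = NA_character_) {
  if (any(a_se <= 0) || any(b_se <= 0))
    stop("se_ratio_stats: standard errors must be > 0")
  ba <- bland_altman(log(a_se), log(b_se), comparison = comparison)
  list(comparison = comparison, n_series = ba$n_series,
       gm_ratio = exp(ba$mean_diff),
       loa_low = exp(ba$loa_low), loa_high = exp(ba$loa_high),
       median_ratio = exp(ba$median_diff),
       iqr_low = exp(ba$iqr_low), iqr_high = exp(ba$iqr_high),
       log_stats = ba)
}

#' Scale a confidence interval pair to a comparator-spanned axis
#'
#' Applies the affine map that sends the comparator interval `ci_b` to
#' \[-0.5, 0.5\] — `x -> (x - midpoint(ci_b)) / width(ci_b)` — to the
#' interval `ci_a` and both point estimates, so intervals from many series
#' can be drawn on one axis with the comparator as the shaded reference
#' band. The width ratio `width(ci_a)/width(ci_b)` is returned alongside.
#'
#' @param ci_a,ci_b Length-2 numeric intervals (low, high).
#' @param est_a,est_b Point estimates (optional).
#' @return List with `ci_a_scaled`, `est_a_scaled`, `est_b_scaled`,
#'   `width_ratio`.
#' @export
ci_ratio_scaled <- function(ci_a, ci_b, est_a = NA_real_, est_b = NA_real_) {
  if (diff(ci_b) <= 0) stop("ci_ratio_scaled: zero-width comparator interval")
  if (diff(ci_a) <= 0) stop("ci_ratio_scaled: degenerate interval ci_a")
  mid_b <- mean(ci_b); w_b <- diff(ci_b)
  scale <- function(x) (x - mid_b) / w_b
  list(ci_a_scaled = scale(ci_a),
       est_a_scaled = scale(est_a), est_b_scaled = scale(est_b),
       width_ratio = diff(ci_a) / w_b)
}

#' Categorise a p-value by level of statistical significance
#'
#' Two schemes: `"dichotomous"` splits at the 5% significance level with a
#' strict inequality (`< 0.05` vs `>= 0.05`); `"fine"` uses the gradation
#' `<= 0.01`, `(0.01, 0.05]`, `(0.05, 0.1]`, `> 0.1` (closed on the
#' right at each cut).
#'
#' @param p P-value(s) in (0, 1].
#' @param scheme `"dichotomous"` or `"fine"`.
#' @return Character vector of category labels.
#' @export
categorize_p <- function(p, scheme = c("dichotomous", "fine")) {
  scheme <- match.arg(scheme)
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1))
    stop("categorize_p: p must lie in (0, 1]")
  if (scheme == "dichotomous") {
    ifelse(p < 0.05, "<0.05", ">=0.05")
  } else {
    cut(p, breaks = c(0, 0.01, 0.05, 0.1, 1),
        labels = c("<=0.01", "(0.01,0.05]", "(0.05,0.1]", ">0.1"),
        include.lowest = TRUE, right = TRUE) |> as.character()
  }
}

#' Concordance of p-value significance categories
#'
#' Percentage of series for which two sources fall in the same
#' significance category, with a cross-tabulation of the discordant pairs.
#' Under the fine scheme the categories are ordered, so each discordant
#' pair is additionally classed as adjacent or not (discordance between
#' sources, when it occurs, tends to land in the adjacent category).
#'
#' @param labels_a,labels_b Equal-length character vectors of category
#'   labels (from [categorize_p()], same scheme).
#' @return List with `percent_agree`, `n_series`, `n_discordant`,
#'   `discordant` (data frame of discordant label pairs with `adjacent`),
#'   `table` (full cross-tabulation).
#' @export
concordance <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b))
    stop("concordance: label sequences differ in length (",
         length(labels_a), " vs ", length(labels_b), ")")
  agree <- labels_a == labels_b
  lev <- c("<0.05", ">=0.05", "<=0.01", "(0.01,0.05]", "(0.05,0.1]", ">0.1")
  ord <- function(l) match(l, lev)
  disc <- data.frame(a = labels_a[!agree], b = labels_b[!agree])
  disc$adjacent <- abs(ord(disc$a) - ord(disc$b)) == 1L
  list(percent_agree = 100 * mean(agree),
       n_series = length(agree),
       n_discordant = sum(!agree),
       discordant = disc,
       table = table(a = labels_a, b = labels_b))
}
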