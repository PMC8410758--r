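#' Chi-square upper tail probability
#'
#' @param stat Non-negative test statistic.
#' @param df Degrees of freedom, > 0.
#' @return The survival probability `P(X >= stat)` for X ~ chi-square(df).
#' @export
chi2_upper_tail <- function(stat, df) {
  if (any(stat < 0)) stop_cfg("'stat' must be non-negative")
  if (any(df <= 0)) stop_cfg("'df' must be positive")
  stats::pchisq(stat, df, lower.tail = FALSE)
}

#' Two-sided p-value from a z-score
#'
#' @param z Finite z-score(s).
#' @return `2 * P(Z >= |z|)` for a standard normal Z.
#' @export
p_from_z <- function(z) {
  if (any(!is.finite(z))) stop_cfg("'z' must be finite")
  2 * stats::pnorm(-abs(z))
}

#' Two-sided p-value from a t statistic
#'
#' @param t t statistic.
#' @param df Degrees of freedom (possibly fractional, as from a
#'   Welch-Satterthwaite approximation).
#' @return `2 * P(T >= |t|)` for T ~ Student-t(df).
#' @export
p_from_t <- function(t, df) {
  if (any(!is.finite(t))) stop_cfg("'t' must be finite")
  if (any(df <= 0)) stop_cfg("'df' must be positive")
  2 * stats::pt(-abs(t), df)
}

#' Welch two-sample t-test
#'
#' Unequal-variance two-sample t statistic with Satterthwaite degrees of
#' freedom and two-sided p-value. When both samples have zero variance and
#' equal means the statistic is 0 with p = 1 (rather than the error
#' `stats::t.test()` raises on constant data).
#'
#' @param a,b Numeric samples, each of length >= 2.
#' @return A list of class `t_test_result` with `t_stat`, `df`
#'   (possibly fractional), `p_value`, `estimate` (mean difference a - b).
#' @export
welch_t <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2L || length(b) < 2L) stop_cfg("each sample needs n >= 2")
  va <- stats::var(a); vb <- stats::var(b)
  if (va == 0 && vb == 0) {
    if (mean(a) == mean(b))
      return(structure(list(t_stat = 0, df = length(a) + length(b) - 2,
                            p_value = 1, estimate = 0),
                       class = "t_test_result"))
    stop_cfg("both samples constant with different means: t undefined")
  }
  ht <- stats::t.test(a, b, var.equal = FALSE)
  structure(list(t_stat = unname(ht$statistic), df = unname(ht$parameter),
                 p_value = ht$p.value,
                 estimate = unname(diff(rev(ht$estimate)))),
            class = "t_test_result")
}

#' One-sample t-test
#'
#' @param values Numeric sample, n >= 2, with nonzero variance.
#' @param mu0 Null mean.
#' @return A list of class `t_test_result`.
#' @export
one_sample_t <- function(values, mu0 = 0) {
  values <- as.numeric(values)
  if (length(values) < 2L) stop_cfg("need n >= 2")
  if (stats::var(values) == 0) stop_cfg("zero variance: t undefined")
  ht <- stats::t.test(values, mu = mu0)
  structure(list(t_stat = unname(ht$statistic), df = unname(ht$parameter),
                 p_value = ht$p.value,
                 estimate = unname(ht$estimate) - mu0),
            class = "t_test_result")
}

#' @export
print.t_test_result <- function(x, ...) {
  cat(sprintf("t(%.4g) = %.4g, two-sided p = %.4g\n", x$df, x$t_stat, x$p_value))
  invisible(x)
}

#' Reference z-score for one subject
#'
#' Standardizes a raw measurement (e.g. head circumference) against the
#' subject's reference stratum: `z = (value - ref_mean) / ref_sd`.
#'
#' When a reference-norm table is supplied, the stratum row is looked up by
#' `sex` and `age_months`; a missing stratum is an error naming it.
#'
#' @param value Raw measurement.
#' @param ref_mean,ref_sd Reference mean and SD (`ref_sd > 0`); or
#' @param ref Optional reference table with columns `sex`, `age_months`,
#'   `mean`, `sd`; then `sex` and `age_months` select the row.
#' @param sex,age_months Stratum keys, used with `ref`.
#' @param subject_id Optional identifier carried through.
#' @return A list of class `subject_z` with `subject_id`, `raw_value`,
#'   `ref_mean`, `ref_sd`, `z`.
#' @export
subject_z <- function(value, ref_mean = NULL, ref_sd = NULL, ref = NULL,
                      sex = NULL, age_months = NULL, subject_id = NA_character_) {
  if (!is.null(ref)) {
    req <- c("sex", "age_months", "mean", "sd")
    miss <- setdiff(req, names(ref))
    if (length(miss)) stop_cfg("reference table lacks columns: %s",
                               paste(miss, collapse = ", "))
    hit <- ref$sex == sex & ref$age_months == age_months
    if (!any(hit))
      stop_cfg("no reference row for stratum sex=%s, age_months=%s",
               sex, age_months)
    ref_mean <- ref$mean[which(hit)[1L]]
    ref_sd <- ref$sd[which(hit)[1L]]
  }
  if (is.null(ref_mean) || is.null(ref_sd))
    stop_cfg("supply ref_mean/ref_sd or a reference table")
  ref_sd <- check_positive(ref_sd, "ref_sd")
  structure(list(subject_id = subject_id, raw_value = value,
                 ref_mean = ref_mean, ref_sd = ref_sd,
                 z = (value - ref_mean) / ref_sd),
            class = "subject_z")
}

#' @export
print.subject_z <- function(x, ...) {
  cat(sprintf("z = (%.4g - %.4g) / %.4g = %.4g\n",
              x$raw_value, x$ref_mean, x$ref_sd, x$z))
  invisible(x)
}

#' Weighted (Stouffer) combination of z-scores
#'
#' \eqn{z = \sum w_i z_i / \sqrt{\sum w_i^2}} with two-sided p-value from
#' the standard normal tail. With equal weights this is the classical
#' Stouffer statistic `mean(z) * sqrt(n)`; weights of `sqrt(n)` per stratum
#' give the sample-size-weighted combination.
#'
#' @param z_values Numeric z-scores.
#' @param weights Non-negative weights, not all zero; default equal.
#' @return A list with `z_combined` and `p_two_sided` (and `p_one_sided`,
#'   the upper tail, since reports differ on which tail they print).
#' @export
combined_weighted_z <- function(z_values, weights = rep(1, length(z_values))) {
  z_values <- as.numeric(z_values); weights <- as.numeric(weights)
  if (length(z_values) != length(weights)) stop_cfg("lengths differ")
  if (any(weights < 0) || all(weights == 0))
    stop_cfg("weights must be non-negative and not all zero")
  z <- sum(weights * z_values) / sqrt(sum(weights^2))
  list(z_combined = z, p_two_sided = p_from_z(z),
       p_one_sided = stats::pnorm(z, lower.tail = FALSE))
}

#' Median of three blinded ordinal scores
#'
#' Ordinal ratings in \{-2, -1, 0, 1, 2\} assigned three times per subject;
#' the recorded value is the middle order statistic.
#'
#' @param scores Exactly three integer scores in \{-2, ..., 2\}.
#' @return The median score (integer).
#' @export
median_score <- function(scores) {
  if (length(scores) != 3L) stop_cfg("exactly 3 scores required")
  if (!all(scores %in% -2:2)) stop_cfg("scores must be integers in -2..2")
  as.integer(sort(scores)[2L])
}
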