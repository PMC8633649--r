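#' Back-calculate the standard error of a pooled estimate from its 95% CI
#'
#' For mean differences the CI is symmetric on the identity scale, so
#' `SE = (upper - lower) / (2 z)`; for ratio measures (RR, OR) the CI is
#' symmetric on the natural-log scale, so `SE = (log upper - log lower) /
#' (2 z)`.  The returned SE is always on the analysis scale (log scale for
#' ratio measures).
#'
#' @param ci_lower,ci_upper Reported 95% CI bounds on the reported scale.
#'   Both must be positive for ratio measures.
#' @param measure Effect-measure code(s): `"MD"`, `"SMD"`, `"RR"`, `"OR"`.
#' @param z The normal quantile assumed to have generated the CI.  The
#'   default `1.959964` is the 97.5% point to six decimals; use `1.96` to
#'   reproduce hand-calculated literature values.
#' @return Numeric vector of standard errors on the analysis scale.
#' @examples
#' back_calculate_se(0.99, 1.83, "OR") # log-scale SE of the worked example
#' back_calculate_se(-1, 1, "MD")
#' @export
back_calculate_se <- function(ci_lower, ci_upper, measure, z = Z975) {
  check_measure(measure)
  n <- max(length(ci_lower), length(ci_upper), length(measure))
  ci_lower <- rep_len(ci_lower, n)
  ci_upper <- rep_len(ci_upper, n)
  measure <- rep_len(measure, n)
  ok <- !is.na(ci_lower) & !is.na(ci_upper)
  if (any(ok & ci_lower >= ci_upper)) {
    abort("ci_lower < ci_upper violated (degenerate or reversed interval).")
  }
  ratio <- is_ratio_measure(measure)
  if (any(ok & ratio & (ci_lower <= 0 | ci_upper <= 0))) {
    abort("ratio CI must be positive")
  }
  lo <- ci_lower
  hi <- ci_upper
  lo[ratio & ok] <- log(ci_lower[ratio & ok])
  hi[ratio & ok] <- log(ci_upper[ratio & ok])
  (hi - lo) / (2 * z)
}

#' Two-sided Wald p-value for a pooled estimate
#'
#' Normal test of the analysis-scale estimate against 0 (which is the null
#' for ratio measures after the log transform): `p = 2 (1 - Phi(|M| / SE))`.
#'
#' @param m Pooled estimate on the analysis scale.
#' @param se_m Standard error of `m`; must be positive.
#' @return p-values in `(0, 1]`.
#' @examples
#' wald_p(log(1.35), back_calculate_se(0.99, 1.83, "OR"))
#' @export
wald_p <- function(m, se_m) {
  if (any(!is.na(se_m) & se_m <= 0)) abort("se_m must be positive")
  2 * pnorm(-abs(m) / se_m)
}

#' 95% prediction interval for a new study's true effect
#'
#' The interval `M +/- t(k - 2, 0.975) * sqrt(tau2 + SE(M)^2)` on the
#' analysis scale, exponentiated back to the reported scale for ratio
#' measures.  It widens with the between-study variance `tau2` and narrows
#' as the number of trials `k` grows; it always contains the recomputed 95%
#' CI because `t(k - 2, 0.975) >= z` and `tau2 >= 0`.
#'
#' @param m Pooled estimate on the analysis scale.
#' @param se_m Standard error of `m` on the analysis scale (positive).
#' @param tau2 Between-study variance estimate (nonnegative; `NA` means the
#'   interval is not computable and yields `NA` bounds).
#' @param k Number of trials; must be at least 3 so that the t distribution
#'   has `k - 2 >= 1` degrees of freedom.
#' @param measure Effect-measure code(s); ratio measures are exponentiated
#'   back to the reported scale.
#' @param df_offset Degrees-of-freedom rule: the t quantile uses
#'   `k - df_offset` df.  The default 2 follows the standard construction;
#'   set 1 for a `k - 1` sensitivity analysis.
#' @return A tibble with columns `lower`, `upper` (reported scale), `kind`
#'   (`"PI95"`), `null_value`, and `significant` (`TRUE` iff the null value
#'   lies outside the interval).
#' @examples
#' prediction_interval(0.5, 0.1, tau2 = 0.04, k = 5)
#' @export
prediction_interval <- function(m, se_m, tau2, k, measure = "MD",
                                df_offset = 2) {
  check_measure(measure)
  n <- max(length(m), length(se_m), length(tau2), length(k), length(measure))
  m <- rep_len(m, n); se_m <- rep_len(se_m, n)
  tau2 <- rep_len(tau2, n); k <- rep_len(k, n)
  measure <- rep_len(as.character(measure), n)
  if (any(!is.na(k) & k < 3)) {
    abort("prediction interval undefined below three trials")
  }
  if (any(!is.na(tau2) & tau2 < 0)) abort("tau2 must be nonnegative")
  if (any(!is.na(se_m) & se_m < 0)) abort("se_m must be nonnegative")
  h <- qt(0.975, k - df_offset) * sqrt(tau2 + se_m^2)
  interval_result(m - h, m + h, measure, kind = "PI95")
}

#' Recomputed 95% confidence interval for the pooled estimate
#'
#' `M +/- z * SE(M)` on the analysis scale, exponentiated back for ratio
#' measures.  Used when the agreement analysis is run against recomputed
#' rather than reported CIs.
#'
#' @inheritParams prediction_interval
#' @inheritParams back_calculate_se
#' @return A tibble like [prediction_interval()]'s with `kind = "CI95"`.
#' @export
confidence_interval <- function(m, se_m, measure = "MD", z = Z975) {
  check_measure(measure)
  h <- z * se_m
  interval_result(m - h, m + h, measure, kind = "CI95")
}

# analysis-scale bounds -> reported-scale interval tibble with verdict
interval_result <- function(lower, upper, measure, kind) {
  ratio <- is_ratio_measure(measure)
  lo <- ifelse(ratio, exp(lower), lower)
  hi <- ifelse(ratio, exp(upper), upper)
  nv <- null_value(measure)
  tibble::tibble(
    lower = lo, upper = hi, kind = kind, null_value = nv,
    significant = nv < lo | nv > hi
  )
}

#' Interval significance against the measure's null value
#'
#' `TRUE` iff the null (0 for MD/SMD, 1 for RR/OR) lies strictly outside
#' `[lower, upper]` on the reported scale.
#'
#' @param lower,upper Interval bounds on the reported scale.
#' @param measure Effect-measure code(s).
#' @return Logical vector (`NA` where a bound is missing).
#' @export
interval_significant <- function(lower, upper, measure) {
  nv <- null_value(measure)
  nv < lower | nv > upper
}

AGREEMENT_LEVELS <- c(
  "corroborated_significant", "both_nonsignificant", "ci_sig_pi_not",
  "not_computable"
)

#' Classify CI/PI agreement for one or more meta-analyses
#'
#' The taxonomy of the agreement analysis: a significant CI *corroborated*
#' by a significant PI; both intervals non-significant; a significant CI
#' whose PI spans the null (`ci_sig_pi_not`); or `not_computable` when no PI
#' exists (tau-squared unreported or fewer than three trials).  Because a
#' 95% PI always contains the 95% CI, a significant PI with a
#' non-significant CI is impossible for valid input and raises an error.
#'
#' @param ci_significant Logical: CI excludes the null.
#' @param pi_significant Logical: PI excludes the null; `NA` when the PI is
#'   not computable.
#' @return Factor with levels `corroborated_significant`,
#'   `both_nonsignificant`, `ci_sig_pi_not`, `not_computable`.
#' @export
classify_agreement <- function(ci_significant, pi_significant) {
  n <- max(length(ci_significant), length(pi_significant))
  ci_significant <- rep_len(ci_significant, n)
  pi_significant <- rep_len(pi_significant, n)
  bad <- !is.na(pi_significant) & pi_significant &
    !is.na(ci_significant) & !ci_significant
  if (any(bad)) {
    abort(paste(
      "PI significant while CI non-significant: violates the nesting",
      "property; input is corrupted."
    ))
  }
  out <- dplyr::case_when(
    is.na(pi_significant) ~ "not_computable",
    ci_significant & pi_significant ~ "corroborated_significant",
    !ci_significant & !pi_significant ~ "both_nonsignificant",
    ci_significant & !pi_significant ~ "ci_sig_pi_not"
  )
  factor(out, levels = AGREEMENT_LEVELS)
}

#' Append analysis-scale summaries, prediction intervals and agreement
#'
#' The data-frame verb wiring corpus columns to the interval engine: for
#' each record it back-calculates `se_m` from the reported CI (log scale for
#' ratio measures), computes the 95% PI where `tau2` is present and
#' `k_trials >= 3`, evaluates CI and PI significance, and classifies the
#' agreement category.
#'
#' @param records A corpus tibble (typically after [filter_eligible()]).
#' @param z Normal quantile for back-calculation and recomputed CIs.
#' @param df_offset Degrees-of-freedom rule for the PI t quantile.
#' @param use_reported_ci If `TRUE` (default) the significance of the CI is
#'   judged from the reported bounds verbatim; if `FALSE`, from a CI
#'   recomputed as `M +/- z * se_m`.
#' @return The input with appended columns `m` (analysis scale), `se_m`,
#'   `pi_computable`, `pi_lower`, `pi_upper`, `ci_significant`,
#'   `pi_significant`, `agreement`.
#' @export
add_intervals <- function(records, z = Z975, df_offset = 2,
                          use_reported_ci = TRUE) {
  measure <- as.character(records$effect_measure)
  check_measure(measure, "effect_measure")
  ratio <- is_ratio_measure(measure)
  m <- records$pooled_estimate
  pos <- ratio & !is.na(m) & m > 0
  m[pos] <- log(records$pooled_estimate[pos])
  m[ratio & !pos] <- NA_real_
  se_m <- back_calculate_se(
    records$ci_lower, records$ci_upper, measure, z = z
  )
  computable <- !is.na(records$tau2) & !is.na(records$k_trials) &
    records$k_trials >= 3 & !is.na(m) & !is.na(se_m)

  pi_lower <- rep(NA_real_, nrow(records))
  pi_upper <- rep(NA_real_, nrow(records))
  pi_sig <- rep(NA, nrow(records))
  if (any(computable)) {
    pi <- prediction_interval(
      m[computable], se_m[computable], records$tau2[computable],
      records$k_trials[computable], measure[computable],
      df_offset = df_offset
    )
    pi_lower[computable] <- pi$lower
    pi_upper[computable] <- pi$upper
    pi_sig[computable] <- pi$significant
  }

  if (use_reported_ci) {
    ci_sig <- interval_significant(
      records$ci_lower, records$ci_upper, measure
    )
  } else {
    ci_sig <- confidence_interval(m, se_m, measure, z = z)$significant
  }

  dplyr::mutate(
    records,
    m = m, se_m = se_m, pi_computable = computable,
    pi_lower = pi_lower, pi_upper = pi_upper,
    ci_significant = ci_sig, pi_significant = pi_sig,
    agreement = classify_agreement(ci_sig, pi_sig)
  )
}
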