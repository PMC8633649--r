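#' Summarise CI/PI agreement over the computable records
#'
#' Counts and percentages of the agreement taxonomy over the records whose
#' prediction interval could be computed; `not_computable` records are
#' reported separately so the accounting from corpus size down to the
#' analysed subset is explicit.
#'
#' @param per_record Output of [add_intervals()].
#' @return A one-row tibble: `n_total` (computable records),
#'   `n_corroborated`, `n_both_nonsig`, `n_ci_sig_pi_not`,
#'   `n_not_computable`, and the matching percentages of `n_total`.
#' @export
summarize_agreement <- function(per_record) {
  agr <- per_record$agreement
  n_nc <- sum(agr == "not_computable")
  comp <- agr[agr != "not_computable"]
  n <- length(comp)
  cnt <- function(lv) sum(comp == lv)
  pct <- function(x) if (n > 0) 100 * x / n else NA_real_
  n_cor <- cnt("corroborated_significant")
  n_non <- cnt("both_nonsignificant")
  n_dis <- cnt("ci_sig_pi_not")
  if (n == 0) warn("no records with a computable prediction interval")
  tibble::tibble(
    n_total = n,
    n_corroborated = n_cor, pct_corroborated = pct(n_cor),
    n_both_nonsig = n_non, pct_both_nonsig = pct(n_non),
    n_ci_sig_pi_not = n_dis, pct_ci_sig_pi_not = pct(n_dis),
    n_not_computable = n_nc
  )
}

#' Effect-measure and tau-squared reporting frequencies
#'
#' @param records A corpus tibble.
#' @return A tibble with columns `variable`, `level`, `n`, `pct`
#'   (percentages of the corpus size, printed style: one decimal).
#' @export
tabulate_frequencies <- function(records) {
  n_records <- nrow(records)
  em <- records |>
    dplyr::count(level = as.character(.data$effect_measure)) |>
    dplyr::mutate(variable = "effect_measure")
  t2 <- tibble::tibble(
    variable = "tau2",
    level = c("reported", "not_reported"),
    n = c(sum(!is.na(records$tau2)), sum(is.na(records$tau2)))
  )
  dplyr::bind_rows(em, t2) |>
    dplyr::mutate(pct = round(100 * .data$n / n_records, 1)) |>
    dplyr::select("variable", "level", "n", "pct")
}

or_row <- function(variable, level, n_not, n_rep, fit = NULL, p = NULL,
                   note = NA_character_) {
  tibble::tibble(
    variable = variable, level = level,
    n_not_reported = n_not, n_reported = n_rep,
    or = if (is.null(fit)) NA_real_ else fit$estimate,
    or_kind = if (is.null(fit)) NA_character_ else fit$kind,
    ci_lower = if (is.null(fit)) NA_real_ else fit$ci_lower,
    ci_upper = if (is.null(fit)) NA_real_ else fit$ci_upper,
    p_value = p %||% if (is.null(fit)) NA_real_ else fit$p_value,
    note = note
  )
}

safe_exact <- function(x, y = NULL) {
  tryCatch(exact_or_test(x, y), error = function(e) NULL)
}

#' Covariate associations with prediction-interval reporting
#'
#' The cross-tabulation report: for each review-level covariate, counts of
#' reviews not reporting / reporting a prediction interval and the exact
#' conditional inference — conditional-MLE (or median-unbiased) odds
#' ratios, exact tail-inversion CIs, and probability-ordering exact
#' p-values.  Year of publication and number of authors are analysed as
#' continuous covariates via the exact-logistic DP; the continent block
#' uses Europe as reference, pairwise 2x2 subtables, plus a Freeman-Halton
#' p-value across all levels; the significance block drops
#' `not_reported` verdicts from the 2x2 analysis.  Levels whose exact
#' estimate does not exist (degenerate support) are kept with a
#' `"not estimable"` note.
#'
#' @param records A corpus tibble with a logical `pi_reported` column.
#' @return A tibble with one row per covariate level: counts, `or`,
#'   `or_kind`, `ci_lower`, `ci_upper`, `p_value`, `note`.
#' @export
tabulate_associations <- function(records) {
  y <- records$pi_reported
  rows <- list()

  two_by_two <- function(flag) {
    matrix(
      c(
        sum(!flag & !y), sum(flag & !y),
        sum(!flag & y), sum(flag & y)
      ),
      nrow = 2
    )
  }

  # year and author count as continuous covariates
  for (v in c("year", "n_authors")) {
    fit <- safe_exact(records[[v]], y)
    rows[[length(rows) + 1]] <- or_row(
      v, "per unit", sum(!y), sum(y), fit,
      note = if (is.null(fit)) "not estimable" else "continuous covariate"
    )
  }

  # continent: Europe reference, pairwise exact 2x2, Freeman-Halton overall
  cont <- as.character(records$continent)
  levs <- c("Europe", "Americas", "AsiaOther")
  tab_r2 <- vapply(
    levs, function(l) c(sum(cont == l & !y), sum(cont == l & y)), numeric(2)
  )
  fh_p <- tryCatch(fisher_exact_rxc(t(tab_r2)), error = function(e) NA_real_)
  rows[[length(rows) + 1]] <- or_row(
    "continent", "Europe", tab_r2[1, 1], tab_r2[2, 1],
    note = "reference"
  )
  for (l in levs[-1]) {
    sub <- cont %in% c("Europe", l)
    m <- matrix(
      c(
        sum(sub & cont == "Europe" & !y), sum(sub & cont == l & !y),
        sum(sub & cont == "Europe" & y), sum(sub & cont == l & y)
      ),
      nrow = 2
    )
    fit <- safe_exact(m)
    rows[[length(rows) + 1]] <- or_row(
      "continent", l, m[2, 1], m[2, 2], fit,
      note = if (is.null(fit)) "not estimable" else NA_character_
    )
  }
  rows[[length(rows) + 1]] <- or_row(
    "continent", "overall", sum(!y), sum(y), p = fh_p,
    note = "Freeman-Halton exact test"
  )

  for (v in c("prospero", "cochrane")) {
    flag <- records[[v]]
    m <- two_by_two(flag)
    fit <- safe_exact(m)
    rows[[length(rows) + 1]] <- or_row(
      v, "yes vs no", m[2, 1], m[2, 2], fit,
      note = if (is.null(fit)) "not estimable" else NA_character_
    )
  }

  # reported significance: 2x2 over yes/no verdicts only
  sig <- as.character(records$reported_significant)
  keep <- sig %in% c("no", "yes")
  m <- matrix(
    c(
      sum(keep & sig == "no" & !y), sum(keep & sig == "yes" & !y),
      sum(keep & sig == "no" & y), sum(keep & sig == "yes" & y)
    ),
    nrow = 2
  )
  fit <- safe_exact(m)
  rows[[length(rows) + 1]] <- or_row(
    "reported_significant", "yes vs no", m[2, 1], m[2, 2], fit,
    note = if (is.null(fit)) "not estimable" else NA_character_
  )
  n_nr <- sum(sig == "not_reported")
  if (n_nr > 0) {
    rows[[length(rows) + 1]] <- or_row(
      "reported_significant", "not_reported",
      sum(sig == "not_reported" & !y), sum(sig == "not_reported" & y),
      note = "excluded from 2x2 analysis"
    )
  }
  dplyr::bind_rows(rows)
}

#' Run the full reporting pipeline on a corpus
#'
#' Orchestrates the analysis end to end: validates the corpus, applies the
#' three-trial eligibility filter, back-calculates standard errors,
#' computes prediction intervals where tau-squared is available, classifies
#' CI/PI agreement, and assembles the covariate-association and frequency
#' tables plus descriptive statistics.  Every excluded or not-computable
#' record is accounted for with a reason.
#'
#' @param corpus A corpus tibble ([read_corpus()] or
#'   [generate_corpus()]`$corpus`).
#' @param z Normal quantile for SE back-calculation and recomputed CIs.
#' @param df_offset Degrees-of-freedom rule for the PI t quantile
#'   (`k - df_offset`).
#' @param use_reported_ci Judge CI significance from the reported bounds
#'   (default) or from recomputed ones.
#' @param out_dir If non-`NULL`, writes `per_record.csv`, `table1.tsv`,
#'   `table2.tsv` and `agreement.json` there.
#' @return An object of class `"metapi_report"`: a list with `per_record`
#'   (input plus computed columns), `agreement`, `table1`, `table2`,
#'   `descriptives`, and `accounting` (one row per excluded or
#'   not-computable record with its reason).
#' @export
run_pipeline <- function(corpus, z = Z975, df_offset = 2,
                         use_reported_ci = TRUE, out_dir = NULL) {
  probs <- validate_corpus(corpus)
  if (nrow(probs) > 0) {
    abort(sprintf(
      "corpus failed validation with %d problem(s); see validate_corpus()",
      nrow(probs)
    ))
  }
  flagged <- filter_eligible(corpus)
  eligible <- dplyr::filter(flagged, .data$eligible)
  per_record <- add_intervals(
    eligible, z = z, df_offset = df_offset,
    use_reported_ci = use_reported_ci
  )
  agreement <- summarize_agreement(per_record)
  table1 <- tabulate_associations(eligible)
  table2 <- tabulate_frequencies(eligible)

  descriptives <- tibble::tibble(
    n_records = nrow(corpus),
    n_eligible = nrow(eligible),
    n_pi_reported = sum(eligible$pi_reported),
    pct_pi_reported = round(100 * mean(eligible$pi_reported), 1),
    median_authors = median(eligible$n_authors),
    iqr_authors_low = unname(quantile(eligible$n_authors, 0.25)),
    iqr_authors_high = unname(quantile(eligible$n_authors, 0.75))
  )

  accounting <- dplyr::bind_rows(
    flagged |>
      dplyr::filter(!.data$eligible) |>
      dplyr::transmute(.data$sr_id, reason = .data$exclusion_reason),
    per_record |>
      dplyr::filter(.data$agreement == "not_computable") |>
      dplyr::transmute(
        .data$sr_id,
        reason = dplyr::if_else(
          is.na(.data$tau2), "tau2 not reported", "interval not computable"
        )
      )
  )

  report <- structure(
    list(
      per_record = per_record, agreement = agreement,
      table1 = table1, table2 = table2,
      descriptives = descriptives, accounting = accounting
    ),
    class = "metapi_report"
  )
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' Write a pipeline report to disk
#'
#' @param report A `metapi_report`.
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  per_record <- dplyr::mutate(
    report$per_record,
    dplyr::across(dplyr::where(is.factor), as.character)
  )
  readr::write_csv(
    per_record, file.path(out_dir, "per_record.csv"), na = "",
    progress = FALSE
  )
  readr::write_tsv(
    report$table1, file.path(out_dir, "table1.tsv"), na = "",
    progress = FALSE
  )
  readr::write_tsv(
    report$table2, file.path(out_dir, "table2.tsv"), na = "",
    progress = FALSE
  )
  jsonlite::write_json(
    as.list(report$agreement), file.path(out_dir, "agreement.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(out_dir)
}

#' @export
print.metapi_report <- function(x, ...) {
  d <- x$descriptives
  a <- x$agreement
  cat(sprintf(
    "Corpus: %d records, %d eligible (>= 3 trials)\n",
    d$n_records, d$n_eligible
  ))
  cat(sprintf(
    "Prediction intervals reported: %d (%.1f%%)\n",
    d$n_pi_reported, d$pct_pi_reported
  ))
  cat(sprintf(
    "Agreement over %d computable meta-analyses:\n", a$n_total
  ))
  cat(sprintf(
    "  CI and PI significant:        %3d (%.1f%%)\n",
    a$n_corroborated, a$pct_corroborated
  ))
  cat(sprintf(
    "  both non-significant:         %3d (%.1f%%)\n",
    a$n_both_nonsig, a$pct_both_nonsig
  ))
  cat(sprintf(
    "  CI significant, PI spans null:%3d (%.1f%%)\n",
    a$n_ci_sig_pi_not, a$pct_ci_sig_pi_not
  ))
  cat(sprintf("  not computable:               %3d\n", a$n_not_computable))
  invisible(x)
}
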