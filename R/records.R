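#' Column schema of an extracted meta-analysis corpus
#'
#' One row per systematic review (SR): bibliographic covariates, the selected
#' random-effects meta-analysis summary (pooled estimate, 95% CI, tau-squared,
#' number of trials, effect measure), and the prediction-interval reporting
#' flags.  `tau2` may be missing (`NA`), meaning the review did not report it;
#' it is never imputed as zero.
#'
#' @format A named character vector mapping column names to types.
#' @keywords internal
corpus_schema <- function() {
  c(
    sr_id = "character",
    year = "integer",
    n_authors = "integer",
    continent = "enum:Europe,Americas,AsiaOther",
    prospero = "logical",
    cochrane = "logical",
    pi_reported = "logical",
    pi_discussed = "enum:no,yes,not_applicable",
    k_trials = "integer",
    effect_measure = "enum:MD,SMD,RR,OR",
    pooled_estimate = "double",
    ci_lower = "double",
    ci_upper = "double",
    tau2 = "double",
    reported_significant = "enum:no,yes,not_reported"
  )
}

enum_levels <- function(type) strsplit(sub("^enum:", "", type), ",")[[1]]

parse_logical_cell <- function(x) {
  x <- tolower(trimws(as.character(x)))
  out <- rep(NA, length(x))
  out[x %in% c("true", "t", "yes", "y", "1")] <- TRUE
  out[x %in% c("false", "f", "no", "n", "0")] <- FALSE
  bad <- !is.na(x) & x != "" & x != "na" & is.na(out)
  list(value = out, bad = bad)
}

#' Read an extracted-corpus CSV
#'
#' Reads a comma-separated, UTF-8, headered table with the corpus schema
#' (see [validate_corpus()] for the per-field invariants).  Missing values
#' may be encoded as empty cells or `"NA"`; a missing `tau2` is parsed as
#' `NA`, never as zero.  Validation problems are collected with row numbers
#' and attached as the `"problems"` attribute (a tibble with columns `row`,
#' `field`, `message`); with `strict = TRUE` any problem aborts the read.
#'
#' @param path Path to a CSV file.
#' @param strict If `TRUE`, validation problems become errors instead of a
#'   warning.
#' @return A tibble, one row per systematic review, with a `"problems"`
#'   attribute.
#' @seealso [write_corpus()], [filter_eligible()]
#' @export
read_corpus <- function(path, strict = FALSE) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  raw <- readr::read_csv(
    path,
    col_types = readr::cols(.default = readr::col_character()),
    na = c("", "NA"), progress = FALSE
  )
  schema <- corpus_schema()
  missing_cols <- setdiff(names(schema), names(raw))
  if (length(missing_cols) > 0) {
    abort(sprintf(
      "Corpus header is missing column(s): %s.",
      paste(missing_cols, collapse = ", ")
    ))
  }

  problems <- list()
  note <- function(row, field, message) {
    problems[[length(problems) + 1]] <<- tibble::tibble(
      row = row, field = field, message = message
    )
  }

  out <- tibble::tibble(.rows = nrow(raw))
  for (col in names(schema)) {
    type <- schema[[col]]
    x <- raw[[col]]
    if (type == "character") {
      out[[col]] <- x
    } else if (type %in% c("integer", "double")) {
      val <- suppressWarnings(as.numeric(x))
      bad <- which(!is.na(x) & is.na(val))
      for (i in bad) note(i, col, sprintf("unparseable numeric cell '%s'", x[i]))
      out[[col]] <- if (type == "integer") as.integer(round(val)) else val
    } else if (type == "logical") {
      p <- parse_logical_cell(x)
      for (i in which(p$bad)) {
        note(i, col, sprintf("unparseable logical cell '%s'", x[i]))
      }
      out[[col]] <- p$value
    } else {
      levs <- enum_levels(type)
      bad <- which(!is.na(x) & !x %in% levs)
      for (i in bad) {
        note(i, col, sprintf(
          "unknown label '%s'; allowed labels: %s", x[i],
          paste(levs, collapse = ", ")
        ))
      }
      val <- x
      val[!val %in% levs] <- NA
      out[[col]] <- factor(val, levels = levs)
    }
  }

  problems <- dplyr::bind_rows(
    c(problems, list(validate_corpus(out))),
    .id = NULL
  )
  if (nrow(problems) > 0) {
    problems <- dplyr::arrange(problems, .data$row, .data$field)
    msg <- sprintf(
      "Corpus has %d validation problem(s); first: row %d, %s: %s",
      nrow(problems), problems$row[1], problems$field[1], problems$message[1]
    )
    if (strict) abort(msg) else warn(msg)
  }
  attr(out, "problems") <- problems
  out
}

#' Validate corpus invariants
#'
#' Checks the per-record invariants: `ci_lower < ci_upper` when both are
#' present; for ratio measures (RR, OR) the pooled estimate and both CI
#' bounds must be positive; the pooled estimate must lie inside its CI;
#' `tau2 >= 0` when present; `k_trials >= 1`; `n_authors >= 1`.
#'
#' @param records A corpus tibble (as returned by [read_corpus()] or
#'   [generate_corpus()]).
#' @return A tibble of problems with columns `row`, `field`, `message`
#'   (zero rows when the corpus is valid).
#' @export
validate_corpus <- function(records) {
  probs <- list()
  note <- function(rows, field, message) {
    for (i in rows) {
      probs[[length(probs) + 1]] <<- tibble::tibble(
        row = i, field = field, message = message
      )
    }
  }
  with_ci <- !is.na(records$ci_lower) & !is.na(records$ci_upper)
  note(
    which(with_ci & records$ci_lower >= records$ci_upper),
    "ci_lower", "ci_lower < ci_upper violated"
  )
  ratio <- !is.na(records$effect_measure) &
    records$effect_measure %in% RATIO_MEASURES
  for (col in c("pooled_estimate", "ci_lower", "ci_upper")) {
    note(
      which(ratio & !is.na(records[[col]]) & records[[col]] <= 0),
      col, "ratio-measure value must be positive"
    )
  }
  inside <- with_ci & !is.na(records$pooled_estimate)
  note(
    which(inside &
      (records$pooled_estimate < records$ci_lower |
        records$pooled_estimate > records$ci_upper)),
    "pooled_estimate", "pooled_estimate outside [ci_lower, ci_upper]"
  )
  note(which(!is.na(records$tau2) & records$tau2 < 0), "tau2", "tau2 < 0")
  note(
    which(!is.na(records$k_trials) & records$k_trials < 1),
    "k_trials", "k_trials must be >= 1"
  )
  note(
    which(!is.na(records$n_authors) & records$n_authors < 1),
    "n_authors", "n_authors must be >= 1"
  )
  if (length(probs) == 0) {
    return(tibble::tibble(
      row = integer(), field = character(), message = character()
    ))
  }
  dplyr::bind_rows(probs)
}

#' Write a corpus CSV
#'
#' Inverse of [read_corpus()]: comma-separated, UTF-8, header row, missing
#' values written as empty cells.  A write/read round trip reproduces the
#' records field-identically.
#'
#' @param records A corpus tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(records, path) {
  out <- dplyr::mutate(
    records,
    dplyr::across(dplyr::where(is.factor), as.character)
  )
  readr::write_csv(out, path, na = "", progress = FALSE)
  invisible(path)
}

#' Flag records eligible for prediction-interval analysis
#'
#' A prediction interval needs at least three trials, so records with
#' `k_trials < 3` are excluded.  The input is returned with two appended
#' columns — `eligible` (logical) and `exclusion_reason` (`NA` for eligible
#' rows) — so that every record appears in exactly one of the two groups and
#' the accounting is auditable.
#'
#' @param records A corpus tibble.
#' @return The input tibble with columns `eligible` and `exclusion_reason`
#'   appended.
#' @examples
#' recs <- tibble::tibble(
#'   sr_id = c("a", "b"), k_trials = c(2L, 3L)
#' )
#' filter_eligible(recs)
#' @export
filter_eligible <- function(records) {
  dplyr::mutate(
    records,
    eligible = !is.na(.data$k_trials) & .data$k_trials >= 3,
    exclusion_reason = dplyr::if_else(
      .data$eligible, NA_character_, "fewer than three trials"
    )
  )
}
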