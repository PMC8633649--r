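#' Specification of a synthetic meta-analysis corpus
#'
#' Bundles the generating distributions for a corpus of systematic reviews
#' whose statistical structure matches what the analysis pipeline assumes:
#' per-study effects from a normal random-effects model, DerSimonian-Laird
#' summaries written into the extraction-sheet schema, and review-level
#' covariates whose log odds shift the probability that a prediction
#' interval is reported.
#'
#' Defaults emulate the study corpus: 121 reviews; effect-measure mix
#' 64.5% MD / 19.0% SMD / 9.1% RR / 7.4% OR; tau-squared blanked with
#' probability 0.215; publication years 2012-2021 weighted as observed;
#' author counts `2 + Poisson(3)` (median 5, IQR roughly 4-6); trial counts
#' `3 + Poisson(4)` with 10% mass at `k = 2` to exercise the eligibility
#' filter; true effects `N(0.3, 0.2^2)`, heterogeneity
#' `Gamma(shape = 1.2, scale = 0.05)`, within-study variances
#' `U(0.01, 0.1)`; PROSPERO prevalence 0.51 with log odds `log(3.3)` on
#' reporting and Cochrane prevalence 0.05 with log odds `log(0.5)`.
#'
#' @param n_sr Number of systematic reviews.
#' @param k_sampler Function of `n` returning trial counts (integer, >= 2).
#' @param mu_sampler,tau2_sampler Functions of `n` returning true pooled
#'   effects (analysis scale) and between-study variances (>= 0).
#' @param within_var_sampler Function of `k` returning within-study
#'   variances.
#' @param measure_mix Named probabilities over `MD`, `SMD`, `RR`, `OR`.
#' @param covariates Tibble with columns `name`, `prevalence`, `log_odds`:
#'   binary review-level covariates and their effect on `pi_reported`.
#' @param reporting_intercept Baseline log odds of reporting a prediction
#'   interval when all binary covariates are 0.
#' @param continent_probs Named probabilities over the three continent
#'   levels.
#' @param year_probs Named probabilities over publication years.
#' @param n_authors_sampler Function of `n` returning author counts.
#' @param tau2_missing_rate Probability that a record's tau-squared is
#'   blanked (missing, never zero).
#' @param sig_not_reported_rate Probability that the authors' significance
#'   verdict is recorded as `not_reported`.
#' @param seed Integer seed used by [generate_corpus()]; `NULL` leaves the
#'   RNG state alone.
#' @return A list of class `"corpus_spec"`.
#' @export
corpus_spec <- function(
    n_sr = 121,
    k_sampler = function(n) {
      ifelse(runif(n) < 0.1, 2L, 3L + rpois(n, 4))
    },
    mu_sampler = function(n) rnorm(n, 0.3, 0.2),
    tau2_sampler = function(n) stats::rgamma(n, shape = 1.2, scale = 0.05),
    within_var_sampler = function(k) runif(k, 0.01, 0.1),
    measure_mix = c(MD = 0.645, SMD = 0.190, RR = 0.091, OR = 0.074),
    covariates = tibble::tibble(
      name = c("prospero", "cochrane"),
      prevalence = c(0.51, 0.05),
      log_odds = c(log(3.3), log(0.5))
    ),
    reporting_intercept = log(0.10 / 0.90),
    continent_probs = c(Europe = 0.42, Americas = 0.16, AsiaOther = 0.42),
    year_probs = setNames(
      c(1, 3, 6, 8, 14, 22, 25, 21, 19, 2) / 121, 2012:2021
    ),
    n_authors_sampler = function(n) 2L + rpois(n, 3),
    tau2_missing_rate = 0.215,
    sig_not_reported_rate = 0.01,
    seed = NULL) {
  stopifnot(
    n_sr >= 1,
    abs(sum(measure_mix) - 1) < 1e-8,
    abs(sum(continent_probs) - 1) < 1e-8,
    tau2_missing_rate >= 0, tau2_missing_rate <= 1
  )
  structure(
    list(
      n_sr = as.integer(n_sr), k_sampler = k_sampler,
      mu_sampler = mu_sampler, tau2_sampler = tau2_sampler,
      within_var_sampler = within_var_sampler, measure_mix = measure_mix,
      covariates = covariates, reporting_intercept = reporting_intercept,
      continent_probs = continent_probs, year_probs = year_probs,
      n_authors_sampler = n_authors_sampler,
      tau2_missing_rate = tau2_missing_rate,
      sig_not_reported_rate = sig_not_reported_rate, seed = seed
    ),
    class = "corpus_spec"
  )
}

#' Simulate one meta-analysis study set
#'
#' Draws `k` true study effects `theta_i ~ N(mu, tau2)` and observed
#' effects `y_i ~ N(theta_i, v_i)` with within-study variances from
#' `within_var_sampler`.  With `tau2 = 0` every true effect equals `mu`
#' exactly.  Uses the current RNG state, so results are reproducible under
#' `set.seed()`.
#'
#' @param mu True pooled effect on the analysis scale.
#' @param tau2 Between-study variance (>= 0).
#' @param k Number of studies (>= 2).
#' @param within_var_sampler Function of `k` returning positive variances.
#' @return A tibble with columns `study`, `theta`, `effect`, `variance`.
#' @export
simulate_study_set <- function(mu, tau2, k,
                               within_var_sampler = function(k) {
                                 runif(k, 0.01, 0.1)
                               }) {
  if (!is.finite(k) || k < 2 || k != round(k)) abort("k must be >= 2")
  if (!is.finite(tau2) || tau2 < 0) abort("tau2 must be nonnegative")
  v <- within_var_sampler(k)
  if (any(v <= 0)) abort("within-study variances must be positive")
  theta <- rnorm(k, mu, sqrt(tau2))
  tibble::tibble(
    study = seq_len(k),
    theta = theta,
    effect = rnorm(k, theta, sqrt(v)),
    variance = v
  )
}

#' Generate a synthetic corpus of extracted meta-analysis records
#'
#' For each review: draws an effect measure, trial count, true effect and
#' heterogeneity; simulates a study set; fits the DerSimonian-Laird model;
#' and writes the pooled estimate, 95% CI (`M +/- z * SE` on the analysis
#' scale, exponentiated for ratio measures) and estimated tau-squared into
#' the extraction-sheet schema.  Tau-squared is blanked with probability
#' `tau2_missing_rate`.  Covariates are drawn at their prevalences and
#' `pi_reported` follows a logistic model with the specified log odds.
#' Generating parameters are returned alongside as a truth table.
#'
#' @param spec A [corpus_spec()].
#' @return A list with elements `corpus` (tibble in the corpus schema) and
#'   `truth` (tibble with `sr_id`, true `mu`, `tau2`, the DL fit, and the
#'   reporting probability).
#' @examples
#' sim <- generate_corpus(corpus_spec(n_sr = 10, seed = 1))
#' sim$corpus
#' @export
generate_corpus <- function(spec) {
  if (!inherits(spec, "corpus_spec")) abort("spec must be a corpus_spec")
  if (!is.null(spec$seed)) set.seed(spec$seed)
  n <- spec$n_sr

  measure <- sample(
    names(spec$measure_mix), n, replace = TRUE, prob = spec$measure_mix
  )
  k <- as.integer(spec$k_sampler(n))
  mu <- spec$mu_sampler(n)
  tau2_true <- spec$tau2_sampler(n)
  continent <- sample(
    names(spec$continent_probs), n, replace = TRUE,
    prob = spec$continent_probs
  )
  year <- as.integer(sample(
    names(spec$year_probs), n, replace = TRUE, prob = spec$year_probs
  ))
  n_authors <- pmax(1L, as.integer(spec$n_authors_sampler(n)))

  cov_draws <- purrr::map(
    seq_len(nrow(spec$covariates)),
    function(i) runif(n) < spec$covariates$prevalence[i]
  )
  names(cov_draws) <- spec$covariates$name
  eta <- spec$reporting_intercept +
    Reduce(`+`, purrr::map2(
      cov_draws, spec$covariates$log_odds, function(d, b) b * d
    ))
  p_report <- plogis(eta)
  pi_reported <- runif(n) < p_report

  fits <- purrr::map(seq_len(n), function(i) {
    s <- simulate_study_set(
      mu[i], tau2_true[i], k[i], spec$within_var_sampler
    )
    glance(dl_fit(s$effect, s$variance))
  })
  fits <- dplyr::bind_rows(fits)

  ratio <- is_ratio_measure(measure)
  pooled <- ifelse(ratio, exp(fits$m), fits$m)
  ci_lo <- ifelse(ratio, exp(fits$m - Z975 * fits$se_m), fits$m - Z975 * fits$se_m)
  ci_hi <- ifelse(ratio, exp(fits$m + Z975 * fits$se_m), fits$m + Z975 * fits$se_m)
  tau2_missing <- runif(n) < spec$tau2_missing_rate
  sig <- interval_significant(ci_lo, ci_hi, measure)
  sig_lab <- ifelse(
    runif(n) < spec$sig_not_reported_rate, "not_reported",
    ifelse(sig, "yes", "no")
  )
  pi_discussed <- ifelse(
    pi_reported, ifelse(runif(n) < 0.26, "yes", "no"), "not_applicable"
  )

  corpus <- tibble::tibble(
    sr_id = sprintf("SR%04d", seq_len(n)),
    year = year,
    n_authors = n_authors,
    continent = factor(continent, levels = names(spec$continent_probs)),
    prospero = cov_draws[["prospero"]] %||% rep(FALSE, n),
    cochrane = cov_draws[["cochrane"]] %||% rep(FALSE, n),
    pi_reported = pi_reported,
    pi_discussed = factor(
      pi_discussed, levels = c("no", "yes", "not_applicable")
    ),
    k_trials = k,
    effect_measure = factor(measure, levels = EFFECT_MEASURES),
    pooled_estimate = pooled,
    ci_lower = ci_lo,
    ci_upper = ci_hi,
    tau2 = ifelse(tau2_missing, NA_real_, fits$tau2),
    reported_significant = factor(
      sig_lab, levels = c("no", "yes", "not_reported")
    )
  )
  truth <- tibble::tibble(
    sr_id = corpus$sr_id,
    mu = mu, tau2 = tau2_true, k = k,
    m_hat = fits$m, se_m_hat = fits$se_m, tau2_hat = fits$tau2,
    i2_hat = fits$i2, p_report = p_report
  )
  list(corpus = corpus, truth = truth)
}
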