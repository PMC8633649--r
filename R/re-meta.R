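#' DerSimonian-Laird random-effects meta-analysis
#'
#' Inverse-variance pooling with the moment estimator of the between-study
#' variance.  Fixed-effect weights `w_i = 1/v_i` give Cochran's
#' `Q = sum w_i (y_i - ybar_w)^2`; with `C = sum w_i - sum w_i^2 / sum w_i`
#' the DerSimonian-Laird estimate is `tau2 = max(0, (Q - (k - 1)) / C)`
#' (negative moment estimates are truncated at zero).  Random-effects
#' weights `1 / (v_i + tau2)` then give the pooled estimate and its
#' standard error; `I2 = max(0, (Q - (k - 1)) / Q)` summarises the share of
#' variability attributable to heterogeneity.
#'
#' @param effects Numeric vector of study effects on the analysis scale.
#' @param variances Numeric vector of within-study variances (positive),
#'   same length as `effects`; at least two studies.
#' @return An object of class `"dl_fit"`: a list with elements `m`, `se_m`
#'   (random-effects pooled estimate and SE), `tau2`, `q`, `i2`, `k`, and
#'   the fixed-effect results `m_fixed`, `se_fixed`.  [tidy()] and
#'   [glance()] methods return tibbles.
#' @examples
#' fit <- dl_fit(c(0.2, 0.4, 0.6), c(0.01, 0.01, 0.01))
#' glance(fit)
#' @export
dl_fit <- function(effects, variances) {
  if (length(effects) != length(variances)) {
    abort("effects and variances must have the same length")
  }
  k <- length(effects)
  if (k < 2) abort("at least two studies are required")
  if (any(!is.finite(effects)) || any(!is.finite(variances))) {
    abort("effects and variances must be finite")
  }
  if (any(variances <= 0)) abort("all within-study variances must be positive")

  w <- 1 / variances
  sw <- sum(w)
  m_fixed <- sum(w * effects) / sw
  q <- sum(w * (effects - m_fixed)^2)
  cc <- sw - sum(w^2) / sw
  tau2 <- max(0, (q - (k - 1)) / cc)
  i2 <- if (q > 0) max(0, (q - (k - 1)) / q) else 0

  ws <- 1 / (variances + tau2)
  m <- sum(ws * effects) / sum(ws)
  se_m <- 1 / sqrt(sum(ws))

  structure(
    list(
      m = m, se_m = se_m, tau2 = tau2, q = q, i2 = i2, k = k,
      m_fixed = m_fixed, se_fixed = 1 / sqrt(sw),
      effects = effects, variances = variances
    ),
    class = "dl_fit"
  )
}

#' @export
print.dl_fit <- function(x, ...) {
  cat(sprintf(
    "Random-effects meta-analysis (DerSimonian-Laird), k = %d\n", x$k
  ))
  cat(sprintf("  pooled estimate: %.4f (SE %.4f)\n", x$m, x$se_m))
  cat(sprintf(
    "  tau2 = %.4f, Q = %.3f, I2 = %.1f%%\n", x$tau2, x$q, 100 * x$i2
  ))
  invisible(x)
}

#' @describeIn dl_fit One row per model term (the pooled effect) with
#'   estimate, standard error and 95% CI bounds on the analysis scale.
#' @param x A `dl_fit` object.
#' @param ... Unused.
#' @method tidy dl_fit
#' @export
tidy.dl_fit <- function(x, ...) {
  tibble::tibble(
    term = "pooled_effect",
    estimate = x$m,
    std.error = x$se_m,
    conf.low = x$m - Z975 * x$se_m,
    conf.high = x$m + Z975 * x$se_m
  )
}

#' @describeIn dl_fit One-row model summary: `k`, `tau2`, `q`, `i2`, and
#'   the fixed-effect comparators.
#' @method glance dl_fit
#' @export
glance.dl_fit <- function(x, ...) {
  tibble::tibble(
    k = x$k, m = x$m, se_m = x$se_m, tau2 = x$tau2, q = x$q, i2 = x$i2,
    m_fixed = x$m_fixed, se_fixed = x$se_fixed
  )
}
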