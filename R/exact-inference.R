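#' Exact conditional distribution of a sufficient statistic
#'
#' A `cond_dist` holds the support and log base weights of the conditional
#' distribution of the sufficient statistic `T` for a log odds(-ratio)
#' parameter `beta = log(psi)`:
#' `P_psi(T = t) = c_t psi^t / sum_s c_s psi^s`.  The weights `c_t` are the
#' coefficients of the conditional generating polynomial at `psi = 1`
#' (binomial-coefficient products for a 2x2 table; subset counts for a
#' continuous covariate) and are stored as logarithms so very large counts
#' never overflow.
#'
#' @name cond_dist
NULL

new_cond_dist <- function(support, log_weights, t_obs = NA_real_,
                          kind = "generic") {
  stopifnot(length(support) == length(log_weights))
  support <- as.numeric(support)
  o <- order(support)
  structure(
    list(
      support = support[o], log_weights = log_weights[o], t_obs = t_obs,
      degenerate = length(support) == 1L, kind = kind
    ),
    class = "cond_dist"
  )
}

#' @export
print.cond_dist <- function(x, ...) {
  cat(sprintf(
    "Exact conditional distribution (%s): %d support point(s) in [%g, %g]%s\n",
    x$kind, length(x$support), min(x$support), max(x$support),
    if (x$degenerate) " [degenerate]" else ""
  ))
  invisible(x)
}

#' Probability mass of a conditional distribution at a given log odds ratio
#'
#' @param dist A [cond_dist] object.
#' @param log_psi Log odds(-ratio) parameter value.
#' @return Numeric vector of probabilities over `dist$support`, summing
#'   to 1.
#' @export
cond_dist_pmf <- function(dist, log_psi = 0) {
  lp <- dist$log_weights + dist$support * log_psi
  lp <- lp - max(lp)
  p <- exp(lp)
  p / sum(p)
}

cond_dist_mean <- function(dist, log_psi = 0) {
  sum(cond_dist_pmf(dist, log_psi) * dist$support)
}

as_table_2x2 <- function(x) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (is.table(x)) x <- unclass(x)
  if (!is.matrix(x) || !all(dim(x) == c(2, 2))) {
    abort("expected a 2x2 table of counts")
  }
  if (any(x < 0) || any(x != round(x))) {
    abort("cell counts must be nonnegative integers")
  }
  x
}

#' Conditional distribution of the (2,2) cell of a 2x2 table
#'
#' Rows index the covariate (reference level first), columns the outcome
#' (non-event first).  Conditioning on all margins, the sufficient statistic
#' is the event count in the second row, whose noncentral (extended)
#' hypergeometric weights are `c_t = C(n2, t) C(n1, s - t)` with `n1`, `n2`
#' the row totals and `s` the event column total.  The odds-ratio parameter
#' `psi` compares row 2 to row 1.
#'
#' @param x A 2x2 matrix of counts.
#' @return A [cond_dist] with `t_obs = x[2, 2]`.  Degenerate margins (an
#'   empty row or outcome column) give a single-point support, flagged via
#'   `$degenerate`.
#' @examples
#' cond_dist_2x2(matrix(c(1, 1, 1, 1), 2))
#' @export
cond_dist_2x2 <- function(x) {
  x <- as_table_2x2(x)
  n1 <- sum(x[1, ]); n2 <- sum(x[2, ]); s <- sum(x[, 2])
  if (n1 + n2 == 0) abort("empty table")
  support <- max(0, s - n1):min(n2, s)
  new_cond_dist(
    support, lchoose(n2, support) + lchoose(n1, s - support),
    t_obs = x[2, 2], kind = "2x2"
  )
}

# elementwise log(exp(a) + exp(b)) robust to -Inf
logaddexp <- function(a, b) {
  m <- pmax(a, b)
  out <- m + log1p(exp(pmin(a, b) - m))
  out[is.infinite(m) & m < 0] <- -Inf
  out
}

#' Conditional distribution for a single continuous covariate
#'
#' Exact logistic regression conditions on the number of events `m`; the
#' sufficient statistic for the slope is `T = sum of x_i over the events`.
#' The weight `c_t` is the number of size-`m` subsets of the covariate
#' multiset attaining sum `t`, computed by dynamic programming over
#' (subset size, subset sum) in log space — never by explicit subset
#' enumeration.  Covariate values must be integer-valued (e.g. calendar
#' years); they are shifted by their minimum internally, which leaves the
#' slope unchanged, and the support is reported on the original scale.
#'
#' @param x Integer-valued numeric covariate vector.
#' @param y Logical (or 0/1) outcome vector of the same length, with at
#'   least one event and one non-event.
#' @return A [cond_dist] with `t_obs = sum(x[y == 1])`.
#' @examples
#' cond_dist_continuous(c(1, 1, 2), c(TRUE, FALSE, FALSE))
#' @export
cond_dist_continuous <- function(x, y) {
  y <- as.logical(y)
  if (length(x) != length(y)) abort("x and y must have the same length")
  if (anyNA(x) || anyNA(y)) abort("x and y must be complete")
  if (any(abs(x - round(x)) > 1e-8)) {
    abort("covariate values must be integer-valued")
  }
  m <- sum(y)
  n <- length(y)
  if (m == 0 || m == n) abort("conditional distribution degenerate")

  x <- as.integer(round(x))
  xmin <- min(x)
  xo <- x - xmin
  max_t <- sum(sort(xo, decreasing = TRUE)[seq_len(m)])

  # L[s + 1, t + 1] = log(number of size-s subsets with offset-sum t)
  L <- matrix(-Inf, nrow = m + 1, ncol = max_t + 1)
  L[1, 1] <- 0
  for (i in seq_len(n)) {
    xi <- xo[i]
    top <- min(m - 1, i - 1)
    for (s in top:0) {
      row <- L[s + 1, ]
      shifted <- if (xi > 0) {
        c(rep(-Inf, xi), row[seq_len(max_t + 1 - xi)])
      } else {
        row
      }
      L[s + 2, ] <- logaddexp(L[s + 2, ], shifted)
    }
  }
  lw <- L[m + 1, ]
  keep <- lw > -Inf
  new_cond_dist(
    which(keep) - 1 + m * xmin, lw[keep],
    t_obs = sum(x[y]), kind = "continuous"
  )
}

check_in_support <- function(dist, t_obs) {
  if (!any(abs(dist$support - t_obs) < 1e-9)) {
    abort(sprintf("t_obs = %g is not in the support", t_obs))
  }
}

# Safeguarded root finding for a monotone-increasing f of beta = log(psi).
# Starts from [-30, 30] and doubles the failing end on demand.
solve_monotone <- function(f, lower = -30, upper = 30, tol = 1e-12) {
  fl <- f(lower); fu <- f(upper)
  tries <- 0
  while (fl > 0 && tries < 12) {
    upper <- lower; fu <- fl
    lower <- lower * 2; fl <- f(lower); tries <- tries + 1
  }
  tries <- 0
  while (fu < 0 && tries < 12) {
    lower <- upper; fl <- fu
    upper <- upper * 2; fu <- f(upper); tries <- tries + 1
  }
  if (fl > 0 || fu < 0) abort("root finding failed to bracket a solution")
  uniroot(f, c(lower, upper), f.lower = fl, f.upper = fu, tol = tol)$root
}

#' Two-sided Fisher exact p-value from a conditional distribution
#'
#' Probability-mass ordering at the null `psi = 1`: the p-value sums the
#' null probabilities of all support points no more probable than the
#' observed one, with a `(1 + 1e-7)` relative tolerance guarding ties at
#' machine precision.
#'
#' @param dist A [cond_dist].
#' @param t_obs Observed sufficient statistic; defaults to the one recorded
#'   in `dist`.
#' @return A p-value in `(0, 1]`.
#' @examples
#' fisher_exact_p(cond_dist_2x2(matrix(c(53, 45, 6, 17), 2)))
#' @export
fisher_exact_p <- function(dist, t_obs = dist$t_obs) {
  check_in_support(dist, t_obs)
  p <- cond_dist_pmf(dist, 0)
  p_obs <- p[which.min(abs(dist$support - t_obs))]
  min(1, sum(p[p <= p_obs * (1 + 1e-7)]))
}

#' Freeman-Halton exact test for an r x 2 table
#'
#' Generalises the Fisher exact test: all tables compatible with the
#' observed margins are enumerated and the p-value sums the multivariate
#' hypergeometric probabilities of those no more probable than the observed
#' table (same `(1 + 1e-7)` tie tolerance as [fisher_exact_p()]).
#'
#' @param x An `r x 2` matrix of nonnegative integer counts, `r >= 2`.
#' @param max_tables Enumeration guard: error if the number of candidate
#'   tables exceeds this.
#' @return A p-value in `(0, 1]`.
#' @export
fisher_exact_rxc <- function(x, max_tables = 1e7) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x) || ncol(x) != 2 || nrow(x) < 2) {
    abort("expected an r x 2 matrix with r >= 2")
  }
  if (any(x < 0) || any(x != round(x))) {
    abort("cell counts must be nonnegative integers")
  }
  rows <- rowSums(x)
  s <- sum(x[, 2])
  n <- sum(rows)
  if (s == 0 || s == n) return(1)
  if (prod(pmin(rows, s) + 1) > max_tables) {
    abort(paste(
      "enumeration guard exceeded; use a Monte-Carlo approximation",
      "(not provided)"
    ))
  }
  # log-probability of event-column counts a (given margins):
  #   sum_i C(rows_i, a_i) / C(n, s)
  lden <- lchoose(n, s)
  table_logp <- function(a) sum(lchoose(rows, a)) - lden

  r <- length(rows)
  logps <- numeric(0)
  recurse <- function(i, remaining, acc) {
    if (i == r) {
      if (remaining <= rows[r]) {
        logps[length(logps) + 1] <<- acc + lchoose(rows[r], remaining)
      }
      return(invisible())
    }
    lo <- max(0, remaining - sum(rows[(i + 1):r]))
    hi <- min(rows[i], remaining)
    if (lo > hi) return(invisible())
    for (a in lo:hi) {
      recurse(i + 1, remaining - a, acc + lchoose(rows[i], a))
    }
  }
  recurse(1, s, -lden)
  lp_obs <- table_logp(x[, 2])
  p <- exp(logps)
  min(1, sum(p[logps <= lp_obs + log1p(1e-7)]))
}

#' Conditional maximum-likelihood / median-unbiased odds ratio
#'
#' For an interior observed statistic the conditional MLE solves
#' `E_psi(T) = t_obs` (the conditional mean is strictly increasing in
#' `log psi`, so a safeguarded root search converges to `|E - t_obs| <
#' 1e-10`).  When `t_obs` sits at an end of the support the likelihood has
#' no interior maximum and the median-unbiased estimate is reported
#' instead: the `psi` placing probability one half on the observed tail,
#' `P_psi(T <= t_obs) = 0.5` at the minimum (resp. `P_psi(T >= t_obs) =
#' 0.5` at the maximum).
#'
#' @inheritParams fisher_exact_p
#' @return A list with `estimate` (odds ratio) and `kind`
#'   (`"conditional_mle"` or `"median_unbiased"`).
#' @examples
#' conditional_mle(cond_dist_2x2(matrix(c(53, 45, 6, 17), 2)))
#' @export
conditional_mle <- function(dist, t_obs = dist$t_obs) {
  check_in_support(dist, t_obs)
  if (dist$degenerate) abort("estimate undefined: single-point support")
  at_min <- abs(t_obs - min(dist$support)) < 1e-9
  at_max <- abs(t_obs - max(dist$support)) < 1e-9
  if (at_min || at_max) {
    # observed tail probability is monotone in beta: P(T <= min) decreases,
    # P(T >= max) increases
    f <- if (at_min) {
      function(beta) 0.5 - sum(cond_dist_pmf(dist, beta)[
        dist$support <= t_obs + 1e-9
      ])
    } else {
      function(beta) sum(cond_dist_pmf(dist, beta)[
        dist$support >= t_obs - 1e-9
      ]) - 0.5
    }
    beta <- solve_monotone(f)
    return(list(estimate = exp(beta), kind = "median_unbiased"))
  }
  beta <- solve_monotone(function(b) cond_dist_mean(dist, b) - t_obs)
  list(estimate = exp(beta), kind = "conditional_mle")
}

#' Exact tail-inversion confidence interval for the odds ratio
#'
#' The lower limit solves `P_psi(T >= t_obs) = alpha / 2` and the upper
#' limit `P_psi(T <= t_obs) = alpha / 2`, each by root finding on
#' `log psi`.  At the ends of the support the corresponding limit is exact:
#' 0 below the minimum, infinity above the maximum.
#'
#' @inheritParams fisher_exact_p
#' @param level Confidence level in `(0, 1)`.
#' @return Numeric vector `c(lower, upper)` on the odds-ratio scale.
#' @export
exact_ci <- function(dist, t_obs = dist$t_obs, level = 0.95) {
  check_in_support(dist, t_obs)
  if (dist$degenerate) abort("interval undefined: single-point support")
  if (level <= 0 || level >= 1) abort("level must be in (0, 1)")
  alpha <- 1 - level
  upper_tail <- function(beta) {
    sum(cond_dist_pmf(dist, beta)[dist$support >= t_obs - 1e-9])
  }
  lower_tail <- function(beta) {
    sum(cond_dist_pmf(dist, beta)[dist$support <= t_obs + 1e-9])
  }
  lo <- if (abs(t_obs - min(dist$support)) < 1e-9) {
    0
  } else {
    exp(solve_monotone(function(b) upper_tail(b) - alpha / 2))
  }
  hi <- if (abs(t_obs - max(dist$support)) < 1e-9) {
    Inf
  } else {
    exp(solve_monotone(function(b) alpha / 2 - lower_tail(b)))
  }
  c(lo, hi)
}

#' Exact conditional odds-ratio test
#'
#' High-level wrapper combining the conditional distribution, the point
#' estimate (conditional MLE, or median-unbiased at the support boundary),
#' the exact tail-inversion CI, and the probability-ordering exact p-value.
#' Give either a 2x2 count matrix (rows = covariate levels with the
#' reference first, columns = outcome with non-events first) or a
#' continuous integer-valued covariate with a binary outcome.
#'
#' @param x A 2x2 matrix of counts, or a numeric covariate vector.
#' @param y For the continuous case, the logical outcome vector.
#' @param level Confidence level.
#' @return An object of class `"exact_or_test"` with fields `estimate`,
#'   `kind`, `ci_lower`, `ci_upper`, `p_value`, `t_obs`, `level`, `dist`.
#'   [tidy()] and [glance()] methods return tibbles.
#' @examples
#' prospero <- matrix(c(53, 45, 6, 17), nrow = 2) # rows: not/registered
#' exact_or_test(prospero)
#' @export
exact_or_test <- function(x, y = NULL, level = 0.95) {
  dist <- if (is.null(y)) {
    cond_dist_2x2(x)
  } else {
    cond_dist_continuous(x, y)
  }
  est <- conditional_mle(dist)
  ci <- exact_ci(dist, level = level)
  structure(
    list(
      estimate = est$estimate, kind = est$kind,
      ci_lower = ci[1], ci_upper = ci[2],
      p_value = fisher_exact_p(dist),
      t_obs = dist$t_obs, level = level, dist = dist
    ),
    class = "exact_or_test"
  )
}

#' @export
print.exact_or_test <- function(x, ...) {
  cat("Exact conditional odds-ratio test\n")
  cat(sprintf(
    "  OR = %.4f (%s), %g%% CI [%.4f, %s], exact p = %.4g\n",
    x$estimate, x$kind, 100 * x$level, x$ci_lower,
    if (is.infinite(x$ci_upper)) "Inf" else sprintf("%.4f", x$ci_upper),
    x$p_value
  ))
  invisible(x)
}

#' @describeIn exact_or_test One-row tibble with `estimate`, `kind`,
#'   `conf.low`, `conf.high`, `p.value`, `statistic` (the observed
#'   sufficient statistic).
#' @param ... Unused.
#' @method tidy exact_or_test
#' @export
tidy.exact_or_test <- function(x, ...) {
  tibble::tibble(
    estimate = x$estimate, kind = x$kind,
    conf.low = x$ci_lower, conf.high = x$ci_upper,
    p.value = x$p_value, statistic = x$t_obs
  )
}

#' @describeIn exact_or_test One-row tibble with the support size and
#'   confidence level alongside the estimates.
#' @method glance exact_or_test
#' @export
glance.exact_or_test <- function(x, ...) {
  tibble::tibble(
    estimate = x$estimate, p.value = x$p_value,
    support_size = length(x$dist$support), level = x$level
  )
}
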