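test_that("standard errors back-calculate from CIs in closed form", {
  # worked example: OR 1.35, 95% CI 0.99-1.83 -> log-scale SE
  expect_equal(
    back_calculate_se(0.99, 1.83, "OR"),
    (log(1.83) - log(0.99)) / (2 * 1.959964)
  )
  expect_equal(back_calculate_se(0.99, 1.83, "OR"), 0.15673, tolerance = 1e-4)
  expect_equal(back_calculate_se(-1, 1, "MD"), 0.51021, tolerance = 1e-4)
  # z-approximation switch reproduces hand-calculated values
  expect_equal(back_calculate_se(-1, 1, "MD", z = 1.96), 1 / 1.96)
  expect_error(back_calculate_se(1, 1, "OR"), "ci_lower < ci_upper")
  expect_error(back_calculate_se(-0.5, 1.5, "RR"), "positive")
})

test_that("Wald p-value matches the worked example and its identities", {
  se <- back_calculate_se(0.99, 1.83, "OR")
  p <- wald_p(log(1.35), se)
  expect_equal(round(p, 2), 0.06)
  expect_identical(wald_p(0, 0.3), 1)
  expect_equal(wald_p(1.959964 * 0.2, 0.2), 0.05, tolerance = 1e-6)
  expect_error(wald_p(0.1, 0), "positive")
})

test_that("prediction interval follows the t(k - 2) construction", {
  pi <- prediction_interval(0.5, 0.1, tau2 = 0.04, k = 5)
  expect_equal(qt(0.975, 3), 3.18245, tolerance = 1e-5)
  expect_equal(pi$lower, -0.21162, tolerance = 1e-4)
  expect_equal(pi$upper, 1.21162, tolerance = 1e-4)
  expect_false(pi$significant)
  expect_identical(pi$null_value, 0)

  # ratio measures are exponentiated back to the reported scale
  pio <- prediction_interval(log(1.35), 0.15, 0.02, 6, "OR")
  expect_equal(sqrt(pio$lower * pio$upper), 1.35, tolerance = 1e-9)
  expect_identical(pio$null_value, 1)

  # tau2 = 0, large k: PI converges to the z-based CI
  pi_lim <- prediction_interval(0.3, 0.05, 0, 100000, "MD")
  expect_equal(pi_lim$upper - pi_lim$lower, 2 * 1.959964 * 0.05,
    tolerance = 1e-4
  )

  # degenerate: se -> 0, tau2 = 0 collapses to the point estimate
  pi0 <- prediction_interval(0, 1e-12, 0, 5, "MD")
  expect_equal(pi0$lower, 0, tolerance = 1e-10)
  expect_false(pi0$significant)

  expect_error(prediction_interval(0, 0.1, 0.1, 2), "three trials")
  expect_error(prediction_interval(0, 0.1, -0.1, 5), "nonnegative")
})

test_that("PI nests the CI and is monotone in tau2 and k", {
  set.seed(42)
  n <- 2000
  m <- rnorm(n, 0, 1)
  se <- runif(n, 0.01, 0.5)
  tau2 <- runif(n, 0, 0.5) * rbinom(n, 1, 0.8) # include exact zeros
  k <- sample(3:50, n, replace = TRUE)
  measure <- sample(c("MD", "SMD", "RR", "OR"), n, replace = TRUE)
  pi <- prediction_interval(m, se, tau2, k, measure)
  ci <- confidence_interval(m, se, measure)
  expect_true(all(pi$lower <= ci$lower + 1e-12))
  expect_true(all(pi$upper >= ci$upper - 1e-12))
  # PI significant implies CI significant, never the converse
  expect_false(any(pi$significant & !ci$significant))
  # width strictly increases in tau2, strictly decreases in k
  pi_t <- prediction_interval(m, se, tau2 + 0.1, k, measure)
  pi_k <- prediction_interval(m, se, tau2, k + 5, measure)
  w <- function(x, meas) {
    out <- x$upper - x$lower
    r <- meas %in% c("RR", "OR")
    out[r] <- log(x$upper[r]) - log(x$lower[r])
    out
  }
  expect_true(all(w(pi_t, measure) > w(pi, measure)))
  expect_true(all(w(pi_k, measure) < w(pi, measure)))
})

test_that("agreement classification covers the taxonomy and rejects corrupt input", {
  # CI significant, PI spans the null
  expect_identical(
    as.character(classify_agreement(
      interval_significant(0.2, 0.8, "MD"),
      interval_significant(-0.1, 1.1, "MD")
    )),
    "ci_sig_pi_not"
  )
  expect_identical(
    as.character(classify_agreement(
      interval_significant(1.10, 1.50, "OR"),
      interval_significant(1.05, 1.60, "OR")
    )),
    "corroborated_significant"
  )
  expect_identical(
    as.character(classify_agreement(FALSE, FALSE)), "both_nonsignificant"
  )
  expect_identical(
    as.character(classify_agreement(TRUE, NA)), "not_computable"
  )
  expect_error(classify_agreement(FALSE, TRUE), "nesting")
})

test_that("add_intervals wires corpus columns to the interval engine", {
  corpus <- filter_eligible(toy_corpus())
  out <- add_intervals(dplyr::filter(corpus, eligible))
  expect_identical(nrow(out), 3L)
  expect_true(all(c("se_m", "pi_lower", "agreement") %in% names(out)))
  # ratio record analysed on the log scale
  or_row <- dplyr::filter(out, effect_measure == "OR")
  expect_equal(or_row$m, log(1.35))
  # tau2 present and k >= 3 -> computable
  expect_true(all(out$pi_computable == !is.na(out$tau2)))
  expect_identical(
    as.character(out$agreement[is.na(out$tau2)]), character(0)
  )
})
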