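test_that("2x2 conditional weights match brute-force enumeration", {
  d <- cond_dist_2x2(matrix(c(1, 1, 1, 1), 2))
  expect_equal(d$support, c(0, 1, 2))
  expect_equal(exp(d$log_weights), c(1, 4, 1)) # C(2,t) C(2, 2 - t)
  # ((5,0),(0,5)): margins force support 0..5 with symmetric weights
  d2 <- cond_dist_2x2(matrix(c(5, 0, 0, 5), 2))
  expect_equal(d2$support, 0:5)
  w <- exp(d2$log_weights)
  expect_equal(w, rev(w))
  # empty row collapses the support to a single flagged point
  d3 <- cond_dist_2x2(matrix(c(3, 0, 4, 0), 2))
  expect_true(d3$degenerate)
  expect_identical(length(d3$support), 1L)
})

test_that("conditional pmf sums to one over a psi grid and has monotone mean", {
  set.seed(5)
  for (tab in random_tables_2x2(20)) {
    d <- cond_dist_2x2(tab)
    for (lp in c(-3, -1, 0, 1, 3)) {
      expect_equal(sum(cond_dist_pmf(d, lp)), 1, tolerance = 1e-12)
    }
    if (!d$degenerate) {
      grid <- seq(-4, 4, by = 0.5)
      means <- vapply(
        grid, function(b) sum(cond_dist_pmf(d, b) * d$support), numeric(1)
      )
      expect_true(all(diff(means) > 0))
    }
  }
})

test_that("continuous-covariate DP equals subset enumeration at small n", {
  d <- cond_dist_continuous(c(1, 2, 3), c(TRUE, FALSE, FALSE))
  expect_equal(d$support, c(1, 2, 3))
  expect_equal(exp(d$log_weights), c(1, 1, 1))
  d2 <- cond_dist_continuous(c(1, 1, 2), c(TRUE, FALSE, FALSE))
  expect_equal(d2$support, c(1, 2))
  expect_equal(exp(d2$log_weights), c(2, 1))

  set.seed(9)
  for (i in 1:25) {
    n <- sample(5:15, 1)
    x <- sample(0:8, n, replace = TRUE)
    m <- sample(seq_len(n - 1), 1)
    y <- seq_len(n) %in% sample(n, m)
    d <- cond_dist_continuous(x, y)
    ora <- oracle_subset_counts(x, m)
    expect_equal(d$support, as.numeric(names(ora)))
    expect_equal(exp(d$log_weights), as.numeric(ora), tolerance = 1e-10)
  }
  expect_error(
    cond_dist_continuous(c(1, 2), c(TRUE, TRUE)), "degenerate"
  )
})

test_that("large DP instances agree with enumeration on a subsample", {
  obs <- year_observations()
  d <- cond_dist_continuous(obs$x, obs$y)
  # support is bounded by the extreme size-23 subset sums
  expect_lte(length(d$support), diff(range(d$support)) + 1)
  sub <- c(1:6, 60:65)
  x_sub <- obs$x[sub]
  y_sub <- obs$y[sub]
  d_sub <- cond_dist_continuous(x_sub, y_sub)
  ora <- oracle_subset_counts(x_sub, sum(y_sub))
  expect_equal(d_sub$support, as.numeric(names(ora)))
  expect_equal(exp(d_sub$log_weights), as.numeric(ora), tolerance = 1e-10)
})

test_that("Fisher p matches enumeration oracle and stats::fisher.test", {
  # perfectly balanced table
  expect_equal(fisher_exact_p(cond_dist_2x2(matrix(5, 2, 2))), 1)
  set.seed(13)
  for (tab in random_tables_2x2(40)) {
    d <- cond_dist_2x2(tab)
    p <- fisher_exact_p(d)
    expect_equal(p, oracle_fisher_p_2x2(tab), tolerance = 1e-12)
    expect_equal(p, fisher.test(tab)$p.value, tolerance = 1e-9)
  }
})

test_that("Freeman-Halton test reduces to Fisher on 2x2 and matches enumeration", {
  set.seed(17)
  for (tab in random_tables_2x2(15)) {
    expect_equal(
      fisher_exact_rxc(tab),
      fisher_exact_p(cond_dist_2x2(tab)),
      tolerance = 1e-12
    )
  }
  for (i in 1:10) {
    tab <- matrix(sample(0:6, 6, replace = TRUE), 3)
    if (any(colSums(tab) == 0) || any(rowSums(tab) == 0)) next
    expect_equal(
      fisher_exact_rxc(tab), fisher.test(tab)$p.value, tolerance = 1e-9
    )
  }
  expect_error(
    fisher_exact_rxc(matrix(1000L, 5, 2), max_tables = 10),
    "enumeration guard"
  )
})

test_that("conditional MLE solves the mean equation and handles boundaries", {
  # symmetric table -> OR exactly 1
  d <- cond_dist_2x2(matrix(5, 2, 2))
  est <- conditional_mle(d)
  expect_equal(est$estimate, 1, tolerance = 1e-9)
  expect_identical(est$kind, "conditional_mle")

  # interior estimate satisfies E_psi(T) = t_obs to 1e-10
  tab <- matrix(c(53, 45, 6, 17), 2)
  d <- cond_dist_2x2(tab)
  fit <- conditional_mle(d)
  p <- cond_dist_pmf(d, log(fit$estimate))
  expect_lt(abs(sum(p * d$support) - d$t_obs), 1e-9)
  # attenuated relative to the sample cross-product ratio 3.34
  expect_lt(fit$estimate, 53 * 17 / (45 * 6))

  # boundary table -> median-unbiased estimate
  db <- cond_dist_2x2(matrix(c(92, 6, 23, 0), 2))
  mue <- conditional_mle(db)
  expect_identical(mue$kind, "median_unbiased")
  pm <- cond_dist_pmf(db, log(mue$estimate))
  expect_equal(pm[1], 0.5, tolerance = 1e-9)

  expect_error(
    conditional_mle(cond_dist_2x2(matrix(c(3, 0, 4, 0), 2))), "undefined"
  )
})

test_that("conditional MLE agrees with stats::fisher.test and is equivariant", {
  set.seed(19)
  for (tab in random_tables_2x2(25)) {
    d <- cond_dist_2x2(tab)
    if (d$degenerate) next
    interior <- d$t_obs > min(d$support) && d$t_obs < max(d$support)
    if (!interior) next
    est <- conditional_mle(d)$estimate
    expect_equal(est, unname(fisher.test(tab)$estimate), tolerance = 1e-4)
    # swapping rows (or outcome columns) inverts the odds ratio
    est_swap <- conditional_mle(cond_dist_2x2(tab[2:1, ]))$estimate
    expect_equal(est_swap, 1 / est, tolerance = 1e-8)
    est_cols <- conditional_mle(cond_dist_2x2(tab[, 2:1]))$estimate
    expect_equal(est_cols, 1 / est, tolerance = 1e-8)
  }
})

test_that("exact CI inverts the tails and matches stats::fisher.test", {
  tab <- matrix(c(53, 45, 6, 17), 2)
  d <- cond_dist_2x2(tab)
  ci <- exact_ci(d)
  ft <- fisher.test(tab)
  # fisher.test inverts the same tails with ~1e-4 relative root error
  expect_equal(ci[1], ft$conf.int[1], tolerance = 1e-3)
  expect_equal(ci[2], ft$conf.int[2], tolerance = 1e-3)
  # tail probabilities hit alpha/2 at the limits
  pl <- cond_dist_pmf(d, log(ci[1]))
  expect_equal(sum(pl[d$support >= d$t_obs]), 0.025, tolerance = 1e-9)

  # boundary: lower limit exactly zero, finite upper limit
  db <- cond_dist_2x2(matrix(c(92, 6, 23, 0), 2))
  cib <- exact_ci(db)
  expect_identical(cib[1], 0)
  expect_equal(cib[2], 3.66, tolerance = 0.01)

  # symmetric table: interval symmetric about 1 on the log scale
  cis <- exact_ci(cond_dist_2x2(matrix(5, 2, 2)))
  expect_equal(log(cis[1]) + log(cis[2]), 0, tolerance = 1e-8)
})

test_that("exact_or_test assembles estimate, CI and p for both input kinds", {
  fit <- exact_or_test(matrix(c(53, 45, 6, 17), 2))
  td <- tidy(fit)
  expect_named(
    td, c("estimate", "kind", "conf.low", "conf.high", "p.value", "statistic")
  )
  expect_equal(td$statistic, 17)

  obs <- year_observations()
  fy <- exact_or_test(obs$x, obs$y)
  expect_identical(fy$kind, "conditional_mle")
  expect_lt(fy$estimate, 1)
  expect_gt(glance(fy)$support_size, 100)
})
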