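# Independent oracles used to cross-check the package's implementations.
# Each is coded from the defining formula, not by calling package internals.

# Fisher two-sided p by direct enumeration over tables sharing the observed
# margins, with table probabilities from the multivariate hypergeometric
# factorial formula (probability-mass ordering, 1 + 1e-7 tie tolerance).
oracle_fisher_p_2x2 <- function(tab) {
  n1 <- sum(tab[1, ]); n2 <- sum(tab[2, ]); s <- sum(tab[, 2])
  n <- n1 + n2
  logp <- function(a22) {
    # table fully determined by the (2,2) cell given margins
    a21 <- n2 - a22; a12 <- s - a22; a11 <- n1 - a12
    if (min(a11, a12, a21, a22) < 0) return(-Inf)
    lgamma(n1 + 1) + lgamma(n2 + 1) + lgamma(s + 1) + lgamma(n - s + 1) -
      lgamma(n + 1) - lgamma(a11 + 1) - lgamma(a12 + 1) -
      lgamma(a21 + 1) - lgamma(a22 + 1)
  }
  cand <- 0:min(n2, s)
  lps <- vapply(cand, logp, numeric(1))
  keep <- is.finite(lps)
  lps <- lps[keep]
  lp_obs <- logp(tab[2, 2])
  min(1, sum(exp(lps[lps <= lp_obs + log1p(1e-7)])))
}

# subset-sum counts by explicit enumeration (small n only)
oracle_subset_counts <- function(x, m) {
  sums <- combn(length(x), m, function(idx) sum(x[idx]))
  table(sums)
}

# one-pass DerSimonian-Laird fit, written independently of dl_fit()
oracle_dl <- function(y, v) {
  w <- 1 / v
  mf <- weighted.mean(y, w)
  q <- sum(w * (y - mf)^2)
  tau2 <- max(0, (q - (length(y) - 1)) / (sum(w) - sum(w^2) / sum(w)))
  wr <- 1 / (v + tau2)
  list(
    m = weighted.mean(y, wr), se = sqrt(1 / sum(wr)),
    tau2 = tau2, q = q
  )
}

# random nondegenerate 2x2 tables (both outcome columns occupied)
random_tables_2x2 <- function(n_tables, n_max = 40) {
  out <- vector("list", n_tables)
  i <- 1
  while (i <= n_tables) {
    tab <- matrix(sample(0:(n_max %/% 4), 4, replace = TRUE), 2)
    if (all(rowSums(tab) > 0) && all(colSums(tab) > 0)) {
      out[[i]] <- tab
      i <- i + 1
    }
  }
  out
}

# a small fully valid corpus written as code, for I/O round trips
toy_corpus <- function() {
  tibble::tibble(
    sr_id = c("SR1", "SR2", "SR3", "SR4"),
    year = c(2015L, 2018L, 2019L, 2020L),
    n_authors = c(4L, 5L, 6L, 5L),
    continent = factor(
      c("Europe", "Americas", "AsiaOther", "Europe"),
      levels = c("Europe", "Americas", "AsiaOther")
    ),
    prospero = c(TRUE, FALSE, TRUE, TRUE),
    cochrane = c(FALSE, FALSE, TRUE, FALSE),
    pi_reported = c(TRUE, FALSE, FALSE, FALSE),
    pi_discussed = factor(
      c("yes", "not_applicable", "not_applicable", "not_applicable"),
      levels = c("no", "yes", "not_applicable")
    ),
    k_trials = c(5L, 3L, 2L, 8L),
    effect_measure = factor(
      c("OR", "MD", "SMD", "RR"), levels = c("MD", "SMD", "RR", "OR")
    ),
    pooled_estimate = c(1.35, 0.40, -0.20, 0.85),
    ci_lower = c(0.99, 0.10, -0.60, 0.70),
    ci_upper = c(1.83, 0.70, 0.20, 1.03),
    tau2 = c(0.04, 0.02, NA, 0.01),
    reported_significant = factor(
      c("no", "yes", "no", "no"), levels = c("no", "yes", "not_reported")
    )
  )
}

# Table 1 per-year reconstruction: counts of reviews not reporting /
# reporting a prediction interval by publication year
year_observations <- function() {
  years <- 2012:2021
  total <- c(1, 3, 6, 8, 14, 22, 25, 21, 19, 2)
  reported <- c(1, 1, 1, 2, 3, 4, 4, 5, 2, 0)
  list(
    x = rep(years, total),
    y = rep(
      rep(c(TRUE, FALSE), length(years)),
      as.vector(rbind(reported, total - reported))
    )
  )
}
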