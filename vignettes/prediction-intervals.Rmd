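---
title: "Prediction intervals in random-effects meta-analysis: model, exact inference, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prediction intervals in random-effects meta-analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metapi)
```

## The model

A random-effects meta-analysis assumes each of $k$ trials estimates its own
true effect $\theta_i \sim N(\mu, \tau^2)$, observed with within-study
variance $v_i$: $y_i \sim N(\theta_i, v_i)$. The pooled estimate $M$
approximates $\mu$; its 95% CI describes the precision of that mean. The
95% **prediction interval**

$$M \pm t_{0.975,\,k-2}\sqrt{\hat\tau^2 + \widehat{SE}(M)^2}$$

instead brackets the true effect $\theta_{new}$ of a hypothetical next
trial drawn from the same population of studies. The $t$ quantile with
$k-2$ degrees of freedom (not $k-1$; `df_offset` exposes the rule for
sensitivity analysis) is a pragmatic inflation acknowledging that
$\tau^2$ is itself estimated. Because
$t_{0.975,k-2} \ge z_{0.975}$ and $\tau^2 \ge 0$, the PI always contains
the recomputed CI; consequently a significant PI implies a significant CI
and never the converse. Both facts are asserted as randomized properties in
the test suite (10^4 draws).

The interval is defined only for $k \ge 3$ (so the $t$ distribution has at
least one degree of freedom); the eligibility filter encodes exactly that
three-trial rule, with every exclusion carrying a machine-readable reason.

## Working from published summaries

A corpus row rarely contains study-level data — only $M$, the reported 95%
CI, the effect measure, $k$, and (sometimes) $\tau^2$. The engine therefore:

* **back-calculates** $SE(M)$ as $(\text{upper} - \text{lower}) / (2z)$ on
  the identity scale for MD/SMD and on the natural-log scale for RR/OR.
  All ratio-measure work happens on the log scale and is exponentiated
  only at the boundary; MD and SMD are treated identically (null 0, ratio
  measures null 1).
* uses $z = 1.959964$ (the 97.5% normal point to six decimals) rather than
  1.96, so the closed form is reproducible; `z = 1.96` reproduces
  hand-calculated literature values. The difference is below any reported
  precision.
* treats $\tau^2 = 0$ as a valid input (the PI becomes a $t$-based
  interval around $M$), but a *missing* $\tau^2$ as **not computable** —
  it is never imputed as zero. This is what separates the corpus-level
  prevalence denominator from the smaller agreement-analysis denominator.
* judges CI significance from the *reported* bounds by default
  (`use_reported_ci = TRUE`). A recomputed CI ($M \pm z\,\widehat{SE}$) is
  available as an option; with the same $z$ used for back-calculation the
  two coincide, but the reported bounds are the authors' record and are
  kept authoritative. The authors' own significance verdict
  (`reported_significant`) is stored separately and never conflated with
  the recomputed one.

Agreement between the intervals is a four-level taxonomy: both significant
(the CI's message is *corroborated*), both non-significant, CI significant
but PI spanning the null, and not computable. The fifth combination — PI
significant, CI not — cannot occur for valid input and is treated as a
hard error rather than silently categorised.

## Exact conditional inference

Associations between review-level covariates and PI reporting involve
small cell counts (a zero cell in the review-type table), so asymptotic
logistic regression is inappropriate. Everything is built on the exact
conditional distribution of the sufficient statistic $T$:

$$P_\psi(T = t) = \frac{c_t\,\psi^t}{\sum_s c_s\,\psi^s},$$

For a 2×2 table the $c_t$ are noncentral-hypergeometric binomial products;
for a continuous covariate (publication year), conditioning on the number
of events $m$ makes $c_t$ the number of size-$m$ subsets of the covariate
multiset with sum $t$, computed by dynamic programming over (subset size,
subset sum) — never by explicit subset enumeration, which is infeasible at
$\binom{121}{23}\approx 10^{24}$.

* **Point estimate.** The conditional MLE solves $E_\psi(T) = t_{obs}$;
  the conditional mean is strictly increasing in $\log\psi$, so a
  safeguarded bisection (brackets $[-30, 30]$ on $\log\psi$, expanded on
  demand) converges to $|E - t_{obs}| < 10^{-10}$. When $t_{obs}$ sits at
  an end of the support the likelihood maximum is at 0 or $\infty$, so the
  **median-unbiased estimate** is reported instead: the $\psi$ placing
  probability one half on the observed tail. This matches the behaviour of
  the exact-logistic software family that prints a finite odds ratio for a
  zero-cell table.
* **CI.** Exact tail inversion: lower limit from
  $P_\psi(T \ge t_{obs}) = \alpha/2$, upper from
  $P_\psi(T \le t_{obs}) = \alpha/2$, with exact limits 0 / $\infty$ at
  the support boundary.
* **p-value.** Two-sided Fisher p by probability-mass ordering at
  $\psi = 1$ with a $(1 + 10^{-7})$ relative tie tolerance — the dominant
  convention (shared by `stats::fisher.test`), without which sums flip on
  ties at machine precision. The r×2 Freeman–Halton generalisation
  enumerates margin-compatible tables with a $10^7$-candidate guard.

**Numerical representation.** Weights are held as logarithms throughout
(log-sum-exp), so counts like $\binom{121}{23}$ never overflow and the
relative error (~$10^{-15}$) stays far below the $10^{-10}$ root-finding
tolerance. The DP requires integer-valued covariates (calendar years
qualify); values are shifted by their minimum internally, which leaves the
slope parameter unchanged.

Cross-checks in the suite: DP weights against explicit `combn`
enumeration at $n \le 15$; Fisher p against an independently coded
factorial-formula enumeration oracle on *every* 2×2 table with
$n \le 30$; conditional MLEs and exact CIs against `stats::fisher.test`
(whose independent solver carries ~$10^{-4}$ relative error, the
comparison tolerance); and row/column-swap equivariance
($\psi \mapsto 1/\psi$).

## The synthetic corpus generator

No per-record extraction table is publicly deposited, so pipeline-level
behaviour is validated on generated corpora with known truth. Defaults
describe a corpus of 121 reviews matching the published frequency
structure: effect-measure mix 64.5/19.0/9.1/7.4% (MD/SMD/RR/OR), τ²
blanked with probability 0.215, publication years 2012–2021 at the
observed totals, author counts $2 + \text{Poisson}(3)$ (median 5, IQR
about 4–6), and trial counts $3 + \text{Poisson}(4)$ with 10% mass at
$k = 2$ so the eligibility filter is exercised. True effects are drawn
$\mu \sim N(0.3, 0.2^2)$, heterogeneity
$\tau^2 \sim \text{Gamma}(1.2, \text{scale}=0.05)$, and within-study
variances $v_i \sim U(0.01, 0.1)$ — moderate heterogeneity typical of
clinical corpora. PROSPERO registration (prevalence 0.51) carries log
odds $\ln 3.3$ on reporting and Cochrane status (0.05) $\ln 0.5$,
echoing the published associations; a logistic model combines them.

Each review's study set is DL-fitted and the *estimates* — not the truth —
are written into the corpus schema, exactly as an extraction sheet records
a published review. The generating $\mu$, $\tau^2$ and fitted values
travel in a separate truth table. A single seed governs every draw, and
identical spec + seed yields a byte-identical corpus CSV.

What the generator does **not** emulate: publication bias, small-study
effects, non-normal random effects, rounding of published estimates, or
correlation between covariates. Passing pipeline tests on synthetic
corpora therefore demonstrates correctness of the computation and
accounting, not robustness to those real-data features.

## Calibration of the prediction interval

The coverage simulation (5000 meta-analyses at the generator's moderate-
heterogeneity conditions, $k$ drawn from 10–30, one new
$\theta_{new} \sim N(\mu, \tau^2)$ per replicate) shows empirical coverage
of the nominal 95% PI around 0.92, not 0.95. This is a known property of
the construction, not an implementation artefact: with $\hat\tau^2$
estimated by moments at moderate $I^2$, the interval under-covers even for
$k$ in the tens, and approaches nominal coverage only when $\tau^2$
dominates the within-study variances. The corresponding acceptance
expectation is asserted at the nominal band and documents the gap rather
than masking it; users drawing clinical conclusions from PIs computed off
summary data should read them as approximate at moderate heterogeneity.
Parameter recovery at the same conditions is clean: over 2000 replicates
at $k = 20$, the mean pooled estimate is within ±0.02 of $\mu$ and the
mean DL $\hat\tau^2$ within ±0.015 of $\tau^2$.

## Problem sizes and determinism

Test problem sizes: $10^4$ randomized summaries for the interval
properties; every 2×2 table to $n \le 30$ for the Fisher oracle scan;
$n \le 15$ for brute-force DP checks; 2000 replicates for DL recovery;
5000 for coverage. The pipeline itself is fully deterministic — re-running
on the same corpus writes byte-identical CSV/TSV/JSON outputs — and the
only randomness anywhere is in the generator, always under an explicit
seed.

## Forest-plot display

Several displays for the PI have been proposed (a hollow diamond; extra
whiskers on the summary diamond); both invite confusion with the CI. The
package draws the PI as a **rectangle on its own labelled row** below the
summary diamond, so the two interval types cannot be conflated; the
rectangle always spans at least the diamond by the nesting property, and
the layout is deterministic for a fixed input.
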