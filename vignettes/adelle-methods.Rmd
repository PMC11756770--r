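---
title: "Global trans-eQTL testing with dependence-adjusted equal local levels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Global trans-eQTL testing with dependence-adjusted equal local levels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adelle)
```

## The testing problem

A trans-eQTL typically perturbs the expression of several distant genes,
each weakly. Testing every SNP against every trans gene and correcting
for both dimensions of multiplicity demands per-pair p-values so small
that weak, distributed signals are invisible. This package instead tests,
for each SNP $m$, the *global* null hypothesis

$$H_0^{(m)}: \text{SNP } m \text{ is associated with none of its } D_m
\text{ trans expression traits},$$

using only per-trait association summary statistics (Z scores, or
p-values plus effect signs) and a trait correlation matrix. One test per
SNP leaves only SNP-wise multiplicity to correct, and a statistic tuned
to the *rare-weak* regime — a small fraction of traits carrying
individually weak signals — recovers exactly the signals the per-pair
strategy discards.

## Equal local levels for independent traits

Let $\pi_{(1)} \le \dots \le \pi_{(D)}$ be the sorted two-sided p-values
of one SNP against its $D$ trans traits. Under the global null with
independent traits, $\pi_{(d)} \sim \mathrm{Beta}(d,\,D-d+1)$. The
*l-value*

$$l_d = F_{\mathrm{Beta}(d,\,D-d+1)}\!\left(\pi_{(d)}\right)$$

measures how unusually small the $d$-th order statistic is, on a uniform
scale. The test statistic is the most significant of the first
$\xi = \lfloor qD \rfloor$ l-values, $T = \min_{d \le \xi} l_d$, with
truncation fraction $q$ defaulting to $0.2$: enrichment that only shows
up deep in the upper order statistics is neither expected for a
trans-eQTL nor interpretable. Rejecting when any $l_d < \eta$ uses the
same ("equal") local level $\eta$ for every rank.

The map from local to global level,
$\alpha(\eta) = P_0(T < \eta)$, is computed exactly: the event
$T < \eta$ is a crossing by the uniform order statistics of the boundary
$b_d = F^{-1}_{\mathrm{Beta}(d,\,D-d+1)}(\eta)$, $d \le \xi$, and the
no-crossing probability follows from a Markov-chain recursion over the
boundary cells with binomial increments (counts $N_j$ of p-values at or
below $b_j$ must satisfy $N_j \le j-1$). The recursion works in
probability space — every intermediate quantity is a probability, and
`dbinom` supplies stable binomial terms at any $D$ — so no log-space
rescaling is needed; a non-finite intermediate raises an internal error
rather than returning silently wrong output. `local_level_from_global()`
inverts $\alpha(\eta)$ by bisection on $(0, \alpha]$ to absolute
tolerance $10^{-4}\alpha$ (iteration cap 200); $\eta \le \alpha$ always
holds for $\xi \ge 1$. Configurations with $qD < 1$ are rejected
outright instead of silently testing only the minimum p-value.

## Adjusting for trait dependence

Expression traits are correlated, so the Beta marginals above are wrong
in practice. The adjustment models the per-SNP score vector under the
null as $Z \sim N_D(0, \Omega)$ with $\Omega$ the trait correlation
matrix, and $\pi_d = 2\Phi(-|Z_d|)$. The key identity is that
$\{\pi_{(d)} \le h\}$ and $\{S(c_h) \ge d\}$ are the *same event*, where
$S(c) = \#\{d : |Z_d| \ge c\}$ is the exceedance count and
$c_h = -\Phi^{-1}(h/2)$. The null cdf of each order statistic is
therefore a tail probability of $S$:

$$F_{(d)}(h) = P_0\!\left(S(c_h) \ge d\right).$$

Under dependence $S(c)$ keeps its binomial mean $D \cdot 2\Phi(-c)$ but
is over-dispersed:

$$\mathrm{Var}\,S(c) = D p (1-p) + \sum_{i \ne j}
\left[P\big(|Z_i| \ge c, |Z_j| \ge c\big) - p^2\right],
\qquad p = 2\Phi(-c).$$

The pairwise joint tail is a bivariate normal orthant combination,
reduced to a one-dimensional integral and evaluated by fixed 128-node
Gauss–Legendre quadrature on $[c,\,c+9]$ (the integrand carries a
standard-normal density factor, so the truncated mass is below
$10^{-18}$); the rule is vectorised over the correlation argument and
agrees with adaptive quadrature to $10^{-9}$. The $O(D^2)$ pairwise sum
is collapsed onto a histogram of the off-diagonal correlations (2,000
equal-width bins on $[-1,1]$, each occupied bin represented by its mean),
so each threshold costs one quadrature call per occupied bin.

$S(c)$ is then approximated by a beta-binomial
$\mathrm{BB}(D, \lambda, \gamma)$ whose first two moments match exactly
(method of moments; the moment equations are inverted in closed form).
When the implied variance inflation is negligible — uncorrelated traits,
or rounding-level excess where the matched $(\lambda,\gamma)$ would be
astronomically large and numerically meaningless — the exact binomial is
used instead, which makes the whole construction collapse to the
independence Beta l-values: with $\Omega = I$ the adjusted and
unadjusted tests coincide to $10^{-10}$. A variance above the
beta-binomial's attainable maximum $D^2\mu(1-\mu)$ signals a broken
correlation input and is an error.

The beta-binomial is an approximation, not an exact law: with matched
moments its cdf can still deviate from the true distribution of $S(c)$
by a few percent in the centre under strong global equicorrelation
(deviations in the upper tail, which shapes the l-values, are an order
of magnitude smaller). This is why significance is never read off the
approximation: it only shapes the statistic, while p-values come from
Monte Carlo under the same model, so test validity does not depend on
approximation quality.

## Precompute grid and Monte Carlo significance

`build_null_grid()` tabulates $\log F_{(d)}(h)$ for $d = 1..\xi$ on a
grid of 600 log-spaced thresholds from $10^{-16}$ up to the threshold
where $F_{(1)} = 1/2$, completed by 240 thresholds equally spaced on the
$|Z|$ scale up to $h \approx 1$, so even a completely null-looking score
vector maps into the table. One beta-binomial fit per threshold fills a
whole column. Monte Carlo replicates interpolate $\log F_{(d)}$ linearly
on the $|Z|$-threshold scale $c = -\Phi^{-1}(h/2)$ — a strictly monotone
reparameterisation of $h$ chosen because the replicate pipeline already
produces $|Z|$ order statistics, which avoids roughly $10^9$ normal-cdf
calls in the largest calibration runs; interpolated values agree with
direct evaluation to better than $10^{-4}$ (typically a few $10^{-5}$).
Replicates whose smallest p-value falls below the tabulated range are
recomputed exactly rather than extrapolated. *Reported* l-values for
observed SNPs always bypass the grid and are evaluated exactly at the
observed order statistics.

Significance uses the standard Monte Carlo estimator: with $R$ null
replicates $\tilde Z^{(r)} \sim N_D(0, \hat\Omega)$ pushed through the
same statistic, $p = (N(T)+1)/(R+1)$ where $N(T)$ counts replicate
statistics at or below $T$ (ties inclusive). The smallest attainable
p-value is $1/(R+1)$, so $R$ must be chosen for the significance level
sought. Internally all Monte-Carlo-calibrated statistics are stored so
that smaller is more extreme (log-minimum-l for the order-statistic
tests — the minimum can underflow the probability scale — and negated
statistics for the quadratic and likelihood-ratio aggregators), and all
methods calibrated in one run share the same replicate stream, which
pairs the comparisons and removes between-method Monte Carlo variance.
Replicates are generated in batches (default $10^4$ or $2\times 10^4$
rows) through one Cholesky factor; each replicate consumes a contiguous
block of the RNG stream, so results are independent of the batch size.
The per-replicate partial sort runs in compiled code.

## Estimating and regularising the trait correlation

$\hat\Omega = w\,\hat C + (1-w)\,I$, with $\hat C$ the sample trait
correlation matrix. The weight is always recorded in run metadata and
can be fixed by the user. The automatic rule reflects what the matrix is
*for* — far-tail calibration of the Monte Carlo null — rather than
minimum mean-squared error:

* if $\hat C$ is full rank and well conditioned (in particular whenever
  the estimation sample comfortably exceeds the trait count), no
  shrinkage is applied ($w = 1$): any $w < 1$ biases every pairwise
  correlation toward zero, thins the far tail of the Monte Carlo null,
  and makes extreme p-values anti-conservative — an effect invisible at
  $\alpha = 0.05$ but clear at $\alpha = 10^{-4}$;
* otherwise $w$ is set by a second-moment match,
  $w^2 = 1 - \sum \widehat{\mathrm{Var}}(r_{ij}) / \sum r_{ij}^2$ over
  off-diagonal entries, which makes the aggregate squared correlation of
  $w\hat C$ — the quantity that governs exceedance over-dispersion —
  approximately unbiased for the truth, while any $w < 1$ restores
  positive definiteness (eigenvalues at least $1-w$).

MSE-optimal shrinkage intensities (Ledoit–Wolf/Schäfer–Strimmer style)
were deliberately not used: they shrink substantially even when $N > D$
and measurably inflate the extreme-tail type-1 error of the calibrated
tests. The second-moment rule degrades when $N \ll D$ and pairwise
signal is sparse; in that regime a user-supplied $w$ close to 1 is
preferable, which is why the override is mandatory in the interface.

## The synthetic-data generator

The simulation studies are self-contained: no external data enters.

* **True trait correlation.** The default `modular` structure mixes
  20-trait equicorrelated co-expression modules (within-module
  correlation 0.6) with a weak dense 10-factor background (loading s.d.
  0.15), 60/40, renormalised to unit diagonal. This reproduces the
  regime the full-scale validation studies document: pairwise
  correlations mostly weak (analytic Bonferroni/Simes/Cauchy p-values
  remain essentially calibrated at $\alpha = 0.05$) while the
  exceedance count is clearly over-dispersed (variance ratio near 2 at
  typical thresholds), so adjusting the l-values for dependence matters.
  Equicorrelated, pure factor, pure block, and identity structures are
  available for stress tests.
* **Estimated correlation.** Each study draws $N = 10^3$ individuals
  from the true $\Omega$, estimates the sample correlation, and applies
  the shrinkage rule — calibration always uses the *estimate*, never the
  truth, as in a real analysis.
* **Alternatives.** A SNP associated with exactly $A$ of the $D$ traits
  shifts the mean of those $A$ scores by
  $c_A = \sqrt{N v / (1-v)}$, the noncentrality of a regression Z
  statistic for a standardised predictor explaining fraction $v$ of a
  unit-variance trait at sample size $N$. The associated positions are
  drawn once per study from the seed and held fixed across replicates.
  The six default $(A, v)$ settings keep the full-scale study's
  signal-fraction ratios ($A$ rescaled proportionally to $D$, minimum
  one trait) and its per-trait variance-explained values
  $(1.5\%, 1\%, 0.8\%, 0.5\%, 0.4\%, 0.2\%)$.

What the generator does *not* emulate: real expression data has
non-Gaussian tails, shared technical covariates, and correlation between
signal placement and the co-expression structure (a trans hub's targets
are often one module). Passing tests therefore demonstrate correctness
of the statistical machinery under its own model, not robustness to
violations of it.

## Study sizes and what desk-scale power can show

The bundled studies run at $D = 500$ with $10^4$ simulation plus $10^4$
Monte Carlo replicates for common levels, $2\times 10^6 + 2\times 10^6$
for the $10^{-4}$ tail, and $10^3$ replicates per power setting — sizes
chosen so the full suite completes on a single CPU in minutes while the
binomial acceptance bands remain tight enough to be informative. The
full-scale studies ($D = 10^4$, up to $2\times 10^7$ replicates) are
reachable through the same functions by changing the arguments.

One consequence of reducing $D$ while preserving the signal fraction
$A/D$ and the per-trait effect size is a genuine loss of detectability:
the aggregation advantage of order-statistic and quadratic tests scales
roughly with $A/\sqrt{D}$, which shrinks by $\sqrt{20}$ between
$D = 10^4$ and $D = 500$. At desk scale the sparse-regime ordering
(minimum-p beating the order-statistic test at one associated trait) and
the dense-regime ordering (the quadratic aggregator beating minimum-p)
are reproduced, but in the middle regime all methods' absolute power at
level $10^{-3}$ collapses to a few percent and the adjusted test's
full-scale dominance there cannot be resolved from $10^3$ replicates.
The power harness reports paired comparisons so this is measured, not
asserted.

## Numerical choices and degenerate inputs

* Two-sided p-values are floored at $10^{-300}$; Cauchy and CPMA
  transforms clip to $(10^{-300}, 1 - 10^{-16})$.
* p-value ties are handled by stable sorting and do not affect
  l-values; $\pi = 0$ or $1$ propagate through the Beta cdf to l-values
  of 0 or 1.
* The boundary-crossing recursion and the beta-binomial tails are
  evaluated with per-tail log-sum-exp shifts, so l-values of order
  $10^{-16}$ retain full relative precision.
* Missing Z entries shrink a SNP's trait set; SNPs sharing a trait set
  (chromosome and missingness pattern) share one grid and one Monte
  Carlo null, and sets differing between SNPs are never mixed in one
  calibration.
* The pairwise variance excess of $S(c)$ is evaluated by quadrature on a
  coarse grid of 81 thresholds and splined in log space (relative error
  below $10^{-5}$ over the working range, declining extrapolation beyond
  it, capped at the beta-binomial feasibility bound), so building a
  precompute table costs 81 quadratures rather than one per tabulated
  threshold.
* Grid columns are clamped monotone (and at most 0 in log scale) to
  absorb quadrature-level rounding.
* The QQ acceptance band calibrates a two-sided equal-local-level band
  with half the non-coverage per side (Bonferroni across sides), which
  reproduces the pointwise $(0.025, 0.975)$ band at $n = 1$ and attains
  at least the nominal simultaneous coverage; its cost grows cubically
  in the number of plotted points, so QQ plots thin to 200 ranks by
  default before band calibration.

## Known limitations

* The beta-binomial approximation degrades under strong global
  equicorrelation (see above); validity is protected by Monte Carlo
  calibration, but power may be lost relative to an exact null.
* The automatic shrinkage weight targets the dense-weak-dependence
  regime; with $N \ll D$ and concentrated strong correlations it can
  over- or under-shrink, and the far tail of the calibrated test is the
  first place miscalibration appears.
* Monte Carlo significance bounds the smallest p-value at $1/(R+1)$;
  genome-wide thresholds need $R \sim 2\times 10^7$, which is linear-time
  but not instant.
* Relatedness, population structure, and cross-mapping artefacts must be
  handled upstream in the per-trait association scans; the global test
  inherits whatever miscalibration those scans carry.
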