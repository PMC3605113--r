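---
title: "Analytic power and accuracy of two-sample polygenic scores"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analytic power and accuracy of two-sample polygenic scores}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pgspower)
```

## The model

A pair of traits $(y_1, y_2)$ is written as a linear combination of $m$
independent, standardised genetic markers plus residual error,

$$ y_t = \sum_{j=1}^m \beta_{tj} x_j + \varepsilon_t, $$

with the per-marker effects treated as random across markers: a proportion
$\pi_0$ of markers has no effect on either trait, and the remaining effects
are bivariate normal with variances $\sigma_1^2, \sigma_2^2$ and correlation
$\rho_{12}$.  `pgspower` parameterises the architecture by the *total*
explained variances $v_{g1} = m(1-\pi_0)\sigma_1^2$ and
$v_{g2} = m(1-\pi_0)\sigma_2^2$, so that the panel's explained variance is
invariant to $\pi_0$; this matches the behaviour of the full-inclusion
score, whose properties do not depend on the null proportion at all.

A training sample of $n_1$ subjects yields per-marker least-squares
estimates $\hat\beta_{1j} \sim N(\beta_{1j}, \sigma_\varepsilon^2/n_1)$; the
residual variance is conservatively fixed at the trait variance (effects are
small).  Markers whose two-sided training P-values fall in a window
$(q_0, q_1]$ enter the polygenic score
$\hat S = \sum_{j \in \text{sel}} w_j x_j$, which is tested against $y_2$ in
an independent replication sample of $n_2$ subjects.

Everything downstream depends on two moments, computed by
`score_moments()`:

* $\mathrm{Var}(\hat S)$ — mixes a null component (selection probability
  $q_1 - q_0$, truncated variance of pure noise) and a non-null component
  (selection probability and truncated second moment under the marginal
  effect-plus-noise law).  The truncated-normal kernel
  $E[Z^2 \mid a \le |Z| \le b]$ is exposed as
  `truncated_second_moment()`.
* $\mathrm{Cov}(\hat S, y_2)$ — the regression of $\beta_{2j}$ on
  $\hat\beta_{1j}$ is unaffected by selection *on the estimate*, so the
  covariance is the (selection probability) × (regression coefficient) ×
  (conditional second moment of the selected estimates).

From these, `accuracy_report()` derives

* $R^2 = \mathrm{Cov}^2 / (\mathrm{Var}(\hat S)\,\mathrm{Var}(y_2))$,
* the prediction mean square error
  $\mathrm{Var}(y_2) - 2\,\mathrm{Cov} + \mathrm{Var}(\hat S)$,
* the 1-df non-centrality parameter $\lambda = n_2 R^2 / (1 - R^2)$ of the
  association test and its two-tailed power, and
* for binary traits, the AUC and the liability-scale $R^2$.

### The non-centrality parameter

We use the Wald form $\lambda = n_2 R^2/(1-R^2)$: the squared expected
*t*-statistic of the score regression, whose residual variance shrinks as
the score explains more of the trait.  At the $R^2$ values typical of
polygenic scores the two candidate forms $n_2 R^2$ and $n_2 R^2/(1-R^2)$
differ by a fraction of a percent, but the ratio form is the one that
reproduces the published inversion estimates, their confidence intervals,
and the published sufficient sample sizes simultaneously, and it is exact
for the asymptotic chi-squared of the regression test.  The estimating
equation below inherits this choice.

### Estimators

Three weighting schemes share the same selection machinery:

* **linear** — $w_j = \hat\beta_{1j}$;
* **shrinkage** — all estimates multiplied by the common posterior factor
  $\sigma_1^2 / (\sigma_1^2 + 1/n_1)$ under a single normal prior.  Because
  the factor is shared, $R^2$, NCP, power and AUC are identical to the
  linear estimator; only the MSE improves.  The prior variance is taken as
  the non-null per-marker variance without the point mass at zero — with a
  spike-and-slab prior the factor would no longer be common across markers
  and the equivalence would break, so the single-normal prior is the
  consistent choice here;
* **allele count** — the unweighted score: every selected marker
  contributes a fixed magnitude with the sign of its estimate.  The
  magnitude is chosen so a marker contributes the panel's mean per-marker
  explained variance ($c = \sqrt{v_{g1}/m}$, mapped to the analysis scale).
  All correlation-based metrics are invariant to this constant; the MSE is
  not, and is therefore not reported for this estimator.  Its covariance
  with the trait is a one-dimensional integral over the effect
  distribution, evaluated by adaptive quadrature (relative tolerance
  `1e-8`, integrand standardised so its mass lies within eight standard
  deviations).

## Binary traits

Binary traits arise from a liability threshold model: a standard-normal
liability exceeds $T = \Phi^{-1}(1-K)$ with prevalence $K$.  Small effects
on liability map linearly to the observed 0/1 scale by the factor $z$ (the
normal density at $T$) in a prospective sample, and by
$z\,P(1-P)/\{K(1-K)\}$ under case/control ascertainment with case fraction
$P$ — the two coincide at $P = K$.  The ascertained transform assumes the
genotype variance remains approximately 1 in the ascertained sample, which
degrades for very rare diseases; the simulator's case/control runs at
$K = 0.001$ quantify the residual bias rather than eliminate it.

The 0/1 analysis uses linear regression of the coded trait (variance
$P(1-P)$), which agrees with logistic regression for small effects; the
simulator verifies this agreement directly.

The AUC follows from truncated-normal case/control moments of the score on
the liability scale, driven by the proportion of liability variance the
estimated score explains.  The liability-scale $R^2$ rescales effects by the
inverse observed-scale transform and replaces the binomial trait variance by
the unit liability variance; it is invariant to the replication sample's
case fraction by construction.

`h2_from_sibling_rr()` converts a prevalence and sibling relative
recurrence risk to the implied heritability of liability by solving the
bivariate-normal tail probability with sibling correlation $h^2/2$ exactly;
Reich's classical approximation agrees to four decimals in the ranges used
here.  The conversion ignores shared environment, so it is an upper bound
on the additive $h^2$.  A log-risk alternative for rare diseases
(`logrisk_auc()`) takes the score to estimate normally distributed log
risk, giving $\mathrm{AUC} = \Phi(\sqrt{v/2})$.

## Estimating the architecture from an observed association

The signed root of the observed 1-df chi-squared statistic is approximately
normal with mean $\sqrt{\lambda(\theta)}$ and unit variance.
`estimate_parameter()` solves $\sqrt{\lambda(\hat\theta)} = \sqrt{S}$ for
the free parameter (explained variance, effect correlation, or null
proportion) by bracketed root-finding on the numerically verified monotone
NCP, with 95% bounds solving
$\sqrt{\lambda(\theta)} = \sqrt{S} \mp 1.96$; bounds that leave the
parameter's domain are clamped and flagged.  A worked example:

```{r isc}
isc <- study_design(n1 = 6909, n2 = 5343,
                    trait1 = binary_trait(K = 0.01, P = 3322 / 6909),
                    trait2 = binary_trait(K = 0.01, P = 2687 / 5343),
                    q1 = 0.5)
estimate_parameter(polygenic_model(74062, 0.5), isc, "vg", p = 2e-28)
```

With only ~1,000 markers carrying effects the realised architecture varies
between replicates, over-dispersing the estimating equation; the intervals
are then anti-conservative.  The simulation suite reproduces this known
behaviour rather than correcting it, and shows nominal coverage returning
with 5,000 effect markers.

## Design solvers

`required_n()` brackets and bisects the monotone objective (power scales
both samples; AUC and correlation depend only on the training sample), with
an explicit feasibility gate against the infinite-sample maximum.
`optimal_threshold()` maximises over the upper threshold with a 40-point
log-spaced grid on $[10^{-8}, 1]$ refined by golden-section search — the
full window is always kept as a candidate, so for $\pi_0 = 0$ with the
linear estimator the optimum is $q_1 = 1$.  `optimal_split()` maximises the
NCP over the training fraction; for realistic architectures the optimum
lies near one half and the curve is roughly symmetric, so it matters little
which of two samples is used for training.  `reproduce_table()` regenerates
the published sample-size grids (with cells in 1,000s, rounded up, and the
maximising threshold per cell; the lower threshold is fixed at 0, whose
choice has little bearing on the results).

One regeneration caveat is documented rather than hidden: in the published
grids' most extreme column ($\pi_0 = 0.999$ with $10^6$ markers, i.e. 1,000
effect markers) the printed maximising threshold ($7\times10^{-5}$) is not
the within-model optimum ($\approx 2.6\times10^{-5}$; confirmed by
Monte-Carlo checks of the truncation moments in exactly this regime).  At
the *printed* threshold our solver reproduces the printed sample sizes
exactly (e.g. 31,000 subjects for 90% of the maximum correlation at
$h^2 = 0.8$), while true threshold optimisation attains the same target at
29,000.  Every other column reproduces cell-for-cell under true
optimisation.  The package optimises properly and therefore reports the
smaller size.

## The simulator

`evaluate_replicates()` is the package's validation oracle, not a fixture:
it simulates marker-level data from the generative model and recomputes
every analytic quantity empirically.

* Genotypes are Hardy–Weinberg dosages at allele frequencies
  $\mathrm{Unif}(0.01, 0.5)$, standardised by the *true* frequency (the
  model's definition).  Bulk fills use a xoshiro256++ stream seeded from
  R's RNG, so runs are bit-reproducible under `set.seed()`.
* Effects: exactly $\mathrm{round}(m\pi_0)$ markers are null; the rest are
  bivariate normal, or variance-matched Laplace pairs coupled by a Gaussian
  copula whose correlation is calibrated by Gauss–Hermite quadrature so the
  product-moment correlation hits the target exactly.
* Rare-disease case/control samples are generated without rejection: the
  aggregate genetic liability is drawn from its truncated-normal law given
  case status, and genotypes from their joint-normal approximation given
  the aggregate.  The scheme is validated against brute-force rejection
  sampling at $K = 0.2$, where both are feasible.

The default validation scale is 20,000 markers, samples of 2,000, and
70–200 replicates per scenario — chosen so the full suite (quantitative,
prospective binary, and case/control scenarios, plus parameter recovery at
1,000 and 5,000 effect markers) completes in a coffee break on one core
while keeping Monte-Carlo standard errors small enough for three-standard-
error agreement checks to be meaningful.  The published simulation study
uses 100,000 markers, samples of 4,000, and 1,000 replicates; any scenario
can be run at that scale by passing the corresponding `sim_config()`.

What the simulator does *not* emulate: linkage disequilibrium between
markers (m is an effective number of independent markers), relatedness
between subjects, genotyping error or imputation noise, and effect-size
dependence on allele frequency.  Passing tests therefore validate the
analytic theory under its own assumptions, not the behaviour of the method
on real GWAS data, where LD pruning quality and population structure
dominate the error budget.

## Numerical choices

* Truncated-normal kernels are closed-form; the deep-tail limit
  $a^2 + 2$ guards against vanishing denominators beyond machine
  precision.
* Quadratures (allele-count covariance, bivariate-normal tail for the
  sibling-risk conversion) use adaptive rules with relative tolerance
  $10^{-8}$ or tighter; integrands are standardised to $O(1)$.
* Root-finding uses bracketed bisection (`uniroot`) on the signed-root
  scale with tolerance $10^{-10}$; sample-size searches bracket
  exponentially, bisect, then step down to the exact smallest integer
  before applying any rounding granularity.
* `n1 = Inf` is accepted everywhere and implemented as the analytic limit
  (sampling variance zero; non-null markers have P-value 0 and are selected
  exactly when $q_0 = 0$).
* The expected $-\log_{10}P$ curves evaluate the P-value at the statistic's
  *mean* $1 + \lambda$; the median variant is available
  (`expected_neglog10p(at = "median")`) and is systematically slightly
  lower.  The mean variant reproduces the qualitative published curve
  shapes (improvement to full inclusion for moderate null proportions; the
  unweighted score uniformly less significant with an interior optimum).

## Known limitations

* All results are asymptotic in both samples; no finite-sample or exact
  logistic-regression corrections.
* The large-$m$ equalities treat the realised effect variance as fixed at
  its expectation; with few effect markers this is the source of the
  documented interval under-coverage.
* The ascertained-genotype variance approximation and the linearised
  liability transform both assume small per-marker effects; the case/control
  simulations at $K = 0.001$ bound the resulting bias.
* Estimation inverts one parameter at a time; joint estimation of, say,
  explained variance and null proportion is out of scope.
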