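---
title: "Penalized distributed-lag models for parental depression exposure: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Penalized distributed-lag models for parental depression exposure: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(parentlag)
```

## The scientific question and the model

Repeated measurements of parental depressive symptoms across a child's
development pose a timing question: does exposure in a particular
developmental window carry disproportionate risk for the offspring's
adult mental health? The distributed-lag model answers it by giving
every measurement occasion its own coefficient while constraining those
coefficients to vary smoothly over developmental age.

With exposures $x_{it}$ (EPDS totals, 0–30) at occasions $t = 1,\dots,T$
and confounders $z_i$,
$$\eta_i = \sum_t w_t\, x_{it} + \gamma^\top z_i, \qquad w = B\theta,$$
where $B$ is a cubic B-spline basis evaluated at the occasion ages and
$\theta$ carries an order-2 difference penalty $\lambda\,\theta^\top
D_2^\top D_2 \theta$. Ordinal outcomes use the proportional-odds
(cumulative-logit) likelihood $\operatorname{logit} P(Y_i \ge k) =
\eta_i - \alpha_k$ with one shared $(\theta,\gamma)$ across thresholds;
the binary psychotic-experience outcome uses logistic regression. The
two estimands are the time-response curve $AOR_t = e^{c\,w_t}$ and the
cumulative $AOR = e^{c \sum_t w_t}$ at the contrast $c = 13$, the
conventional EPDS threshold for clinically concerning symptoms; on the
log scale the cumulative effect is identically the sum of the
per-occasion effects.

### Time axis and schedules

Occasions are placed on a developmental-age axis in years with birth at
zero: 18 weeks' gestation at $-0.42$, 32 weeks at $-0.15$ (term birth at
40 weeks), 8 weeks at $0.154$, and 8/21/33 months at $0.667/1.75/2.75$.
The maternal schedule has 12 occasions, the paternal 10 (one pregnancy
measurement, none at 18 years). The psychotic-experience outcome is
interviewer-assessed for experiences since age 12, so its exposure
schedule is truncated at age 11 — `truncate_schedule(sched, 11)` —
leaving 10 maternal occasions.

### Basis, penalty, and what "15 df" means here

The default basis dimension is $K = 15$. With only 12 maternal occasions
an *unpenalized* 15-dimensional fit is not identifiable, so the basis
dimension is read as capacity, with the penalty controlling the
*effective* df, $\operatorname{edf} = \operatorname{tr}\big[(\mathcal I
+ \lambda \tilde P)^{-1}\mathcal I\big]$ over the lag block. The edf
runs from $K$ (or the design rank when $K > T$) at $\lambda = 0$ down to
the penalty null-space dimension (2: linear-in-age curves are free) as
$\lambda \to \infty$; both limits and monotonicity are tested. Knots are
equally spaced in age — the curve is smooth in developmental time, not
in occasion index — extended `degree` intervals beyond the data span so
the basis is a partition of unity over it. Alternative interpretations
of a fixed-df analysis are available through `lambda_rule =
"target_edf"`; `"REML"` (Laplace-approximate restricted likelihood,
golden-section search over $\log\lambda$) is the data-driven default.

### Fitting

A single Newton engine maximizes the penalized cumulative-logit
log-likelihood (the binary model is its two-category case, and the
binary reduction is exact by construction — tested to $10^{-8}$).
Cutpoints are optimized through a log-increment parameterization
($\alpha_1,\ \alpha_k = \alpha_{k-1} + e^{\tau_k}$), which enforces
monotonicity even with sparse extreme categories; ordinal categories
observed zero times are collapsed first, which leaves odds-ratio
contrasts invariant under proportional odds. Step-halving guarantees a
monotone objective; convergence requires the score sup-norm below
`tol` ($10^{-6}$) or a Newton decrement below $10^{-11}(1+|\ell_p|)$,
the latter needed when a stiff penalty makes the absolute score
criterion unattainable in floating point. The reported covariance is
the inverse *penalized* observed information — the Bayesian covariance
that is standard for penalized-spline intervals — and intervals for
AORs are pointwise normal on the log scale, matching the
"NS"-annotation style of sensitive-period figures; simultaneous bands
are out of scope. At $\lambda = 0$ the fits agree with `glm` and
`MASS::polr` to $10^{-6}$.

### Nonlinear exposure (cross-basis) and moderation

The DLNM extension replaces the linear exposure term with basis
functions $f_k$ over the score range, anchored at the reference
($f_k(0) = 0$), in a tensor product with the lag basis. Because a
B-spline basis sums to one everywhere, its anchored version sums to
zero — an exact collinearity — so one basis function is dropped. Each
dimension carries its own difference penalty, with the two smoothing
parameters chosen jointly on a REML grid. With the linear exposure
basis the cross-basis design *equals* the DLM design and the contrast
surface at level 13 reproduces the DLM time-response exactly.

Moderation (offspring sex, polygenic scores) is tested by a Wald
statistic on a moderator-by-lag-curve deviation block, because Wald
chi-squares are what D2 pooling consumes across imputations. In the
pipeline the deviation block gets its own basis of at most 6 columns:
an unpenalized deviation block of the full basis dimension would be
rank-deficient whenever $K$ exceeds the number of occasions, and
moderation of a smooth curve is inherently a low-df question. The
deviation block is left unpenalized so the Wald statistic keeps its
nominal chi-square reference; its D2-pooled type-I error is verified by
simulation (200 null replicates, M = 5: rejection rate within the
binomial band of 0.05).

## Missing data

Pairs missing 95% or more of the required analysis columns are excluded
(the boundary is inclusive, "95% or more"). Two imputation engines are
provided. Item-level: regularized iterative low-rank imputation of the
centred one-hot indicator matrix of questionnaire items — the
computational core of MCA-based imputation, not a feature-complete
clone of any package — with multiple-imputation variants drawn by
adding resampled observed-cell residuals before category assignment.
Score-level: chained equations with randomized-tree ensembles (ranger),
drawing imputations by predictive mean matching on out-of-bag
predictions (k = 5 donors) for numeric variables and class-probability
sampling for factors; all covariates and outcomes enter as auxiliary
predictors, forests are single-threaded and seeded, so imputation is
bit-reproducible. PMM deliberately adds donor noise — proper MI
variability — so its point-RMSE advantage over mean imputation
materialises when neighbours are informative (the AR structure of
repeated EPDS makes them so).

Estimates pool on the log-odds scale by Rubin's rules with
Barnard–Rubin degrees of freedom ($\bar Q$, $W$, $B$, $T = W +
(1+1/M)B$), exponentiating afterwards, so pooled CI endpoints are
order-preserved. Wald chi-squares pool by D2: $r = (1+1/M)\,
\operatorname{var}(\sqrt{w_m})$, $D_2 = \frac{\bar w/k - \frac{M+1}{M-1}r}
{1+r}$ floored at zero, referred to $F(k,\nu)$ with $\nu =
k^{-3/M}(M-1)(1+1/r)^2$; $M = 1$ reduces to $\chi^2/k$ against
$F(k,\infty)$. Tests default to M = 20 (M = 100 is configurable but adds
nothing at desk scale). Whether to pool AORs or coefficients is not
uniquely determined by convention descriptions; pooling on the
coefficient scale is the statistically standard choice and is what is
implemented.

## The synthetic cohort generator

The generator is first-class, tested code, and its defaults *are* the
study conditions the estimator is validated under:

* **Exposures**: a latent Gaussian AR(1) across occasions (lag-1
  correlation 0.6, SD 4.8, mean near 6.5 in pregnancy declining toward
  5), rounded and clipped to 0–30. The latent-then-discretize route is
  used because EPDS totals are integers with strong serial correlation
  but no published generative model; occasion-level means and SDs are
  plausibility choices, as the real ones live in restricted supplements.
* **Covariates**: parental ages, 5-level education, social class,
  parity, crowding, marital status, offspring sex, six standardized
  polygenic scores, prenatal smoking/alcohol (independent of exposure,
  for the secondary covariate set), birth weight and gestational age.
  Entry criteria (gestational age > 32 weeks, birth weight > 1500 g,
  strict inequalities) are applied as a filter with counts reported.
* **Outcomes**: cumulative-logit draws with cutpoints matched to
  plausible right-skewed score distributions (31-category EPDS-like,
  SCAARED-like, AUDIT-like) and a binary psychotic-experience outcome
  (baseline prevalence 12%) generated only from occasions at age ≤ 11.
* **Lag-weight scenarios**, scaled so the 13-vs-0 cumulative AOR matches
  the headline magnitudes of this literature: `flat` and `late_ramp` at
  2.36, `prenatal_spike` at 1.90 — a Gaussian bump in age centred at
  $-0.3$ y with SD 0.8 y, because the estimand is a P-spline-smooth
  curve and a one-occasion needle would not be in the model space any
  smoother would target.
* **Missingness**: MCAR at a flat rate, or MAR where cell missingness is
  a logistic function of fully observed covariates only (lower maternal
  education and younger age increase it), with the intercept calibrated
  to the requested marginal rate. Outcomes are never deleted.

What the generator does *not* emulate: real attrition patterns
(missingness correlated over waves and with the outcome), demographic
margins of any actual cohort, measurement error in the EPDS itself, and
exposure–confounder dependence. Passing tests therefore demonstrate
that the machinery is correct under its own assumptions, not that any
particular substantive finding in restricted data is right.

## Numerical choices and simulation sizes

Validation simulations are sized to desk scale: lag-weight recovery uses
200 replicates at $n = 3000$ with the $K = 15$ basis and a target edf of
8 (bias criterion: mean absolute error of $\hat w$ below 10% of
$\max|w|$); interval calibration uses 500 replicates at $n = 1000$
(coverage within 93–97%); the D2 type-I study uses 200 replicates with
M = 5 imputations on a 6-occasion truncated schedule. Binary outcomes
are used in the replicated studies because they exercise the same lag
machinery at a fraction of the cost of 31-category ordinal fits; the
ordinal path is validated against exact oracles and reductions instead.
Degenerate inputs are handled explicitly: empty ordinal categories are
collapsed; separation is detected and flagged rather than silently
returned; a numerically singular penalized information (possible when
$K$ exceeds the occasion count at tiny $\lambda$) receives a relative
ridge of $10^{-10}$ only where a trace or covariance must still be
produced.

## Known limitations

Estimates are associational; no mediation, no simultaneous bands, no
MNAR sensitivity analysis, no partial proportional odds, and no attempt
to reproduce restricted-data results numerically. REML here is a
Laplace approximation under a penalized non-Gaussian likelihood;
its optimum is validated against a grid search of the same criterion,
not claimed to match any other software's smoothing constant.
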