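---
title: "Models and methods: coupled latent change scores in bivlcs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: coupled latent change scores in bivlcs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific question

Cognitive abilities correlate positively with each other — the *positive
manifold*. Two families of explanation compete. In the *common-factor*
(g) account a single underlying ability drives performance everywhere, and
development is change in that one dimension. In the *mutualism* account
abilities start out more independent but feed each other during development:
a child with a larger vocabulary extracts more from reasoning practice, and
vice versa, so positive correlations *emerge* from reciprocal coupling.
Between them sits *investment* theory, in which coupling runs one way only —
fluid reasoning capacity is "invested" into the acquisition of crystallized
knowledge such as vocabulary.

With two domains measured at three occasions these accounts become
distinguishable as structural models. `bivlcs` implements the three
candidates as bivariate latent change score (LCS) models, two robustness
alternatives (a parallel-process growth model and a random-intercept
cross-lagged panel model), the estimation machinery to fit and compare them
under missing data, and the Monte-Carlo machinery to ask whether this design
could have favoured each account had it been true, and with what power.

## The latent change score model

For domain $Y$ (vocabulary `voc` or matrix reasoning `mat`) at occasion
$t \in \{2, 3\}$, the change score is defined structurally by fixed unit
loadings:

$$Y_t = Y_{t-1} + \Delta Y_t,$$

so $\Delta Y_t$ is a latent variable, not an arithmetic difference of noisy
observations. The dynamics are

$$\Delta Y_t = \alpha_Y + \beta_Y\, Y_{t-1} + \gamma_{X \to Y}\, X_{t-1} + \zeta_{Y,t},$$

where $\beta_Y$ is *self-feedback* (negative values mean approach to an
asymptote), $\gamma_{X \to Y}$ is the *coupling* from the other domain's
prior level, $\alpha_Y$ a change intercept, and $\zeta$ a change residual.

* **Mutualism**: both couplings free (`build_mutualism_lcs()`; 19 free
  parameters, df = 8 against the 27 observed moments of six variables).
* **Investment**: one coupling fixed to zero
  (`build_investment_lcs()`; default keeps reasoning $\to$ vocabulary-change
  free, the classical fluid-into-crystallized direction, exposed as an
  argument because applications disagree).
* **Common factor**: one latent $g_t$ per occasion loading on both scores
  with loadings, intercepts and indicator residuals equated across waves
  (measurement invariance), and a univariate LCS
  $\Delta g_t = \alpha_g + \beta_g g_{t-1} + \zeta_t$ on the factor
  (`build_gfactor_lcs()`; 10 free parameters).

Equality constraints are imposed on the same parameter across waves by
default — the natural small-sample discipline for a three-wave design. One
exception is built in: the vocabulary change intercept is freed per occasion
(`free_vocab_intercept = TRUE`), because conditional vocabulary gains shrink
visibly between successive occasion pairs at these ages; a flag restores
full equality (costing exactly 1 df). Change residuals covary freely across
waves; the contemporaneous change covariance is treated as "the same
parameter at successive waves" and equated.

### Single-indicator reliability adjustment

Each domain is a single indicator per occasion, so measurement residuals are
not identifiable. When the design supplies internal consistencies, each
observed score becomes the sole indicator of a latent true score with its
residual variance *fixed* at $S^2(1 - R_{xx})$
(`reliability_residual_variance()`), where $S^2$ is that variable's sample
variance. All fixed quantities, so the model df are unchanged. Without
reliabilities the scores are treated as error-free — with this design the
two options give very similar comparisons, but the adjustment is the more
honest measurement stance.

### Alternative specifications

The **parallel-process model** (`build_parallel_process()`) gives each
domain an intercept and a linear slope (loadings fixed to 0, 1, 2) and
regresses each slope on the *other* domain's intercept — baseline ability in
one domain driving the rate of gain in the other. The within-domain
intercept-to-slope paths (a "Matthew effect": the rich get richer within a
domain) are fixed to zero by default and freed with
`cross_domain_only = FALSE` (exactly +2 parameters), giving the 2-df
contrast between cross-domain and within-domain driving. A note on
directionality: verbal descriptions of this model sometimes phrase the
regression as "intercepts on slopes". A regression *of* an exogenous
baseline *on* a later rate of change has no sensible causal reading in this
design, so the builder implements slope-on-intercept regression; this is a
deliberate, documented resolution of an ambiguity in how the model is often
described.

The **RI-CLPM** (`build_riclpm()`) separates stable between-person
differences (one random intercept per domain, unit loadings at all waves)
from within-person dynamics: lag-1 autoregressions and cross-lagged paths
among the within-person components, equated across the two lags, with
wave-specific within-person residual covariances and free occasion means
(20 free parameters). Positive cross-lagged paths in both directions are the
model's rendering of mutualism.

## Estimation

All fitting is plain full-information maximum likelihood under the
multivariate normal: each person contributes the log-density of their
observed sub-vector under the matching sub-moments of the model-implied
mean and covariance, so missing-at-random data need no imputation and
persons with no observed scores are excluded with a warning (they carry no
information). Implied moments follow the reticular algebra
$\Sigma = F (I - A)^{-1} S (I - A)^{-\top} F^\top$,
$\mu = F (I - A)^{-1} m$. Internally persons are grouped by missingness
pattern and summarized by per-pattern means and scatter matrices, making a
likelihood evaluation independent of sample size.

Numerical choices, in one place:

* **Optimizer**: `nlminb` (quasi-Newton with numerical gradients) over the
  distinct free labels; equality constraints are enforced by construction
  (shared labels map to one entry of the parameter vector).
* **Starting values**: free *mean* parameters are initialized by an exact
  least-squares match of implied to observed means (the mean structure is
  linear in mean parameters at fixed paths); variances start at
  design-informed magnitudes, paths at 0, loadings at their fixed or
  unit-scale values. On non-convergence the fit restarts from jittered
  starts (default 5, fixed jitter seed, the global RNG stream is restored),
  and non-convergence is flagged on the result, never silent.
* **Positive definiteness** is enforced by Cholesky factorization; a failed
  factorization returns a large penalty to the optimizer rather than an
  error mid-search.
* **Standard errors** come from the inverse observed information (numerical
  Hessian at the optimum); a non-invertible Hessian yields `NA` standard
  errors, not fabricated ones. Negative variance estimates (Heywood cases)
  raise a recorded warning.
* **Saturated model**: closed form for complete data; an EM algorithm for
  the unrestricted MVN under missingness. **Independence baseline** (free
  means and variances, zero covariances — the dominant CFI convention) has a
  closed-form per-variable solution even under missingness.
* **Degenerate inputs**: more free parameters than observed moments, or
  fewer persons than free parameters, are refused with an identification
  error rather than "fitted".
* **Estimation is plain ML throughout.** A robust (Yuan–Bentler style)
  scaled chi-square is *not* provided: every dataset this package generates
  is exactly multivariate normal, where the scaled and plain statistics
  estimate the same quantity, and a scaling implementation that could never
  be exercised against non-normal data here would be untestable ballast.
  Consequence for observed-data replication: published chi-squares computed
  under robust scaling will differ slightly from this package's plain-ML
  values, so those comparisons should be read with a small tolerance.

### Fit indices

$\chi^2 = 2(\ell_{sat} - \ell_{model})$ with
$df = p(p+3)/2 - k$;
$\mathrm{RMSEA} = \sqrt{\max(\chi^2 - df,\, 0) / (df\,(n-1))}$ — the $n-1$
divisor reproduces published three-decimal values exactly — with a 90% CI
from inverting the noncentral $\chi^2$ at 5%/95%; CFI against the
independence baseline; SRMR as the root mean square of covariance residuals
standardized by sample standard deviations (covariance-only, the common
default; a mean-structure variant is available internally);
$\mathrm{AIC} = -2\ell + 2k$, $\mathrm{BIC} = -2\ell + k \ln n$. Exact AIC
or BIC ties in comparisons are *reported as ties*, never broken silently.

### Multigroup invariance

`run_multigroup_invariance()` compares the all-parameters-equal multigroup
model (whose likelihood coincides with the single-group fit) against a model
freeing a configurable label set per group. The default freed set for the
mutualism specification is its dynamic skeleton: both self-feedbacks, both
couplings, the three change intercepts, both change residual variances, the
contemporaneous and the two within-domain cross-wave change covariances, and
the wave-1 cross-domain covariance — 13 labels, so a two-group test has
$\Delta df = 13$. The published 13-df gender test does not list its freed
parameters; this set is this package's documented choice, and a mismatch on
real data would surface as a different $\Delta df$, reported rather than
hidden.

## The synthetic-data generator

`simulate_dataset()` draws person-vectors from the multivariate normal with
the generating specification's *implied* moments — the same code path used
in estimation, so generator and likelihood can never disagree about the
model — then applies a missing-completely-at-random mask. Identical seeds
give identical datasets; simulation loops give replicate $r$ the seed
`base_seed + r`.

Two presets encode the study worlds. Their raw parameter values are this
package's fixed, documented defaults, chosen once so that simulated data
resemble raw Wechsler-type vocabulary and matrix-reasoning scores in middle
childhood, and they are deliberately *not* adjustable by results:

* `gfactor_generating_preset()`: wave-1 means 23 (vocabulary) and 12
  (reasoning), variances 36 and 25, a general factor carrying a within-wave
  cross-domain correlation of about 0.4 (so over half of each indicator's
  variance is unique — a common factor matching realistically moderate
  cross-domain correlations must leave large unique variances), factor
  increments of 4 per occasion and self-feedback 0.2 by default; the 0 and
  −0.2 self-feedback robustness variants are arguments, with the mean
  increment exposed so growth stays globally positive.
* `mutualism_generating_preset()`: the same observed scale; standardized
  self-feedbacks near −0.2 (vocabulary) and −0.3 (reasoning), wave-1
  cross-domain correlation 0.4, contemporaneous change-residual correlation
  0.3, vocabulary gains larger between the first occasion pair than the
  second. The requested *standardized* couplings (first-lag convention; the
  raw coupling is equated across waves, so later-lag standardized values
  drift upward slightly) are converted to raw couplings by a damped
  fixed-point solve against the implied moments.

What the generator emulates: multivariate-normal scores on the study's
scale, its three-wave bivariate layout, and MCAR missingness. What it does
not: non-normal score distributions, floor/ceiling effects, item-level
structure, and attrition that depends on ability (MAR/MNAR). Passing
simulation checks therefore validates the *machinery* and the design's
discriminating power under clean conditions; it does not certify robustness
to those real-data complications.

## The simulation studies

`run_model_recovery()` asks the sanity question behind any model comparison:
if the common-factor world were true, would AIC (used because the g and
mutualism models are not nested) recover it at this design and sample size?
Non-converged replicates are excluded from the preference denominator with
the exclusion count reported; exact AIC ties are counted separately.
`run_power_curve()` sweeps standardized coupling values, fits the mutualism
model to each draw, and tests the vocabulary-to-reasoning coupling — by
default a two-sided Wald $z$ on the raw estimate ("nominally significant at
$\alpha$"), with a 1-df likelihood-ratio alternative behind a flag — and
reports rejection proportions with exact binomial confidence intervals,
flagging any grid point with more than 20% non-convergence.

Default problem sizes are desk-scale choices: 200 recovery replicates and
100 power replicates per grid point at $N = 227$, with arguments to raise
both. A caution for interpretation: Monte-Carlo power at a small
standardized coupling is sensitive to generating details that published
aggregate results do not pin down — chiefly the share of change variance
explained by prior levels and the cross-domain level correlation. Under
this package's defaults (calibrated to the *reported standardized dynamics*,
which explain a modest share of change variance), power at a standardized
coupling of .1 is materially lower than the figure published for the
original generating code, which is not publicly restated parameter by
parameter; the power at .2 and above saturates toward 100% either way.
`scripts/acceptance.R` recomputes both headline quantities from scratch at
every run rather than quoting any number here.

## Known limitations

* Three waves and two domains only; the builders refuse other layouts
  (documented extension point) though the engine itself is general.
* Plain ML only — no robust scaling, no categorical indicators, no
  multilevel structure, no Bayesian estimation.
* MCAR simulation only; FIML itself remains valid under MAR, but the
  generator cannot produce MAR benchmarks.
* The cross-sample $z$ comparisons use standardized-scale standard errors
  approximated by rescaling raw standard errors (the variability of the
  standardizing standard deviations is ignored), and the bundled reference
  estimates ship without published standard errors — rows without supplied
  SEs are reported as not testable.
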