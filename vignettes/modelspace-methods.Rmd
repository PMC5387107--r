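---
title: "Personalized treatment-response prediction in the model space: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Personalized treatment-response prediction in the model space: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(modelspace)
```

## The problem and the modeling idea

In a dose-optimization titration clinic, a child diagnosed with ADHD
attends a series of appointments (anywhere from 1 to 22) at which
medication doses are ramped stepwise until symptoms remit or adverse
effects intervene. Two continuous symptom scores — inattentiveness and
hyperactivity, standardized factor scores extracted from parent-rated
SNAP-IV questionnaires — are recorded at each visit. The prediction task
is longitudinal and personal: given a child's baseline characteristics and
the dose plan, forecast their symptom scores, with honest uncertainty, and
classify whether they will reach remission (score at or below −0.97 for
inattentiveness, −0.92 for hyperactivity — cut-offs equivalent to a mean
SNAP-IV item score of one or less).

Pooled regression struggles here because patients genuinely differ in how
they respond, while per-patient regression struggles because a patient has
at most a couple of dozen visits against P = 19 free parameters. The
package's approach — *learning in the model space* — resolves the tension
by giving every patient their own Bayesian linear model and moving all
cross-patient learning into the space of fitted models.

## The subject-specific regression model

For subject $s$, appointment $a$:

$$ y_{s,a} = [\,\mathbf{b}_s \mid \mathbf{m}_{s,a} \mid 1\,]\;\boldsymbol\omega_s + \varepsilon, \qquad \varepsilon \sim N(0, \sigma_s^2), $$

with $\mathbf{b}_s \in \mathbb{R}^{1\times L}$ the baseline latent factors
($L = 14$ by default, identical in every row of the subject's design),
$\mathbf{m}_{s,a}$ the four medication doses (IR-MPH, XR-MPH, DEX, ATOM on
a common equivalent-daily-dose scale), and an intercept; $P = L + 4 + 1$.
One independent model is fitted per symptom dimension.

The belief about $(\boldsymbol\omega_s, \sigma_s^2)$ is conjugate
Normal–Inverse-Gamma, parameterized as $(\tau, \Lambda^{-1}, \alpha,
\beta)$: $\boldsymbol\omega \mid \sigma^2 \sim N(\tau, \sigma^2
\Lambda^{-1})$ and $\sigma^2 \sim \mathrm{IG}(\alpha, \beta)$. Observing a
block $(X, y)$ of $n$ appointments updates it in closed form:

$$ \Lambda_n = \Lambda_0 + X^\top X, \quad
   \tau_n = \Lambda_n^{-1}(\Lambda_0\tau_0 + X^\top y), \quad
   \alpha_n = \alpha_0 + n/2, $$
$$ \beta_n = \beta_0 + \tfrac12\big(y^\top y + \tau_0^\top\Lambda_0\tau_0
   - \tau_n^\top\Lambda_n\tau_n\big). $$

These are the standard conjugate equations; the test suite verifies them
against dense numerical integration of the raw prior × likelihood on
one- and two-parameter problems (Gauss–Legendre product quadrature with a
log-variance substitution, agreeing to better than $10^{-4}$ relative
error), and verifies that sequential one-row updates reproduce the batch
update to $10^{-9}$ in any order.

The posterior predictive at a design row $x_*$ is location-scale
Student-t:

$$ y_* \sim t_\nu\!\Big(x_*\tau,\; \tfrac{\beta}{\alpha}\big(1 + x_* \Lambda^{-1} x_*^\top\big)\Big), \qquad \nu = 2\alpha, $$

which is what all prediction strategies and the uncertainty-aware
classifier consume. The covariance-scale reading of the quadratic form
(rather than its precision counterpart) is the unique choice consistent
with the $1 + x\Lambda^{-1}x^\top$ structure of the conjugate predictive.

## Prior elicitation from an evidence table

Quantitative effect sizes from heterogeneous studies cannot be put on a
common scale, so the prior encodes only *directions* and *evidence
quality*:

* $\tau_0[i] = \pm 1$, the sign of the association with the symptom score
  (all four medications get $-1$: a positive dose lowers symptoms);
  columns without evidence stay at 0;
* each diagonal variance starts at 1; every qualifying contradicting study
  adds 0.5; otherwise every supporting study subtracts 0.1, floored at
  0.5. When a column has both kinds, contradiction wins — inflating is the
  conservative response to conflicting literature;
* off-diagonal entries are zero except where a causal link is declared
  (the sparsity pattern of the causal factor model); the declared links
  default to magnitude 0 with a configuration hook, since only the
  sparsity pattern is determined by the elicitation procedure.

$\alpha_0 = \beta_0 = 1$ by default (a weakly informative unit-scale
noise prior); both are arguments of `build_prior()`. The shipped
`inst/extdata/evidence.csv` is an *illustrative, synthetic* table that
exercises every rule; it is not a literature synthesis.

## Virtual patient profiles

A new patient arrives with baselines $\mathbf{b}_*$ but no outcomes. Both
profile constructors operate on a pool of fitted patient models
$\{(\mathbf{b}_s, \hat\tau_s, \hat\Lambda_s^{-1}, \hat\alpha_s,
\hat\beta_s)\}$:

**Method 1 (linear map).** Least-squares maps $\hat
Q = (B^\top B)^{-1} B^\top Y$ from baselines to the pooled $\hat\tau_s$
and to the half-vectorized covariance scales $u_s$ (upper triangle,
row-major — fixed for serialization stability). The reconstructed
covariance can be slightly indefinite, so it is symmetrized and its
eigenvalues clipped at $10^{-8}$. $\hat\alpha_*, \hat\beta_*$ are pool
means. Rank-deficient $B^\top B$ falls back to singular-value truncation
with a warning. Optional polynomial features (elementwise powers of the
baselines) exist behind `degree` but default off — higher degrees fit the
pool better and generalize worse.

**Method 2 (kernel averaging).** Euclidean baseline distance $d_s =
\lVert \mathbf{b}_* - \mathbf{b}_s \rVert_2$; the fraction
`retain_fraction` (default 0.175) of nearest subjects is kept — count
$\lceil f\,n\rceil$ with a floor of one, boundary ties all kept for
stability — and weighted by the normalized kernel $w_s \propto
\exp(-\lambda d_s)$, $\lambda = 1.15$. All four components are the
weighted averages, so the profile is a convex combination of valid belief
states and needs no repair. The kernel is applied to the *distance*, not
its square: the dissimilarity is described as Euclidean, and the
triangle-inequality property tests rely on it. The averaging is over the
covariance scales $\Lambda_s^{-1}$ directly (not their inverses); the two
choices differ, and averaging the covariance keeps the convex-combination
guarantee.

## Prediction strategies and cross-validation

Three regimes cover a patient's course, all prequential (the prediction
at appointment $a$ never uses outcomes from $a$ onward):

* **AI** — every appointment predicted from the virtual profile, never
  updated; the uncertainty stays wide and constant-in-information.
* **BR** — appointment 1 as AI; from appointment 2 the model is refit
  from the *elicited prior* on all preceding visits. Deliberately strict:
  BR ignores the model-space pool entirely, so comparing BR with BU
  isolates the value of the pool. (Under conjugacy, refit-from-prior and
  sequential updating coincide when the starting beliefs coincide — the
  test suite checks this algebraic identity.)
* **BU** — appointment 1 as AI; the profile is then sequentially updated
  with each observed visit. Missing outcomes are predicted but skipped in
  updates.

`run_crossval()` performs patient-coherent k-fold validation (default
k = 10): fold sizes differ by at most one, every subject's visits stay in
exactly one fold, pools are fitted on training folds only, profiles for
validation subjects come from that pool only, and nothing from a
validation subject's outcomes can reach another subject's predictions —
an isolation property the tests probe by perturbation.

## Evaluation

The regression error pools within subject first,

$$ \mathrm{rms} = \sqrt{ \tfrac{1}{K}\sum_k \tfrac{1}{|S_k|}\sum_{s \in S_k} \tfrac{1}{A_s} \sum_a (y_{s,a} - \hat y_{s,a})^2 }, $$

so a 22-visit course counts no more than a 2-visit one. The defining
expression is read as a root-mean-square (the square root is applied):
only then is the error on the scale of the symptom scores.

Remission classification compares the predicted score *minus a critical
value* against the clinical threshold, boundary inclusive (a score exactly
at threshold is remission, consistently with the labeling rule). The
critical value is swept two ways:

* **quantile sweep** (default): the grid is a probability level $x$, and
  each case's offset is its own predictive lower-bound distance
  $\sqrt{\text{scale}^2}\, t_x(\nu)$ — more uncertain predictions get
  larger offsets, which is the point of carrying the full predictive
  distribution;
* **additive sweep**: one shared offset, swept over all distinct
  score–threshold gaps, which makes the trapezoid AUC exactly the
  Mann–Whitney pairwise concordance (verified to $10^{-9}$ against a
  brute-force oracle).

The ROC sweep spans both signs of the offset so the curve reaches both
corners; deployable operating points are restricted to the nonnegative
range (loosening toward sensitivity, which is the clinically motivated
direction under 14% prevalence) and selected by maximizing balanced
accuracy on data from the *other* folds only, ties broken toward the
smaller offset. Metrics with zero denominators are reported as `NA`,
never silently dropped.

## The synthetic cohort generator

No deposited dataset accompanies the titration setting, so
`generate_cohort()` emulates its statistical structure. Defaults, chosen
once and frozen:

* **Baselines** standard normal (factor scores are standardized by
  construction in the factor-analysis pipeline they stand in for).
* **Appointments** $A_s \sim$ uniform on 1–22; the true distribution of
  visit counts is unknown beyond its range, and uniform is a neutral
  stand-in.
* **Doses** as fractions of the maximum combined daily dose: stepwise
  ramp 0.2, 0.4, 0.6, 0.8, 1.0 over the first five appointments, then a
  plateau; one active medication at a time with a 5% per-appointment
  switch probability. The normalized unit scale makes the elicitation's
  unit-magnitude medication prior ($\tau_0 = -1$) commensurate with
  plausible true coefficients; with milligram units the same prior would
  imply absurd predicted effects.
* **Response vectors** drawn per coordinate: factor coefficients
  $N(0, 0.15)$, medication coefficients $N(-1, 0.35)$ (medication lowers
  symptoms — enforced as an invariant), intercept $N(0.75, 0.3)$. The
  intercept mean was calibrated once so that visit-level inattentiveness
  remission prevalence averages ≈ 0.14 under the default thresholds,
  matching the imbalance regime of a titration clinic;
  `calibrate_prevalence()` exposes the same bisection for other targets.
* **Noise** $\sigma_\varepsilon = 0.35$ per dimension; the two symptom
  dimensions share one response vector with independent noise (they are
  strongly correlated facets of one construct; the ground-truth container
  carries a single vector per subject).

What the generator does *not* emulate: questionnaire items and the factor
analysis that produces the scores (factors are emitted directly),
adherence and persistence effects, adverse drug reactions, dose decisions
reacting to observed scores (the ramp is exogenous), and dropout
correlated with response. Passing tests on this cohort therefore validate
the machinery — conjugate updating, profile construction, strategy
plumbing, evaluation — under the model's own assumptions, not clinical
performance on real data.

## Identifiability, and how the tests are constructed

Within a single subject the baseline block of the design is a rank-one
object: every baseline column is a multiple of the intercept column, so
whatever the number of visits, the data identify only the four medication
coefficients and the *combination* $\mathbf{b}_s\boldsymbol\omega_b +
\omega_0$. Two consequences shape the test design:

* **Parameter recovery** is checked on a configuration where the target
  is estimable: a long course (500 visits, varied on/off dosing) for a
  subject whose true baseline coefficients are zero, under a prior that
  encodes this (negligible variance on the baseline block). There the
  posterior mean recovers the response vector to $\lVert\hat\tau -
  \omega\rVert_2 < 0.1$ and the 95% predictive intervals cover held-out
  draws at nominal rate.
* **Method-1 fidelity** asks when the baseline → posterior map is
  *actually linear*, since only then can a linear profile map be exact.
  Because $X_s^\top X_s$ depends on $\mathbf{b}_s$, posteriors are
  nonlinear in the baselines whenever true baseline coefficients are
  nonzero — a generic linear ground truth $\omega_s = W\mathbf{b}_s$
  yields cosine alignment around 0.85, not exactness. In the linearly
  recoverable configuration (response depends on baselines only through
  the active-medication and intercept coefficients, shared dose schedule,
  pinned baseline prior), a noiseless 200-subject cohort is predicted
  with cross-validated rms ≈ 0.001.

## Numerical choices

* Singular or near-singular symmetric solves add diagonal jitter
  $10^{-8}\,\mathrm{tr}(M)/P$ with a warning; `nig_update()` also floors
  $\beta$ at the smallest positive double against cancellation in exact
  noiseless fits.
* `psd_repair()` symmetrizes and clips eigenvalues below $10^{-8}$.
* Belief states serialize to JSON at 17 significant digits, which
  round-trips doubles exactly; pools serialize as JSON lines.
* All generator and fold randomness flows through explicit integer seeds;
  the same configuration reproduces outputs byte for byte, and the
  private RNG stream is restored afterward so callers' random state is
  untouched.

## Problem sizes

The shipped tests and the acceptance script run cohorts of 150–200
subjects with 10-fold validation, 20 replicate cohorts for the strategy
comparison, 500-visit courses for recovery, and quadrature grids of a few
hundred nodes per axis — sizes chosen so the full suite completes in
about a minute on a single core while leaving each statistical check
comfortable margins.

## Limitations

The model is linear in doses and baselines with Gaussian noise and no
temporal covariates; medication switching enters only through the dose
columns; remission thresholds are fixed, not estimated. The elicited
prior's unit-magnitude factor directions overstate small true effects, so
profile-only (AI) prediction on the default synthetic cohort is markedly
worse than the updating strategies — visible in the acceptance output —
which is precisely the gap incremental Bayesian updating is designed to
close. Pool augmentation with partially observed new patients and
adverse-effect modeling are out of scope.
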