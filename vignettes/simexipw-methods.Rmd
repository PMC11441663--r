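---
title: "Methods: SIMEX-corrected IPW with confounder selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: SIMEX-corrected IPW with confounder selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The estimation problem

We want the average treatment effect (ATE)
$\tau_0 = E\{Y(1)\} - E\{Y(0)\}$ of a binary treatment $T$ on an outcome
$Y$ (continuous or binary), adjusting for a vector $W$ of pre-treatment
confounders through the propensity score $\pi = P(T = 1 \mid W)$. Under
strong ignorability, consistency (SUTVA), and positivity, the stabilized
(Hájek) inverse-probability-weighted estimator

$$
\hat\tau \;=\;
\Bigl(\sum_i \tfrac{T_i}{\hat\pi_i}\Bigr)^{-1} \sum_i \tfrac{T_i Y_i}{\hat\pi_i}
\;-\;
\Bigl(\sum_i \tfrac{1-T_i}{1-\hat\pi_i}\Bigr)^{-1} \sum_i \tfrac{(1-T_i) Y_i}{1-\hat\pi_i}
$$

is consistent when $\hat\pi_i$ comes from a correctly specified parametric
treatment model $g^{-1}(\pi) = W^\top\gamma$ (logistic, probit, or
complementary log-log link) fit to precisely measured confounders.

Two features of real data break this. First, part of $W$ — call it $X$,
with $Z$ the precisely measured remainder — is only observed through a
surrogate $X^* = X + e$ with classical additive error
$e \sim N(0, \Sigma_e)$ independent of everything else. Fitting the
treatment model to $X^*$ attenuates the coefficients and biases the
weights. Second, $W$ may contain spurious variables irrelevant to the
treatment; carrying them into the weight model inflates variability and can
distort the estimate.

The package addresses both at once with a five-step procedure: a
simulation–extrapolation (SIMEX) correction of the treatment-model
coefficients, penalized selection on the corrected coefficients, and a
SIMEX-extrapolated stabilized-IPW estimate on the selected model.

## The five steps

**Step 1 — simulation.** For each $\psi$ on a grid
$0 = \psi_1 < \cdots < \psi_M$ and $k = 1, \dots, K$, pseudo-surrogates

$$X^*_i(k, \psi) = X^*_i + \sqrt{\psi}\, e_{ik}, \qquad e_{ik} \sim N(0, \Sigma_e)$$

carry total error covariance $(1 + \psi)\Sigma_e$. The $\sqrt{\psi}$
scaling is essential: it makes the total error variance linear in $\psi$
and exactly zero at the extrapolation point $\psi = -1$. (A rendering of
this construction without the radical would inflate the error covariance
by $(1 + \psi)^2 \Sigma_e$-type terms and extrapolate to the wrong point;
`add_pseudo_error()` therefore implements the standard $\sqrt{\psi}$
form.)

**Step 2 — estimation.** The treatment model is refit by maximum likelihood
on each pseudo-surrogate design, and the $K$ estimates are averaged per
$\psi$: $\hat\gamma(\psi) = K^{-1}\sum_k \hat\gamma(k, \psi)$.

**Step 3 — extrapolation.** Each coefficient's trajectory
$\{(\psi, \hat\gamma_j(\psi))\}$ is fit with a working extrapolant —
quadratic (default), linear, cubic, or rational linear
$\beta_0 + \beta_1/(\beta_2 + \psi)$ — and evaluated at $\psi = -1$,
giving the corrected vector $\tilde\gamma$.

**Step 4 — selection.** $\tilde\gamma$ is cleaned by minimizing the
penalized quadratic loss
$\tfrac12(\gamma - \tilde\gamma)^\top V_n (\gamma - \tilde\gamma)
+ \sum_{j=1}^{p} \rho_\lambda(|\gamma_j|)$
(the intercept is never penalized) with LASSO, SCAD ($a = 3.7$), MCP
($a = 3$), or elastic-net penalties, and $\lambda$ tuned by BIC or V-fold
cross-validation. Zeros identify spurious confounders.

**Step 5 — weighting.** With the selected support fixed, the reduced
treatment model is refit per $(k, \psi)$ on regenerated pseudo-surrogates,
the stabilized IPW estimate $\hat\tau(k, \psi)$ is computed, averaged over
$k$, and the trajectory $\{(\psi, \hat\tau(\psi))\}$ is extrapolated to
$\psi = -1$. The reduced model is *refit* at each $(k,\psi)$ rather than
reusing Step 4's coefficient values: extrapolating $\hat\tau(\psi)$
requires estimates that respond to $\psi$, and the selection step's output
is $\psi$-free. The selected support only determines which columns enter
the reduced model.

Inference is by the nonparametric bootstrap: rows are resampled with
replacement (a subject's replicate columns travel together), Step 5 is
re-run with the support held fixed, the sample variance of the bootstrap
estimates is reported, and the p-value is the two-sided tail of a normal
reference, $2\{1 - \Phi(|\hat\tau| / \widehat{\mathrm{se}})\}$. The normal
reference is a choice — the procedure defines only "a variance and a
p-value" — and is recorded in the output (`reference = "normal"`). Because
selection is not repeated inside the bootstrap (matching a workflow where
the selected coefficient vector is an *input* to the ATE stage),
model-selection variability is understated.

## Four sources for the error covariance

* **Known** (`error_model()`): user-specified, e.g. for sensitivity
  analysis over plausible error magnitudes.
* **Replicates** (`sigma_e_from_replicates()`): the method-of-moments
  estimator — pooled within-subject scatter of replicate surrogates about
  their subject means over $\sum_i (n_i - 1)$. The within-subject mean uses
  the per-subject divisor $n_i$ (a flat $n^{-1}$ would be dimensionally
  inconsistent when replicate counts vary). This estimator is PSD by
  construction.
* **Validation** (`sigma_e_from_validation()`): covariance additivity,
  $\hat\Sigma_e = \hat\Sigma_{X^*} - \hat\Sigma_X$ over an external sample
  of paired true/surrogate values, both with divisor $m$ as the plain
  moment estimator. The difference can be indefinite in finite samples; it
  is then projected onto the PSD cone by eigenvalue truncation with a
  warning and a `psd_repaired` flag — truncation suffices because the
  matrix is only consumed by a Gaussian sampler, which needs a valid
  factorization, not a correlation structure.
* **Replicate contrasts** (`replicate = TRUE`): when *every* subject has
  $n_i \ge 2$ replicates, Step 1 is replaced by
  $X^{**}_i(k,\psi) = \bar X^*_i + \sqrt{\psi / n_i}\sum_j c_{ij} X^*_{ij}$
  with contrasts $c_{ij}$ built from fresh standard-normal draws, centered
  and scaled so $\sum_j c_{ij} = 0$, $\sum_j c_{ij}^2 = 1$. The increment
  has covariance $(\psi / n_i)\Sigma_e$ around the replicate mean (whose
  own error is $\Sigma_e / n_i$) without ever estimating $\Sigma_e$.

When only some subjects are replicated and $\Sigma_e$ is estimated from
them, the *first* replicate is used as the working surrogate for every
subject (`collapse = "first"`), so the surrogate error covariance is
exactly $\Sigma_e$ for all rows; per-subject means would give heterogeneous
covariance $\Sigma_e / n_i$, which the Step-1 generator does not model.
`collapse = "mean"` is available for users who prefer the lower-noise
surrogate and accept the approximation.

## Tuning parameters and defaults

| parameter | default | meaning |
|---|---|---|
| `psi` | 10 equally spaced points on $[0, 1]$ | error-inflation grid; $\psi_1 = 0$ required |
| `k` | 200 | simulated surrogate sets per grid point (50–500 reasonable) |
| `extrapolant` | quadratic | working extrapolation family |
| `link` | logistic | treatment-model link |
| penalty | SCAD in `ate_pipeline()` | near-unbiased for large coefficients |
| `a` | 3.7 (SCAD), 3 (MCP) | concavity constants |
| `b` | 100 | bootstrap resamples |
| `drop_max` | 0.10 | tolerated fraction of failed $(k,\psi)$ fits |

Larger `k` reduces Monte-Carlo noise in the per-$\psi$ averages at linear
cost in time. Extending the grid to $[0, 2]$ probes the trajectory more
widely but leans harder on the extrapolant's shape.

## Design choices where the design was open

**Sign and scale of the penalized loss.** Written literally, the Step-4
objective subtracts the penalty from the loss; a negative penalty cannot
produce sparsity, so the objective is implemented as loss *plus* penalty,
consistent with the shrinkage intent of the penalties themselves. The
sample-size multiplier on the penalty is absorbed into the $\lambda$ grid
(only the product matters once $\lambda$ is tuned); the default grid is 100
log-spaced values from the smallest all-zeroing $\lambda$ (a KKT bound)
down by a factor of 1000.

**The selection weight $V_n$.** `select_gamma()` defaults to the identity,
matching the reference workflow's unweighted loss. `ate_pipeline()`,
however, defaults `v = "information"`: the observed Fisher information of
the naive treatment-model fit. The reason is the BIC. With
$\mathrm{BIC}(\lambda) = 2\ell(\hat\gamma(\lambda)) + 2\log(n)\,df_\lambda$,
an identity-weighted $\ell$ is $O(1)$ per coefficient while the model-size
term is $2\log n$ per retained coefficient, so the criterion zeroes every
coefficient smaller than about $\sqrt{2\log n}$ — at any realistic sample
size it always selects the empty model. Weighting by the information
matrix makes $\ell$ the second-order approximation of the treatment-model
log-likelihood, which is exactly the scale on which a BIC trades fit
against size: truly zero coefficients (whose $\tilde\gamma_j$ is within
sampling noise of 0) are dropped and genuinely informative ones are kept.
`v = "identity"` remains available and reproduces the unweighted analysis.

**BIC conventions.** $\ell$ is a loss, so the textbook $-2\ell$ becomes
$+2\ell$; $df_\lambda$ counts all nonzero components including the
intercept; ties prefer the larger (sparser) $\lambda$.

**Cross-validation.** The loss is recast as least squares through a
square-root factor $R$ of $V_n$ (pseudo-response $R\tilde\gamma$, design
$R$) and squared prediction error is cross-validated over the $p + 1$
pseudo-observations. A subject-level CV — re-running the full SIMEX per
training fold — would be the other reading of "split the original
dataset", but it is incompatible with a selection stage whose inputs are
only $(V_n, \tilde\gamma)$, and is not implemented. Note that under
$V_n = I$ the pseudo-regression CV carries almost no information: a
held-out component's design column is identically zero in the training
rows, so its prediction cannot respond to $\lambda$. BIC is therefore the
pipeline default (`tuning = "bic"`); CV is provided for completeness and
for non-diagonal $V_n$.

**Numerical safeguards.**

* Inverse links are clamped to $[10^{-12}, 1 - 10^{-12}]$; propensities
  are further clamped to $[10^{-6}, 1 - 10^{-6}]$ before weighting, with
  the clamp count reported (`n_clamped`).
* The treatment model is fit by Newton–Raphson with step-halving and a
  BFGS fallback on a non-positive-definite information matrix; convergence
  means max-abs score below $10^{-8}$. Complete separation (every fitted
  probability numerically at its outcome) is flagged as non-convergence
  with a warning rather than an error, because the SIMEX loops average
  over many fits and isolated failures are dropped (up to `drop_max`,
  beyond which the run errors).
* Per-$(k, \psi)$ random draws use substreams derived deterministically
  from the master seed in $k$-major order, so results are bit-reproducible
  and changing $K$ or the grid does not silently reshuffle unrelated
  draws.
* The rational-linear extrapolant is fit by Levenberg–Marquardt with
  starts profiled over a grid of pole positions; it falls back to the
  quadratic (flagged and warned) when no admissible fit exists — pole on
  the fitting interval ($\beta_2 \in (-\psi_M, 0]$), pole at the
  extrapolation point ($|\beta_2 - 1| < 10^{-6}$), or a constant
  trajectory.
* SCAD/MCP coordinate updates use exact minimization over each quadratic
  piece of the penalty, so solutions carry hard zeros and match the
  closed-form threshold maps to $10^{-10}$ at $V = I$.

## What the synthetic-data generator does and does not emulate

`simulate_mev_data()` draws $W \sim N(0, \Sigma_W)$, assigns treatment
from the specified link and coefficients, composes observed outcomes from
potential outcomes, and adds classical Gaussian error (optionally as
replicates, with cross-confounder error correlation preserved within a
replicate index). The benchmark scenario — $n = 2000$, two error-prone and
three error-free confounders, $\gamma = (0, 0.5, 0.5, 0, 0, 0)$, linear
outcome $Y = T + 0.5(x_1 + z_1) + N(0, 1)$ so $\tau_0 = 1$, and
$\Sigma_e = 0.25 I$ (reliability 0.8 per surrogate) — was chosen to
exercise selection, correction, and ATE recovery simultaneously at an
error size where attenuation is material.

The generator matches the model assumptions exactly: Gaussian confounders,
a correctly specified link, homoscedastic classical error, no missing
data. Passing tests therefore demonstrate that the implementation realizes
the method under its own assumptions; they say nothing about robustness to
non-Gaussian confounders, Berkson or heteroscedastic error, link
misspecification, or informative missingness — all outside the method's
scope.

Test-suite problem sizes are the benchmark conditions above with 200
Monte-Carlo replicates for the bias comparisons (the first 100 for support
recovery), 5000 subjects / 5000 validation pairs for the covariance
estimators, and 20000 subjects for second-moment checks of the
replicate-contrast path; the acceptance script re-runs the same pipeline
at 50 replicates.

## Known limitations

* Classical additive Gaussian error only; no Berkson, heteroscedastic, or
  mixed discrete/continuous error.
* Parametric propensity models only, with $p < n$.
* Bootstrap inference holds the selected support fixed, understating
  selection uncertainty; the normal reference for the p-value is an
  approximation.
* Replicate layouts with unequal counts per confounder are truncated to
  the smallest count on the replicate-contrast path.
* Outcomes must be fully observed; no censoring.
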