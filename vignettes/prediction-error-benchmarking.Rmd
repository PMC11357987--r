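---
title: "Prediction-error benchmarking of linear and nonlinear neural dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prediction-error benchmarking of linear and nonlinear neural dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pembench)
```

## The question and the method

Macroscopic neural recordings — fMRI parcel time series, intracranial
field potentials — are produced by microscopically nonlinear machinery,
yet simple linear models often predict them as well as flexible nonlinear
ones. `pembench` provides the machinery to make that comparison honestly,
and a simulation suite that shows *why* it tends to come out that way.

The comparison framework is one-step-ahead prediction-error system
identification. Every model family is reduced to the same contract: fit on
training segments, then emit predictions $\hat y(t\,|\,t-1)$ on a held-out
test segment using only samples strictly before $t$. Two scores follow:

* **Accuracy.** Per channel $i$,
  $R^2_i = 1 - \sum_t \varepsilon_i(t)^2 / \sum_t (y_i(t)-\bar y_i)^2$
  with $\varepsilon(t) = y(t) - \hat y(t\,|\,t-1)$ and $\bar y_i$ the mean
  of the *scored test samples*. This choice of baseline makes
  "$R^2 = 0$ $\Leftrightarrow$ as good as the constant predictor" literally
  true on the test segment; the statement is ambiguous if a training mean
  is used instead. $R^2 \le 1$ always, and can be negative. Channels that
  are constant on the test segment have no defined $R^2$ and are reported
  as `NA` and excluded from medians.

* **Whiteness.** If a model has captured all temporal structure, its
  residuals should be serially independent. We use the multivariate
  portmanteau statistic
  $Q = (N-M)\sum_{i=1}^{M} \mathrm{tr}\!\left(\hat R(i)^\top \hat R(0)^{+}
  \hat R(i) \hat R(0)^{+}\right)$ with
  $\hat R(i) = \frac{1}{N-M}\sum_{t=0}^{N-M-1} e(t+i)e(t)^\top$.
  On real recordings the asymptotic $\chi^2$ law of $Q$ is unreliable, so
  the rejection threshold $Q_{thr}$ is the 95th percentile of $Q$ over 100
  random time permutations of the residuals; `Q/Q_thr <= 1` means
  whiteness is not rejected. A Box–Pierce $\chi^2$ variant
  (`chi2_whiteness_univariate`, with a Ljung–Box option) covers inherently
  univariate residuals. The lag count defaults to
  $M = \min(20, \lfloor N/5\rfloor)$ — a conventional choice; the
  randomization threshold makes results insensitive to it.

The baseline every model must beat is the zero-order hold
$\hat y(t\,|\,t-1) = y(t-1)$ — a random walk, which on smooth signals
already scores a high $R^2$. Comparisons between families use one-sided
Wilcoxon signed-rank tests on paired scores with Benjamini–Hochberg FDR
control.

## Model families and their numerical choices

**Linear (V)AR** (`fit_ar`). First-difference dynamics
$y(t) - y(t-1) = W y(t-1) + D_2 y(t-2) + \cdots + D_d y(t-d) + e(t)$,
where $W$ is the effective-connectivity matrix. `structure` selects dense
(ordinary least squares), sparse (LASSO, objective
$\mathrm{RSS} + \lambda \sum |\beta|$, solved by coordinate descent via
glmnet with internal standardization), or scalar ($W$ and all $D_p$
diagonal: $n$ decoupled scalar AR models). `lag_mode` keeps $D_{p\ge 2}$
diagonal (AR flavor) or full (VAR flavor). Channels are mean-centered per
training segment and the pooled mean is stored and reapplied at
prediction; the data source does not always guarantee centered inputs,
and this keeps the constant-predictor baseline of $R^2$ coherent. Lags
never cross segment boundaries — segments are independent recordings — so
within each test segment predictions start at $t = d+1$.

**Subspace state space** (`fit_subspace`). When predictable structure
lives in fewer dimensions than channels, an innovation-form model
$x(t+1) = A x(t) + w(t)$, $y(t) = C x(t) + v(t)$ is identified by a
projection-based stochastic subspace method: past and future output
block-Hankel matrices ($s$ past, $r$ future block rows), orthogonal
projection of the future onto the past row space, truncated SVD at order
$n_x$, then least-squares regressions on the recovered state sequence for
$(A, C)$ and the noise covariances $(Q, M, R)$. Because $(Q, M, R)$ is a
genuine sample covariance, the filter Riccati recursion for the
steady-state predictor gain $K$ is well-posed; it is iterated to
$10^{-10}$ (at most $10^4$ iterations, otherwise a numerical-degeneracy
error). We chose this variant over the covariance-Hankel factorization
route, whose Riccati recursion can diverge when the estimated covariance
sequence fails to be positive real on finite data. The predictor filter
runs from a zero state, and the first $\max(r, s)$ predictions are flagged
as burn-in and excluded from scoring. Asking for $n_x$ above the numerical
rank of the projection produces a warning rather than an error: truncated
directions carry (near-)zero singular value and are harmless to the
predictor.

**Locally linear, "model on demand"** (`manifold_predict`). For each test
query (the $d$ stacked lags), training points are weighted by
$k^{\ell,m} = \exp(-\|q_m - q_\ell\|^2 / 2h^2)$ and an order-1 local
polynomial $[c\; W]$ is fit by weighted least squares through a
pseudo-inverse whose singular values are truncated below $10^{-10}$ of the
largest; the local intercept $c$ is the predicted first difference. The
bandwidth $h$ interpolates between nearest-neighbor prediction and the
global linear model (equal weights as $h \to \infty$). If every weight
underflows to zero (a query far outside the training cloud at small $h$),
the prediction falls back to the global linear fit with a logged warning.
There is no training phase, so training time is defined as zero.

**MMSE conditional expectation** (`mmse_predict`). The conditional mean
$E[\,y_i(t)-y_i(t-1)\mid \text{conditioning}\,]$ is the minimum-MSE
predictor among *all* functions of the conditioning variables, so its
cross-validated $R^2$ upper-bounds what any nonlinear model of the same
inputs can achieve. It is estimated nonparametrically: Gaussian weights in
the conditioning variable with $\sigma = \beta \times$ (training range),
an `n_bins`-bin weighted histogram of the training first differences over
their training range, normalization, and the histogram mean. Pairwise mode
conditions channel $i$ on a designated source channel at $t-1$ (the
training range is taken over the conditioning channels jointly); scalar
mode conditions on $d$ own lags with Euclidean distance (range per
channel). Defaults $\beta = 0.02$ and `n_bins = 100`; the observation-
noise experiment widens the window as $\beta = 0.02 + 0.02/\mathrm{SNR}$,
since noisier conditioning variables carry less information per unit
distance. Degenerate cases are explicit: a zero training range is an
error; queries where all histogram mass underflows fall back to the
unconditional mean difference with a logged warning. Because the window
is a fraction of the *joint* training range, channels on very different
scales should be standardized first; the estimator is scale-equivariant
per channel only in scalar mode.

**MLP NARX** (`fit_mlp`). A fully connected network maps the stacked lags
to the first difference: $D$ blocks of [linear map, batch normalization,
ReLU, dropout 0.5], a final linear layer, minibatch Adam under a fixed
seed, inputs standardized internally. A 10 % validation split provides
early stopping (patience 20, epoch cap 200). Batch normalization uses
batch statistics in training and running statistics (momentum 0.9) at
evaluation; dropout is disabled at evaluation. The implementation is
self-contained R with an analytically derived backward pass, verified in
the unit tests against finite differences. Identity activations are
available as a control: the network then collapses to an affine map and
should match the dense linear model.

**Hyperparameter search** (`sgd_tune`). A stochastic ascent over
hyperparameter vectors: per iteration, candidates form either the full
$3^{N}$ hypercubic mesh around the incumbent (probe steps: 1 for integer,
$10^{-6}$ for real parameters) or the $2N+1$ coordinate directions; each
candidate is scored on an independently drawn minibatch; integer
parameters jump to the best candidate while real parameters take a
gradient step along the finite-difference slope with step size
$0.1 \times \max(|\theta|, 1)$ (the probe step pins the slope estimate,
not the update size, which is otherwise unspecified — this scale-aware
default is ours). Ties keep the incumbent; the search stops at the
iteration budget or after 10 unchanged iterations.

## What the synthetic-data generators emulate

The generators produce every input the comparisons need, each a pure
function of its parameters and seed:

* `gen_stable_var` — ground-truth sparse stable first-difference VARs.
  Stability is exact, not approximate: scaling the lag-$p$ coefficient by
  $s^p$ scales every companion eigenvalue by $s$, so one rescale sets the
  spectral radius to the target. A burn-in of $10n$ samples is discarded
  (empirically ample at spectral radius $\le 0.95$).
* `gen_iid_tanh_ensemble` — pairs $(x_i, \tanh x_i)$ with iid standard
  normal inputs. The input law is our choice: zero-mean and symmetric
  keeps the sigmoid centered in its active region.
* `gen_sphere_correlated_ensemble` — jointly Gaussian units placed
  uniformly in the unit ball with correlation $\exp(-d_{ij}/\rho)$; the
  exponential is the simplest monotone kernel consistent with
  "correlation decays with distance". Cholesky factorization escalates
  jitter ($0$ to $10^{-4}$) before declaring degeneracy; $\rho = \infty$
  short-circuits to exact copies of one signal.
* `gen_colored_signal` — spectral synthesis with amplitude
  $(1+k)^{-p/2}$ over the frequency index $k$ and uniform phases; the
  $1+k$ form keeps the DC amplitude finite, and the log–log periodogram
  slope is $-p$ away from the lowest frequencies. Output is normalized to
  unit sample variance.
* `gaussian_lpf` — time-domain Gaussian kernel with
  $\sigma_t = 1/f_{cutoff} - 1$ samples (truncated at $4\sigma_t$,
  unit-sum taps, mirror boundary), parameterized so that
  $f_{cutoff} = 1$ is *exactly* the identity.
* `add_noise_at_snr` — independent Gaussian noise with variance
  $\mathrm{var}(\text{signal})/\mathrm{SNR}$ (SNR as a variance ratio).
* `gen_sum_tanh_dataset` — $y = \tanh(x_1 + \cdots + x_n)$, a
  one-dimensional nonlinearity embedded in $n+1$ dimensions, noise-free.
* `simulate_izhikevich` — uncoupled quadratic integrate-and-fire neurons
  with recovery, forward Euler at 0.1 ms, reset at 30 mV. Coupling is
  deliberately absent: the averaging demonstration isolates the effect of
  summing many units, and coupling would confound it. With
  `random_init = TRUE` initial potentials are drawn uniformly between the
  reset value and threshold, modelling an asynchronous population; a
  population started in lockstep would stay partially synchronized for
  many cycles and its mean would not shrink like that of independent
  units.

What these generators do **not** emulate: haemodynamics (no HRF forward
model), spatial structure beyond pairwise correlation, nonstationarity,
coupling between neurons, or measurement artifacts. Passing tests on this
suite therefore demonstrates the *mechanisms* — averaging, filtering,
noise, and dimensionality linearize — not that any particular real
dataset is linear.

## The linearizing-effects experiments

Each experiment pits plain linear regression against the optimal
nonlinear predictor (MMSE for one-dimensional conditioning; the locally
linear predictor in higher dimensions, where conditional density
estimation starves) on identical data within each repetition, and
reports the mean and standard error of both cross-validated $R^2$ values
over a parameter grid. "The relation is effectively linear" is
operationalized as the mean nonlinear-minus-linear gap dropping below
$\varepsilon = 0.01$ (`gap_threshold`); the threshold is ours — the
underlying claim is about curves, and 0.01 in $R^2$ is well below any
difference a model comparison would act on. Cross-validation is 2-fold
(contiguous halves) for the static relations and 5-fold for the
dimensionality experiment; with iid samples the fold geometry is
immaterial, and contiguous folds keep runs deterministic.

Default problem sizes — series of length 2,000, 20 repetitions per grid
point (10 for the dimensionality sweep with $N = 1000$ samples), bandwidth
swept logarithmically over $[0.1, 10]$ in 12 points — reproduce all
qualitative effects with standard errors a few times smaller than the
effects themselves. In the dimensionality experiment the best bandwidth
per fold is chosen by test-fold $R^2$, mirroring how the optimal window is
tracked as dimension grows; its per-fold argmax is noisy once every
bandwidth behaves globally, so only the trend of the mean bandwidth is
meaningful, not adjacent-point monotonicity. Ties in any grid argmax go to
the smallest grid value.

The Izhikevich experiment scores one-step prediction (scalar AR-1 versus
scalar MMSE) on the population-averaged membrane potential binned at
1 ms. The input-current noise (std 3 by default) is what desynchronizes
the neurons; with it, the nonlinear advantage present for a single neuron
(spike-reset dynamics are strongly nonlinear) collapses once a thousand
neurons are averaged.

## Known limitations

* The MMSE estimator degrades when conditioning variables have very
  different scales (global window width) or when the conditional
  distribution has heavy tails the histogram range cannot cover;
  standardize channels first.
* The subspace routine assumes stationary segments; it refuses to filter
  with an unstable predictor rather than returning divergent predictions.
* The MLP trainer is a compact reference implementation, adequate for the
  small networks used here, not a performance-tuned deep-learning stack.
* Whiteness shuffling treats samples as exchangeable under the null;
  residual heteroscedasticity (not serial dependence) can still inflate
  rejection slightly.
* The fMRI-like and iEEG-like cross-validation plans implement the
  segment arithmetic of the corresponding protocols; they do not parse
  neuroimaging container formats — recordings enter as channels-by-time
  matrices (`read_recording`).
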