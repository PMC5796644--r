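---
title: "Methods: spectral DCM, functional-connectivity priors, and Bayesian model reduction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spectral DCM, functional-connectivity priors, and Bayesian model reduction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(specdcm)
```

This vignette is the package's own account of the model it implements, the
choices that were genuinely open, and what its synthetic benchmarks do and
do not demonstrate.

## The generative model

Resting-state BOLD dynamics are modeled as a linear stochastic system at
the neural level,

$$\dot x(t) = A\,x(t) + v(t),$$

where $x$ are hidden neural states of $n$ regions and $A$ (in Hz) is the
effective connectivity: $A_{ij}$ is the directed, signed rate at which
region $j$ influences region $i$ (column = source, row = target, so an
in-strength is a row sum). Self-connections are inhibitory by
construction: the diagonal is parameterized as $-0.5\,e^{\theta_{ii}}$ Hz,
which precludes runaway excitation and makes $\theta_{ii}$ a dimensionless
log-scaling with a Gaussian prior. Exogenous inputs exist in the model
specification (`C`, `u`) but are frozen at zero at rest; the inversion
entry point rejects nonzero values.

The endogenous fluctuations $v(t)$ and the observation noise $e(t)$ are
parameterized in the spectral domain as scale-free power laws,

$$g_v(\omega) = \alpha_v\,\omega^{-\beta_v}, \qquad
  g_e(\omega) = \alpha_e\,\omega^{-\beta_e},$$

with per-region amplitudes (log-parameterized) and one shared exponent
each (additive deviation around 1, i.e. 1/f by default). Whether the
amplitude should be shared across regions is not settled; per-region is
the default and a shared variant is used by the simulator's mode-rank
scenario (below).

Each region's neural state drives BOLD through the four-state
balloon–Windkessel model (vasodilatory signal, blood flow, venous volume,
deoxyhemoglobin). Only two hemodynamic parameters are estimated per
region — venous transit time ($2 e^{\theta}$ s) and the
intra/extravascular ratio $\epsilon$ — with the remaining constants fixed
at conventional values and collected in `hemo_constants()`: signal decay
$\kappa = 0.64\,s^{-1}$, autoregulation $\gamma = 0.32\,s^{-1}$, Grubb
exponent $0.32$, resting oxygen extraction $E_0 = 0.4$, echo-time-
dependent output constants at 3T ($TE = 0.04$ s, $V_0 = 4$,
$k_1 = 4.3\,\nu_0 E_0\,TE$, $k_2 = \epsilon\,r_0 E_0\,TE$,
$k_3 = 1-\epsilon$). For the frequency-domain model the balloon system is
linearized around its fixed point; `hemodynamic_transfer()` returns the
complex low-pass gain $B_i(\omega)$ of that linearization, and the tests
verify it against the numerically integrated nonlinear impulse response
(2% over the analysis band).

The data features are complex cross-spectral densities. The predicted
spectra compose the pieces:

$$G_y(\omega) = H(\omega)\, G_v(\omega)\, H(\omega)^\dagger + G_e(\omega),
\qquad H(\omega) = \mathrm{diag}\big(B(\omega)\big)\,(i\omega I - A)^{-1}.$$

Both $G_v$ and $G_e$ are diagonal (independent fluctuations, regionally
specific noise; a shared global noise component is not modeled). All
densities in the package are two-sided, per Hz, indexed by frequency in Hz,
with the power laws evaluated at $\omega = 2\pi f$; for a single region
with unit gain this gives the exact closed form
$\alpha\omega^{-\beta}/(\omega^2+a^2)$, which the test suite checks to
machine precision.

### Frequency grid

The analysis band is 0.0078–0.1 Hz, the standard resting-state band
between scanner drift and the hemodynamic roll-off. `model_spec()`
defaults to 32 linearly spaced bins (linear spacing keeps Parseval-style
checks simple); the workbench configuration fits on 8 bins — see
"Feature count and posterior calibration" below for why.

## Estimating the observed spectra

`estimate_csd()` removes the mean and linear trend (optionally a
high-pass at the band edge) and fits a multivariate autoregressive model
by least squares, converting the coefficients to spectral densities on
the requested grid: smooth parametric spectra suited to a few hundred
volumes. The MAR order is a convention; 8 is the function default, and
the workbench uses 16 (32 s of memory at TR = 2 s), which in our
benchmarks trades a little variance for a visibly better-calibrated
posterior downstream. A Welch cross-periodogram (`method = "welch"`,
Hann window, 50% overlap, band-averaged onto the grid) provides a
nonparametric cross-check and is the estimator used in the
simulator-versus-model agreement test, where data are long.

## Variational Laplace inversion

`invert()` fits the model by Gauss–Newton ascent on the variational free
energy $F$ (nats), the evidence lower bound: expected log-likelihood of
the packed spectral features under a Gaussian posterior minus
KL(posterior ‖ prior). Implementation contracts:

* **Monotone trace.** Steps are Levenberg-regularized; a candidate step
  is re-evaluated fully (residuals, Jacobian, curvature) and accepted
  only if it does not decrease $F$; otherwise the regularization is
  escalated (up to 8 retries). The recorded trace of accepted $F$ values
  is therefore non-decreasing by construction, and every test asserts it.
* **Convergence.** $\Delta F < 0.01$ nats for 3 consecutive iterations,
  cap 128.
* **Noise precisions.** The Gaussian feature noise has log-precision
  hyperparameters updated between parameter steps by deterministic line
  searches, each kept only if $F$ does not decrease. The hyperprior is
  Gaussian with variance 16 and a mean centered empirically at the
  precision implied by the prior-mean prediction error (capped so an
  exact fit stays finite).
* **Priors.** Off-diagonal couplings $\mathcal N(0, 1/64)$ (Hz), self
  log-scalings $\mathcal N(0, 1/256)$, fluctuation/noise log-parameters
  $\mathcal N(0, 1/64)$, hemodynamic log-deviations
  $\mathcal N(0, 1/256)$ — standard shrinkage values, all exposed in
  `prior_spec()`.
* **Scale.** Because the amplitude priors are tight, the observed
  spectra are rescaled once so their mean auto-spectral power matches the
  prior-mean prediction; the factor is reported as `$scale`. Coupling
  estimates are invariant to this.
* **Rank-deficient priors.** A mode-reduced prior covariance is handled
  by estimating coefficients in its column space (eigen-truncation at
  relative $10^{-8}$), so the optimizer never touches null directions.
* **Determinism.** The optimizer contains no randomness; identical
  inputs give identical posteriors, which the workbench tests check at
  the byte level.

### Feature count and posterior calibration

A Gaussian likelihood over spectral features treats every bin as an
independent observation. MAR-derived spectra are smooth: 32 bins across
a one-decade band carry roughly the information of an order-16 MAR fit,
not of 32 independent measurements, and treating them as independent
makes the posterior overconfident — harmless for point estimates, but
fatal for evidence-based pruning, which then retains every noisily
nonzero edge. Two settings keep the implied information count honest:
the workbench fits on 8 bins (spacing comparable to the estimator's
effective resolution), and the noise precision is estimated per
frequency band (8 components by default) because residual magnitudes
vary strongly across a power-law band. With these settings the 6-node
benchmarks recover both weights and support (median correlation ≈ 0.8,
pruning sensitivity and specificity ≈ 0.75 over ten replicates).

## Functional-connectivity priors and the mode sweep

Large graphs have $O(n^2)$ couplings. The prior covariance over
$\mathrm{vec}(A)$ (column-major throughout, asserted by a cross-module
test) can be projected onto the leading left singular vectors $U_m$ of
the row-centered data matrix:

$$K_m = (U_m U_m^\top) \otimes (U_m U_m^\top), \qquad
  \Sigma_m = K_m\,\Sigma\,K_m^\top,$$

which introduces prior correlations and reduces the effective number of
coupling parameters to $m^2$: coupling among *modes* rather than among
*nodes*. The projector is kept in factored form (its $n\times n$ node
projector) and materialized only on demand. Two refinements:

* The constraint concerns extrinsic (between-region) coupling;
  `reduce_prior()` therefore restores the self-connection prior variance
  on the diagonal slots, so intrinsic inhibition stays estimable at any
  $m$.
* At $m = n$ the projector is analytically the identity, so the sweep
  uses the full prior unchanged there and its $\Delta F$ is exactly zero
  — not merely numerically small.

`sweep_modes()` scores every $m$ by Bayesian model reduction of one full
inversion and selects the maximum (ties toward smaller $m$), reporting
the curve relative to $m = 1$. A caution the sweep inherits from the
method itself: for spectral DCM the free-energy curve typically rises
and then *plateaus*, so selection by strict argmax on the plateau is
noisy — in the mode-rank benchmark the selected $m^*$ usually falls at
or just above the generating rank, with occasional excursions toward
$n$ when the estimated modes are misaligned. Starting a routine analysis
at a moderate fixed $m$ (around 10 for dozens of nodes) is the
pragmatic alternative; both workflows are supported.

## Bayesian model reduction

`reduce_model()` computes, from a single full inversion, the posterior
and log-evidence change under any modified prior, in closed form via
precision arithmetic; on conjugate linear-Gaussian models it matches
exact evidence differences to better than $10^{-6}$ nats (tested over
100 random prior modifications). Singular covariances are floored at
$10^{-8}$, which is also the removal variance used for pruning: an
"absent" edge is a prior pinned at zero with negligible variance, never
an exactly singular precision.

`prune_edges()` scores each off-diagonal coupling by the $\Delta F$ of
its removal — evaluated by an algebraically equivalent rank-one shortcut,
tested against the full reduction — and eliminates edges whose removal
strictly increases the evidence, then removes the flagged set jointly.
Ties ($\Delta F = 0$) retain the edge. Self-connections are never
pruned. A greedy variant iterates scoring against the jointly reduced
posterior until the set is stable; the single pass is the default. The
result is a sparse, signed, weighted, directed adjacency with a
companion retention mask — a principled alternative to magnitude
thresholding, and the binarization used by the group summaries.

## The simulator and what the benchmarks mean

`make_ground_truth()` + `simulate_bold()` generate data the inversion
has never seen as model output: neural states are stepped exactly
(zero-order-hold matrix exponential) under fluctuations synthesized by
spectral factorization of white noise (with a documented low-frequency
floor at 0.001 Hz for non-integrable exponents), passed through the
*nonlinear* balloon model (RK4 in log-states, compiled, with internal
sub-stepping; positivity by construction), downsampled to TR by
zero-order hold, and corrupted by power-law observation noise at TR
resolution. The study conditions are fixed once:

* TR = 2 s, a few hundred volumes (512 in the benchmarks), band
  0.0078–0.1 Hz — a typical resting-state acquisition.
* Coupling scale 0.25 Hz with magnitudes uniform in [0.5, 1.5] × scale
  and random signs; 40% edge density for the sparse scenario; diagonal
  deepened (×1.25 steps) until the stability margin is below −0.05 Hz.
* Fluctuation amplitudes calibrated so in-band BOLD fluctuations have
  standard deviation 0.75 percent signal units — the order of
  resting-state gray-matter fluctuations, and comfortably inside the
  hemodynamic linear regime, whatever the network's stability margin.
  The sparse scenario calibrates per region; the mode-rank scenario uses
  one shared amplitude, because per-region rescaling would distort the
  mode geometry that scenario exists to embody.
* Observation-noise density at band center set to 10% of each region's
  signal power (moderate SNR for eigenvariate data).
* The mode-rank scenario builds $A$'s deviation as $U(S+K)U^\top$ with
  $S$ symmetric positive definite (eigenvalues ≈ 1.4 × scale): net
  excitatory within-mode coupling amplifies variance along the mode
  span, which is what makes the modes visible to functional
  connectivity in the first place — the premise of using FC priors on
  effective connectivity.

What passing benchmarks show: the full loop (simulate → estimate spectra
→ invert → reduce) identifies directed, signed couplings and sparse
structure under realistic sampling, noise, and nonlinear hemodynamics
that the fitted (linearized, spectral) model does not itself assume.
What they do not show: robustness to head motion, physiological
confounds, regional hemodynamic variability beyond transit/$\epsilon$,
non-power-law noise, ROI misspecification, or anything about the
empirical group analyses the method is typically used for; users supply
cleaned regional time series.

## Problem sizes and numerics

The shipped tests and the acceptance script run 6-node (sparse) and
8-node (mode-rank) studies with ten replicates each, one long (2^18
neural samples) simulator-agreement run, and closed-form oracles; the
whole suite completes in a few minutes on one core. The method itself
has no such limit — cost is dominated by the finite-difference Jacobian
(one spectral prediction per parameter per iteration), quadratic-to-
cubic in $n^2$ — and the per-edge pruning scores use the rank-one
shortcut precisely so that graphs with dozens of nodes stay cheap after
one full inversion. Degenerate inputs are rejected with named errors
(zero-variance regions, non-Hermitian features, unstable coupling
matrices, incompatible prior modifications, grids off the model's band).
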