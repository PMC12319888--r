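---
title: "Two-compartment exchange models of gray-matter diffusion MRI: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-compartment exchange models of gray-matter diffusion MRI: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gmexi)
```

## The model

Gray matter is modelled as two exchanging water pools: an intra-neurite
compartment (randomly oriented zero-radius sticks, one-dimensional
diffusion at $D_i$ along the stick axis) and an isotropic Gaussian
extra-neurite compartment ($D_e$), with signal fractions $f$ and $1-f$
and an inter-compartment exchange time $t_{ex}$.  The parameter vector is
$p = [t_{ex},\, D_i,\, D_e,\, f]$ with units ms, µm²/ms, µm²/ms and
dimensionless.

Along one gradient direction with orientation cosine $u = \mathbf{g}
\cdot \mathbf{n}$, the two-pool magnetization obeys the generalized rate
(Kärger) equation

$$
\frac{dM}{dt} = \left(R - k(t)^2 D\right) M, \qquad
D = \mathrm{diag}(D_i u^2,\ D_e), \qquad
R = \begin{pmatrix} -k_{ie} & k_{ei} \\ k_{ie} & -k_{ei} \end{pmatrix},
$$

with $M(0) = (f,\, 1-f)^\top$.  The exchange rates satisfy detailed
balance $f\,k_{ie} = (1-f)\,k_{ei}$ and $1/t_{ex} = k_{ie} + k_{ei}$,
giving $k_{ie} = (1-f)/t_{ex}$ and $k_{ei} = f/t_{ex}$.  Under this
convention $t_{ex}$ is the *total* exchange time (the harmonic sum of the
two residence times), which is the standard Kärger parameterization; the
intra-neurite residence time is $t_i = t_{ex}/(1-f)$ if needed for
comparison with other conventions.  The columns of $R$ sum to zero (mass
conservation) and the equilibrium fractions are stationary under $R$.

The powder-averaged signal integrates the per-direction kernel over the
orientation cosine,

$$
\bar S(b, t_d) = \int_0^1 K(u;\ p,\ q,\ t_d)\, du ,
$$

which this package evaluates by fixed-order Gauss–Legendre quadrature.

### NEXI: the narrow-pulse limit

When the gradient pulses (duration $\delta$) are treated as
instantaneous, the kernel has the closed form

$$
K = \mathbf{1}^\top \exp\!\big[(R - q^2 D)\, t_d\big]\, M(0),
\qquad t_d = \Delta - \delta/3, \qquad q = \sqrt{b/t_d}.
$$

The $\delta/3$ correction to the diffusion time is the standard PGSE
bookkeeping that makes $b = q^2 t_d$ exact for rectangular pulses.  The
2×2 exponential is evaluated in closed form via its eigendecomposition
(the off-diagonal entries of $R - q^2D$ are non-negative, so the
eigenvalues are always real); the degenerate-eigenvalue branch uses
$e^{\lambda t}(I + (A - \lambda I)t)$.

### SMEX: finite pulses

On clinical gradient systems $\delta$ is long (16.5 ms here) and the
narrow-pulse assumption is violated.  SMEX integrates the same rate
equation through the actual rectangular waveform: the wave number ramps
linearly over $[0, \delta]$, is constant at $q_{\max} =
\sqrt{b/(\Delta-\delta/3)}$ on $[\delta, \Delta]$, and ramps down over
$[\Delta, \Delta+\delta]$.  The constant plateau is advanced with the
analytic matrix-exponential propagator
$\exp[(\Delta-\delta)(R - q_{\max}^2 D)]$; the two ramps are integrated
with an adaptive Dormand–Prince RK45.  Both ramps are integrated
explicitly — $R$ and $D$ do not commute, so the second pulse is not
assumed to mirror the first.  The models share parameters exactly and
differ only in their treatment of the pulse width; as $\delta \to 0$
SMEX converges to NEXI, which the test suite verifies over the full
parameter ranges at $\delta = 2, 0.5, 0.1$ ms.

## Numerical choices

* **Orientation quadrature**: Gauss–Legendre with 32 nodes on $[0,1]$.
  The integrand is smooth in $u$, and doubling to 64 nodes changes no
  clinical-protocol signal by more than $10^{-8}$ (asserted in the test
  suite).
* **Ramp integration**: adaptive RK45 with `rtol = 1e-8`, `atol = 1e-10`
  per pulse segment.  Loose ODE control is a known source of comb-like
  artifacts in fitted-parameter histograms when combined with a
  grid-search initializer, so the defaults are deliberately tight; the
  analytic-plateau fast path agrees with a dense ODE solve of the whole
  interval to $10^{-8}$.
* **$\delta = \Delta$** (no plateau) is handled by skipping the analytic
  segment.
* **Degenerate eigenvalues** in the 2×2 exponential switch to the
  first-order expansion when the eigenvalue gap falls below
  $10^{-12}$ of the eigenvalue scale.
* **Rician expectation**: $E[S] = \sigma\sqrt{\pi/2}\,
  L_{1/2}(-\nu^2/2\sigma^2)$ is evaluated with exponentially-scaled
  Bessel functions $I_0, I_1$; above $\nu/\sigma = 30$ the asymptotic
  series $\nu + \sigma^2/2\nu - \sigma^4/8\nu^3$ is used to avoid any
  overflow path.  $\sigma$ is the per-magnitude-image scale in
  b0-normalized units: the Rician bias of an average of magnitudes is
  the average of the per-image biases, so the floor transform applies
  $\sigma$ itself to the powder-averaged prediction (not
  $\sigma/\sqrt{n_\text{dirs}}$), while the Gaussian spread of the
  average does scale with $1/\sqrt{n_\text{dirs}}$ in simulations.

## Fitting

The fit target is the powder-averaged, per-$\Delta$ b0-normalized signal
curve; only b > 0 shells enter the objective (after normalization the
b = 0 points are identically 1 and carry no information), so the
clinical protocol has $n = 16$ fitted points.  The objective is the
floor-corrected residual sum of squares
$\sum_s \big(\hat S_s - E_\text{Rice}[S_s(p)]\big)^2$.

* **Initialization**: a grid search over 8 points per axis
  ($t_{ex}$ log-spaced, others linear; 4096 candidates before the
  $D_i > D_e$ filter).  $D_i > D_e$ is enforced *only* here — it is a
  soft constraint that guides the starting basin, and the optimizer may
  subsequently cross it.  The candidate signal matrix depends only on
  the grid and the protocol, so it is computed once and cached across
  voxels.  For SMEX the grid is evaluated with relaxed settings
  (16 orientation nodes, ramp `rtol = 1e-6`); the grid is an initializer
  and the relaxed model selects the same basin at a fraction of the
  cost, while the NLS itself always runs at the forward-model defaults.
* **Optimizer**: bounded quasi-Newton (L-BFGS-B) on parameters rescaled
  to the unit box (the raw scales span three orders of magnitude), with
  objective tolerance $10^{-14}$ (`factr = 45`).  Box bounds default to
  $t_{ex} \in [1, 150]$ ms, $D_i, D_e \in [0.1, 3.5]$ µm²/ms,
  $f \in [0.1, 0.9]$.  The gradient is a batched central difference
  (step $10^{-6}$ on the unit box) evaluated through one vectorized
  forward call; estimates are flagged `at_bound` when within
  $10^{-9}$ of a bound (relative to its span), and the NLS result is
  never allowed to be worse than its grid start.
* **Model comparison**: AICc in the Gaussian least-squares form
  $n\ln(\mathrm{rss}/n) + 2k + 2k(k+1)/(n-k-1)$ with $k = 4$ ($\sigma$
  fixed, not counted), matching the scale on which the two model
  variants are compared on real data.
* `model_jacobian()` exposes forward-model sensitivities for NEXI via
  complex-step differentiation of the closed-form kernel (machine
  precision) and for SMEX via central differences with tightened ODE
  tolerances; both are validated against an independent
  finite-difference oracle.

## The synthetic study

`sample_ground_truth()` draws flat, independent parameters from
$t_{ex} \in [1, 40]$ ms, $D_i \in [2.5, 3.5]$, $D_e \in [0.5, 1.5]$
µm²/ms, $f \in [0.2, 0.7]$ — plausible cortical ranges.
`generate_dataset()` emulates the acquisition: per voxel and b > 0
shell, 20 Rician magnitude draws around the noiseless signal are
averaged (the direction count of the clinical protocol); b = 0 shells
get a single draw, and every shell is divided by the noisy b0 of its
diffusion time, so normalization noise is part of the pipeline.  The
default noise scale is $\sigma = 0.02$ in b0-normalized units (SNR 50
at b = 0), a plausible clinical value chosen once; the experimental
noise level of any given scanner should be substituted when known,
since absolute bias magnitudes depend on it.

`recovery_study()` generates with SMEX (the finite-pulse model is the
more faithful generator for wide pulses), fits with NEXI and/or SMEX,
discards voxels whose fit hit a bound or failed to converge, and
reports per-parameter bias and RMSE with the paired (truth, estimate)
values.  Two pulse-duration scenarios are built in: $\delta = 16.5$ ms
(the clinical sequence) and $\delta = 4$ ms (a high-performance-gradient
surrogate); $\Delta$ and b are unchanged.

The pulse-width bias itself is cleanest at zero noise: long pulses
weaken the apparent exchange signature (at equal parameters the
finite-pulse signal decays less steeply with $\Delta$ than the
narrow-pulse solution — 6.4% vs 7.1% over the protocol's $\Delta$ range
at b = 2 for mid-range parameters), so a NEXI fit of SMEX signals
compensates with a longer $t_{ex}$ (+15–20%) and higher $D_i$, and a
lower $f$; this is a robust global minimum (multi-start verified) and
shrinks roughly in proportion to $\delta$.  At clinical noise levels a
second, larger effect superposes: the poorly identified parameters
($t_{ex}$, $D_i$) scatter across their box bounds, and clipping plus
regression dilution dominate the *mean* bias — its sign then depends on
the noise scale and on where the truth distribution sits relative to
the bounds (e.g. $D_i \in [2.5, 3.5]$ abuts the 3.5 bound, dragging its
mean estimate down).  Mean-bias signs from such studies should therefore
be read as properties of the (σ, truth-range, bounds) configuration,
not of the estimator alone.  Robust across configurations: $t_{ex}$
accuracy degrades as the true value approaches the longest sampled
diffusion time (~60 ms), and $t_{ex}$ and $D_i$ carry the largest
normalized uncertainty.

**Problem sizes.** The package's default study size is 500 voxels
(spec'd down from the 10,000-voxel scale of a full study; the estimator
properties asserted — bias signs, orderings, RMSE orderings — are
stable at this size).  The test suite runs the NEXI arms at 500 voxels
and the NEXI-vs-SMEX bias comparison at 200 voxels; noiseless recovery
uses 100 draws per model.  All randomness flows from explicit seeds and
every dataset is bit-reproducible.

### What the generator does and does not emulate

The generator reproduces the signal model, the direction-averaged Rician
magnitude noise, and the b0 normalization.  It does **not** emulate
spatially correlated noise, partial volume effects with white matter or
CSF, denoising residuals, motion/eddy/distortion artifacts, or
orientation dispersion beyond the powder average.  Passing recovery
tests therefore demonstrate estimator behaviour under the model's own
assumptions, not robustness to those real-data effects.

## Analysis tools

* `powder_average()` collapses a 4D acquisition to per-voxel shell
  curves (arithmetic mean over directions, per-$\Delta$ b0
  normalization).
* `slope_test()` regresses signal on diffusion time at fixed b — the
  exchange signature is a negative slope (restriction would give a
  positive one).  The p-value is reported two-sided; a one-sided claim
  of decrease corresponds to `slope < 0 & p/2 < level`.
* `mode_hdi()` summarizes ROI-mean distributions by the mode of a
  Gaussian-kernel density (Silverman's rule-of-thumb bandwidth, 512-grid)
  and the smallest density-superlevel interval holding the requested
  mass — an HDI "integrated around the mode", which is the natural
  summary for the skewed, heavy-tailed parameter distributions these
  fits produce.
* `repeatability()` contrasts intra-subject (scan–rescan) against
  inter-subject ROI-mean differences and correlations; correlations are
  pooled over (subject, ROI) pairs rather than averaged per subject —
  the pooled variant is the more stable with ~10 subjects and is the
  convention adopted here.  Paired Wilcoxon signed-rank tests compare
  two methods' difference distributions.
* `correlate_roi_maps()` computes subject-averaged ROI-level Pearson
  correlations between any two maps (e.g. exchange time against myelin
  water fraction).  ROI means use no outlier exclusion by default;
  median aggregation is available behind the `robust` flag.

## Known limitations

* The NEXI objective surface is multi-modal at clinical SNR: a minority
  of noiseless fits (about 10% of flat-range draws) converge to a
  secondary basin, typically flagged `at_bound`.  The grid initializer
  controls, but does not eliminate, this; multi-start fitting would,
  at proportional cost.
* $\sigma$ is an input: noise estimation (e.g. MP-PCA) and correlated
  noise are out of scope.
* Preprocessing (denoising, Gibbs, distortion/eddy), segmentation and
  surface projection are expected to happen upstream; ROI label images
  and lookup tables are consumed as-is.
* The first-order exchange correction makes the no-exchange closed form
  accurate only to $\mathcal{O}(t_d/t_{ex})$ — at $t_{ex} = 10^6$ ms
  that is $\approx 2\times10^{-6}$ on the worst shell, which is the
  physics, not numerics (the deviation scales exactly as $1/t_{ex}$).
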