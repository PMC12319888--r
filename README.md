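# gmexi

Gray-matter microstructure mapping from multi-shell, multi-diffusion-time
diffusion MRI with two-compartment exchange models, built for
clinical-scanner protocols.

## The problem

In cortical gray matter, water exchanges between neurites and the
extra-cellular space on a time scale of tens of milliseconds, and the
diffusion-weighted signal decreases with diffusion time at fixed b — the
*exchange signature*. Two-compartment exchange models turn that
time-dependence into biophysical parameters:

- `t_ex` — inter-compartment exchange time (ms), a proxy for membrane
  permeability (and, indirectly, myelination),
- `D_i` — intra-neurite (stick) diffusivity (µm²/ms),
- `D_e` — extra-neurite isotropic diffusivity (µm²/ms),
- `f` — intra-neurite signal fraction.

The per-direction signal solves the Kärger rate equation
`dM/dt = (R − k(t)² D) M` with exchange matrix
`R = [[−k_ie, k_ei], [k_ie, −k_ei]]`, `k_ie = (1−f)/t_ex`,
`k_ei = f/t_ex`, `D = diag(D_i u², D_e)`; the measured signal is the
powder average `S̄(b, t_d) = ∫₀¹ K(u) du`.

Two variants share these parameters and differ only in pulse handling:

- **NEXI** (narrow-pulse): gradients treated as instantaneous,
  `K = 1ᵀ exp[(R − q²D) t_d] (f, 1−f)ᵀ`, with `t_d = Δ − δ/3` and
  `q = √(b/t_d)` — fast, analytic, valid for short pulses.
- **SMEX** (finite-pulse): the rate equation is integrated through the
  actual rectangular PGSE waveform (adaptive RK45 on the two gradient
  ramps, analytic matrix-exponential propagator on the plateau) — the
  faithful model when δ is long, as on clinical scanners (δ = 16.5 ms in
  the built-in protocol).

Estimation is Rician-floor-corrected bounded nonlinear least squares: the
model prediction is passed through the Rician expectation
`E[S] = σ√(π/2)·L₁/₂(−S²/2σ²)` before residuals are formed, a grid search
(with the `D_i > D_e` soft constraint) supplies the starting point, and
L-BFGS-B (tolerance 1e-14) refines it within bounds
`t_ex ∈ [1,150]` ms, diffusivities `∈ [0.1, 3.5]` µm²/ms, `f ∈ [0.1,0.9]`.
Model comparison uses AICc. A synthetic noise-propagation study
quantifies estimator bias/precision, and ROI-level tools cover the
exchange-signature slope test, mode + highest-density-interval summaries,
scan–rescan repeatability and cross-map correlations.

The package is aimed at diffusion-MRI researchers who want to fit NEXI /
SMEX on clinical-protocol data (4D NIfTI + acquisition table + mask +
noise map) or study estimator behaviour in simulation.

## Worked example

```r
library(gmexi)

proto <- clinical_protocol()     # b = {1,2}@Δ={28.3,36}; {1,2,3.2,4.44}@45;
count_volumes(proto)             # {1,2,3.2,5}@{55,65}; δ = 16.5 ms
#> [1] 325

truth <- tissue_params(t_ex = 30, D_i = 3, D_e = 1, f = 0.4)
curve <- smex_signal(truth, proto)           # finite-pulse forward signal
round(curve[proto$Delta == 45], 4)
#> [1] 1.0000 0.4115 0.2052 0.1117 0.0738

# fit the wide-pulse signal with both variants
fit_smex <- fit_curve(curve, noise_model(0), "smex", protocol = proto)
fit_smex$params
#>  t_ex   D_i   D_e     f
#>  30.0   3.0   1.0   0.4

fit_nexi <- fit_curve(curve, noise_model(0), "nexi", protocol = proto)
round(fit_nexi$params, 3)
#>   t_ex    D_i    D_e      f
#> 33.674  3.149  0.978  0.384
```

SMEX recovers its own signal exactly; fitting the same wide-pulse signal
with the narrow-pulse NEXI model biases every parameter: long pulses
weaken the apparent exchange signature (the finite-pulse signal decays
less steeply with Δ than the narrow-pulse solution at equal parameters),
so NEXI compensates with a longer `t_ex` (33.7 vs 30 ms) and higher
`D_i`, and a lower `f` — the pulse-width bias that makes the
finite-pulse variant the appropriate choice for clinical protocols.

The exchange signature at b = 2 ms/µm² across the five diffusion times:

```r
p2 <- acq_protocol(rep(2, 5), c(28.3, 36, 45, 55, 65), 16.5, 20)
slope_test(nexi_signal(truth, p2), c(28.3, 36, 45, 55, 65))[c("slope", "p_value")]
#> $slope
#> [1] -0.0003587387
#> $p_value
#> [1] 0.0002061117
```

Voxelwise fitting of an image (`fit_volume()`) takes a 4D array/NIfTI, a
per-volume acquisition table, a mask and a σ map, and returns 3D maps of
the four parameters plus rss/AICc; `inst/cli/gmexi` wraps `fit`,
`simulate` and `summarize` for shell use.

## Layout

- `R/`, `src/` — protocol handling, forward models (Rcpp core), Rician
  noise, fitting, synthetic study, ROI analyses
- `tests/testthat/` — unit, property and acceptance tests
- `vignettes/exchange-models.Rmd` — model, numerics and design notes
- `inst/cli/gmexi` — command-line wrapper
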