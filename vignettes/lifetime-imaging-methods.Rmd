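---
title: "Methods: positronium lifetime imaging from three-photon events"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: positronium lifetime imaging from three-photon events}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pslife)
```

## The measurement

When a positron annihilates in tissue it can do so directly, or via the
positronium bound states: para-positronium (pPs, τ₁ ≈ 125 ps) or
ortho-positronium (oPs). The oPs vacuum lifetime of 142 ns collapses to
the nanosecond range in matter through pick-off annihilation, and the
observed lifetime τ₃ depends on the electron density and dissolved-gas
content of the micro-environment — the quantity this package images.

¹²⁴I provides the clock: 12.0% of its positron decays are accompanied by
a 602.73 keV de-excitation photon emitted essentially at decay time.
A *three-photon event* (3γE) is two singles in the annihilation energy
window [460, 545] keV plus one in the prompt window [568, 639] keV, in
time coincidence. The annihilation vertex comes from the time-of-flight
difference of the pair alone (no tomographic reconstruction), and the
annihilation-minus-prompt emission-time difference Δt, corrected for all
three flight paths through that vertex, is an unbiased draw from the
annihilation-delay distribution convolved with the timing response.

## Spectrum model and priors

A voxel's (or tube's) binned Δt spectrum is modelled as

$$\mu_i = b + N\,w \sum_{k=1}^{3} BR_k\, f(t_i;\tau_k,\sigma,\Delta),
\qquad
f(t;\tau,\sigma,\Delta) = \frac{1}{2\tau}
  e^{\sigma^2/2\tau^2-(t-\Delta)/\tau}
  \operatorname{erfc}\!\Big(\tfrac{\sigma/\tau-(t-\Delta)/\sigma}{\sqrt2}\Big),$$

the exponentially modified Gaussian with bin width $w$ = 133 ps. The
short components are fixed (τ₁ = 125 ps, τ₂ = 388 ps), as is the flat
background $b$, estimated as the mean bin content at Δt < −2.5 ns, where
no physical delay can contribute. The fit range is [−2, 8] ns. Priors:

| parameter | prior | units | note |
|---|---|---|---|
| τ₃ | N(1.78, 0.8), truncated at 0 | ns | lifetimes are physical |
| BR₁..₃ | Dirichlet(0.75, 3.1, 1.15) | — | mean (0.15, 0.62, 0.23) |
| σ | N(0.1, 0.05), truncated at 0 | ns | timing resolution |
| Δ | N(0, 0.5) | ns | global time offset |
| N | N(A, 0.1·A) | counts | A = Σ(yᵢ − b) over the fit range |

The likelihood is Gaussian per bin. The noise scale is not stated by the
model itself, so we use $s_i = \sqrt{\max(\mu_i, 1)}$ — the Gaussian
approximation to Poisson counting noise, floored at one count to avoid
degenerate zero-variance bins. Histograms with $A \le 0$ are marked
unfittable (the N prior would be degenerate) and masked.

## Posterior sampling

The sampler is an adaptive Metropolis scheme on an unconstrained
parameterization: log τ₃, log σ, the additive-log-ratio transform of the
branching simplex (with its $\prod_k BR_k$ Jacobian), Δ, and N/A. Each
chain starts near the posterior mode found by BFGS, with a proposal
shaped by the local inverse Hessian (Laplace approximation). Moves are a
mixture of random-walk steps — global scale tuned towards 30% acceptance
during warmup, covariance re-estimated from the first warmup half — and,
with probability 0.2, Metropolized independence draws from a
multivariate-t version of the Laplace approximation, re-centred on the
warmup draws. Defaults are 4 chains × 1000 warmup + 1000 kept draws with
thinning 5.

Convergence is declared only when the maximum split-R̂ over parameters is
below 1.01 *and* the minimum Geyer effective sample size exceeds 400;
whole-spectrum fits pass this comfortably, while at single-voxel
statistics the weakly identified early-peak nuisance directions
(BR₁/BR₂/σ/Δ trade off against each other) occasionally leave a fit
flagged. τ₃ and BR₃ themselves mix well in all regimes. Non-converged
voxels are reported and excluded from maps by default
(`include_nonconverged = TRUE` keeps them). Point estimates are
posterior means; τ₃ uncertainty is the posterior SD (the posterior is
close to Gaussian); branching fractions get 68% highest-density
intervals, computed as the shortest window over sorted draws.

## What the simulator emulates — and what it does not

`sample_decays()` + `emit_and_detect()` generate ¹²⁴I positron decays in
cylindrical tubes (defaults: the four XAD4 reference samples, ~5 ml,
1.12–1.44 MBq, lifetimes 2.52/2.37/2.27/1.82 ns), draw the annihilation
channel from the material's branching fractions and its delay from the
corresponding exponential, and transport the back-to-back 511 keV pair
and the optional prompt photon to an idealized barrel detector
(radius 410 mm, axial half-length 530 mm). Detection applies a Gaussian
per-photon timing smear (default 95 ps, so the pair difference σ is
~134 ps, matching the 133 ps bin width) and a Gaussian energy smear
scaling as √E from an 11% FWHM at 511 keV. Electron-capture decays are
not generated; the prompt probability of 0.12 is *per positron*.

Random coincidences are a real annihilation pair plus an uncorrelated
prompt: their vertices follow the activity distribution while Δt is
uninformative. `inject_randoms()` therefore emits the pair from an
activity-weighted tube position and back-solves the prompt detection
time, through the same TOF arithmetic the selection applies, so that the
analysis Δt is exactly uniform on a stated window ([−6, 9] ns by
default, covering the histogram with margin). This is a deliberate
engineering of the flat background the background estimator assumes; its
flatness is verified *through* the selection pipeline, not assumed.

Not modelled: positron range and photon acollinearity (the analysis does
not model them either; they only blur localization), Compton scatter in
the object, attenuation, detector dead time, and crystal granularity.
Passing recovery tests therefore demonstrates the correctness of the
estimation chain under its own assumptions, not robustness to these
real-data effects.

Two fast paths bypass photon transport for statistics-hungry studies:
`sample_tdd_direct()` draws spectrum values directly (delay plus
N(Δ, σ) noise, uniform background), and `sample_events_direct()` draws
selected-event tables with the analytically derived localization blur —
σ_loc = (c/2)·√2·σ_t ≈ 20 mm along an isotropic line-of-response
direction — and Δt noise √(5/3)·σ_t (the three smeared detection times
propagated through the vertex correction, averaged over prompt
directions). These reproduce the distributions the full chain produces
at the precision the fits resolve, at ~100× the speed.

## Numerical choices

* **erfc stability.** The EMG is evaluated in log space through
  `pnorm(..., log.p = TRUE)`; no overflow for σ/τ ∈ [10⁻³, 10] and
  |t| ≤ 50 ns. Agreement with direct quadrature of the convolution is
  below 10⁻⁸ relative wherever the density exceeds quadrature underflow.
* **Bin integral.** Expected counts use the midpoint density × width by
  default. The relative bin-curvature error is (w²/24)/τ² per
  exponential component — ~2×10⁻⁴ for the τ₃ tail at 133 ps bins, a few
  10⁻³ where the direct component still contributes; on the steep
  Gaussian rise it reaches a few tens of percent of the bin value and is
  absorbed by the free σ and Δ (the fitted σ comes out ~5% above the
  generative value; τ₃ recovery is unbiased in the suite's tests). A
  5-point Gauss–Legendre bin mean is available via
  `model_expectation(..., method = "integral")`.
* **Histogram extent.** Bins of 133 ps start at −5 ns; 97 bins end at
  7.901 ns. The fit uses bins with centers in [−2, 8] ns (74 bins); the
  background region below −2.5 ns holds 19 bins. The extent below the
  fit range exists precisely to estimate b.
* **Background relative error.** Defined as the standard error of the
  mean over background bins divided by the mean — the natural, testable
  reading of "relative error in the background region". QC passes at
  strictly < 20%; b = 0 gives an infinite error and fails.
* **Conventions.** Energy windows are closed intervals; voxels and time
  bins are half-open (boundary values go up); coincidence clusters are
  greedy from the first record with a 15 ns window (wide enough for the
  full fitted Δt range plus flight-time spreads); clusters with extra
  in-window photons are discarded as ambiguous, which keeps counts
  bit-reproducible at the cost of a few percent efficiency.
* **Grids.** Axis-aligned, cubic voxels, origin centring the phantom
  bounding box plus margin; each voxel size is an independent binning of
  the vertices, never a resampling of a finer grid.
* **Seeds.** One seed drives a run; per-voxel fits derive chain seeds
  deterministically from (seed, voxel linear index), so images are
  reproducible while voxel chains stay independent.

## Problem sizes used by the validation suite

Counts are chosen by matching posterior uncertainty, since detected
event counts per tube are otherwise unconstrained: whole-sample
recovery uses 4×10⁵ signal events over a ~10% background (posterior SD
≈ 0.02 ns); single-voxel recovery uses 5×10³ (SD ≈ 0.15 ns); HDI
calibration uses 50 replicates at the voxel regime. The four-tube
ordering study generates 1.6×10⁸ vertex-level events (20 seeded chunks),
keeps the central axial slab, and fits the 4 mm voxel row through the
tube centres, giving central-voxel SDs of ~0.03 ns so that the strict
lifetime ordering dry > wet > gelatine > water is resolved. The
noiseless flight-time-cancellation check runs at low activity
(0.1 MBq/tube for 2 ms) so triples are isolated in time and absolute
times stay small enough for 10⁻⁹ ns float accuracy.

## Limitations

The Gaussian likelihood under-weights nearly empty bins relative to a
Poisson treatment; with the 133 ps binning and the count regimes above
this is immaterial, but fits of extremely sparse voxels should use
coarser spatial binning instead. The discard rule for ambiguous
clusters makes selection efficiency rate-dependent at high pile-up.
Window-shrinkage monotonicity of the accepted-event count is exact for
isolated triples but can be violated by pile-up clusters whose
multiplicity classification changes. The simulator's detector is a
continuous barrel: spatial resolution effects of finite crystals are
folded into the timing smear only.
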