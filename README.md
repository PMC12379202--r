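# pslife — voxel-wise ortho-positronium lifetime imaging for three-photon PET

`pslife` implements the analysis chain for **ortho-positronium (oPs)
lifetime imaging** on a long-axial-field-of-view PET scanner with a
prompt-gamma emitter such as ¹²⁴I, together with a synthetic phantom and
scanner simulator so that every stage can be validated by parameter
recovery without access to scanner data.

Positronium forms in tissue in a quarter of positron annihilations; the
spin-1 state (oPs) has a vacuum lifetime of ~142 ns that is shortened to
the 1.8–2.6 ns range by pick-off annihilation with environmental
electrons, making the observed lifetime τ₃ a probe of the local
micro-environment (e.g. oxygen tension). ¹²⁴I emits a 602.73 keV prompt
photon in 12.0% of its positron decays; detecting the prompt together
with the two 511 keV annihilation photons (a *three-photon event*, 3γE)
starts and stops a per-decay clock.

The pipeline, per stage:

1. **Event selection** — from a time-sorted singles table, coincidence
   clusters containing exactly two photons in the annihilation energy
   window [460, 545] keV and exactly one in the prompt window
   [568, 639] keV form a 3γE.
2. **TOF localization** — the annihilation vertex is placed on the line
   of response at `midpoint − (c/2)(t_B − t_A)·û`; there is no
   tomographic reconstruction. The vertex-corrected
   annihilation-minus-prompt time difference Δt equals the positron's
   annihilation delay, up to timing resolution.
3. **Histoimaging** — vertices are binned into voxel grids (10.0³, 7.1³
   or 4.0³ mm³); each voxel's Δt values form a time-difference
   distribution (TDD) with 133 ps bins. The flat background *b* is fixed
   to the mean bin content below −2.5 ns, and voxels whose background
   relative error is ≥ 20% are rejected.
4. **Bayesian lifetime fit** — the TDD model is a Gaussian resolution
   function convolved with three exponential components (pPs, direct,
   oPs):

   μᵢ = b + N·w·Σₖ BRₖ · (1/2τₖ) exp(σ²/2τₖ² − (tᵢ−Δ)/τₖ) erfc[(σ/τₖ − (tᵢ−Δ)/σ)/√2]

   with τ₁ = 125 ps and τ₂ = 388 ps fixed, and priors
   τ₃ ~ N(1.78, 0.8) ns, (BR₁,BR₂,BR₃) ~ Dirichlet(0.75, 3.1, 1.15),
   σ ~ N(0.1, 0.05) ns, Δ ~ N(0, 0.5) ns, N ~ N(A, 0.1·A) with
   A = Σ(yᵢ − b) over the fit range [−2, 8] ns, under a Gaussian
   likelihood. Posterior sampling is by adaptive MCMC; τ₃ is reported as
   posterior mean ± SD and branching fractions with 68% highest-density
   intervals.
5. **Imaging** — per-voxel τ₃, relative-uncertainty and BR₃ maps with QC
   masks, NIfTI output, slices and maximum intensity projections. No
   smoothing or post-processing is ever applied.

The simulator generates ¹²⁴I decays in cylindrical tube phantoms (the
four XAD4/water reference samples are built in), transports photons to
an idealized cylindrical detector with Gaussian timing and energy smear,
and injects random coincidences that are flat in Δt. Faster vertex-level
and spectrum-level sampling paths (`sample_events_direct()`,
`sample_tdd_direct()`) support high-statistics recovery studies.

## Worked example

Fit a synthetic whole-tube spectrum generated with the water-sample
ground truth (τ₃ = 1.82 ns, BR = 0.088/0.644/0.268, σ = 0.12 ns, 10⁵
signal events over a ~10% flat background):

```r
library(pslife)
br <- c(0.088, 0.644, 0.268)            # pPs, direct, oPs fractions
dt <- sample_tdd_direct(tau3 = 1.82, br = br, sigma = 0.12,
                        n_signal = 1e5, n_background = 11000, seed = 42)
tdd <- estimate_background(build_tdd(dt))
tdd
#> <tdd> 97 bins of 133 ps over [-5, 7.901) ns, 110556 events; background b = 113/bin (rel err 2.2%, QC pass)
fit <- fit_tdd(tdd, seed = 1)
fit
#> <pslife_fit> tau3 = 1.811 +/- 0.032 ns | BR3 = 0.267 [0.263, 0.271]
#>   sigma = 0.125 ns, delta = -0.002 ns, N = 99943 (A = 99608)
#>   rhat_max = 1.002, ess_min = 1404, converged: yes
tidy(fit)
#> # A tibble: 7 × 5
#>   term       estimate std.error    conf.low     conf.high
#> 1 tau3        1.81      0.0323      1.78         1.84
#> 2 br1         0.0770    0.0113      0.0665       0.0886
#> 3 br2         0.656     0.0136      0.642        0.669
#> 4 br3         0.267     0.00416     0.263        0.271
#> ...
```

The posterior mean recovers the generative lifetime within one standard
deviation, and the oPs branching fraction to three decimals;
`autoplot(tdd, fit = fit)` overlays the fitted expectation on the
spectrum. A full image is one call: `run_pipeline()` chains simulation,
selection, voxelization and per-voxel fitting into a `lifetime_image`
(NIfTI-exportable via `write_image()`, visualized with `autoplot()` and
`plot_mip()`).

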