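# frckit

Spectral decomposition of cooperative adsorption kinetics from QCM-D
records.

Quartz crystal microbalance with dissipation monitoring (QCM-D) reports
biomolecular adsorption as a time-resolved frequency shift Δf(t) at several
overtones of the sensor's resonance. For self-assembling systems such as
solid-binding peptides (e.g. the gold binder AuBP1, WAGAKRLVLRRE), a single
non-cooperative rate constant — the Langmuir observable A·(1 − e^(−k·t)) —
cannot describe the record: adsorption proceeds through several cooperative
processes with growth and convergence phases at different rates. `frckit`
is for experimentalists and modelers who want to resolve those processes
instead of averaging over them.

The core model represents the baseline-zeroed curve −Δf(t) as a sum of
sigmoidal components pinned to a log-spaced grid of apparent rate
constants:

    Δf(t) = Σᵢ Δf∞,ᵢ / (1 + exp(−k_obs,ᵢ (t − Δtᵢ))) − Δf_vs,ᵢ

with per-component amplitude Δf∞,ᵢ (Hz), fixed grid rate k_obs,ᵢ (s⁻¹),
inflection time Δtᵢ (s), and vertical shift Δf_vs,ᵢ (Hz). The fitted
amplitudes over log₁₀ k_obs form a **kinetic spectrum** — how strongly each
rate band contributes — which is then deconvolved into Gaussian peaks to
separate overlapping assembly events. Concentration-dependent equilibrium
responses are summarized by the Hill isotherm (linearized as
ln(θ/(1−θ)) = n·ln C + ln K′), giving the cooperativity constant n, the
equilibrium constant K_eq (M⁻¹), and the binding free energy
ΔG = −RT·ln K_eq.

The package covers the full workflow: delimited-text run I/O, dissipation
quality filtering (strict 0.5×10⁻⁶ excursion bound), 5th/7th/9th-overtone
averaging, minimum-RMSD representative-replicate selection, two-stage
spectral fitting (nonnegative rough scaling, then bounded
Levenberg–Marquardt refinement with near-zero scalings acting as component
on/off switches), spectrum export (`log_k_obs` / `curve_weight` columns),
BIC-guided Gaussian deconvolution, Hill/free-energy analysis, a peptide
average-mass identity check, and a seeded synthetic-data generator with
known ground truth.

## Worked example

Simulate a two-process run — a slow 12 Hz process (k = 2.1×10⁻³ s⁻¹) and a
fast 8 Hz process (k = 0.15 s⁻¹) — with 0.1 Hz sensor noise, then recover
the spectrum:

```r
library(frckit)

truth <- list(sigmoid_component(12, 2.1e-3, t_shift = 475),
              sigmoid_component(8,  1.5e-1, t_shift = 7))
spec  <- synth_spec(truth, noise_sd = 0.1, t_span = 3600, dt = 1,
                    concentration = 0.25, seed = 1)
run   <- simulate_run(spec)
curve <- average_overtones(run)                 # -Δf, overtone-normalized
model <- fit_frc(curve, fit_config(k_min = 3e-5, k_max = 1))
model
#> <frc_model> 50 components on k_obs in [3e-05, 1] s^-1
#>   active components: 4
#>   asymptote: 14.68426 Hz
#>   fit RMSD: 0.009211166 Hz (converged: TRUE)

sp  <- extract_spectrum(model, concentration = 0.25)
dec <- deconvolve(sp)
dec
#> <deconvolution_result> 3 Gaussian peak(s), background: none
#>      center      width        area      height    shape
#>  -2.6962496 0.02307591 0.982041429 16.97778392 gaussian
#>  -0.8176798 0.02595524 0.591059764  9.08482352 gaussian
#>  -0.7692285 0.05929140 0.004195898  0.02823211 gaussian
#>   residual RMSD: 0.004798209 Hz

regime_fractions(sp, k_split = 1e-2)[c("slow", "fast")]
#> $slow
#> [1] 0.5958629
#> $fast
#> [1] 0.4041371
```

Reading the numbers: the fit reaches the noise floor of the
overtone-averaged curve (RMSD ≈ 0.009 Hz) with 4 active of 50 components.
The model asymptote (14.68 Hz) matches the observable plateau of the
baseline-zeroed truth; the total spectral weight (≈ 20.1 Hz) matches the
summed true process amplitudes (12 + 8 Hz), with the vertical shifts
absorbing the pre-zeroing onset offset. The two dominant deconvolved peaks
sit at log₁₀ k ≈ −2.70 and −0.82 — the true rates are at −2.68 and −0.82 —
and the slow/fast split quantifies what the spectrum shows: both regimes
contribute, the slow (thermodynamically driven) band slightly more.

Thermodynamic anchors:

```r
peptide_average_mass("WAGAKRLVLRRE")   # 1454.75 g/mol (AuBP1 identity check)
delta_g(1.06e6)                        # -8.22 kcal/mol at 298.15 K
```

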