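---
title: "Spectral decomposition of cooperative adsorption kinetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spectral decomposition of cooperative adsorption kinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(frckit)
```

## The problem

A quartz crystal microbalance with dissipation monitoring (QCM-D) reports
biomolecular adsorption as a negative shift in the resonance frequency of an
oscillating quartz sensor, recorded at several odd overtones of its
fundamental (here 5 MHz), together with a dissipation signal that reflects
the viscoelasticity of the growing film. For solid-binding peptides such as
the gold binder AuBP1 (WAGAKRLVLRRE), the adsorption record is rarely the
simple saturating exponential of non-cooperative (Langmuir) kinetics:
peptides interact with each other as well as with the surface, assemble in
stages, and reshape the binding energy landscape as coverage grows. The
observable consequence is a sigmoidal curve — a growth (lag) phase followed
by a convergence phase — or a superposition of several such processes with
different apparent rates.

`frckit` represents a baseline-zeroed adsorption curve $-\Delta f(t)$ as a
sum of cooperative sigmoidal components pinned to a log-spaced grid of
apparent rate constants:

$$
\Delta f(t) \;=\; \sum_{i=1}^{n}
  \frac{\Delta f_{\infty,i}}{1 + e^{-k_{\mathrm{obs},i}\,(t - \Delta t_i)}}
  \;-\; \Delta f_{\mathrm{vs},i},
$$

with, per component, an amplitude $\Delta f_{\infty,i} \ge 0$ (Hz), a fixed
grid rate $k_{\mathrm{obs},i}$ (s$^{-1}$), an inflection time $\Delta t_i$
(s) at which the process runs at maximum rate and has accumulated half its
final shift, and a vertical offset $\Delta f_{\mathrm{vs},i} \ge 0$ (Hz)
that moves the curve below the horizontal axis to absorb the
deflection-onset offset. The fitted amplitudes over $\log_{10}
k_{\mathrm{obs}}$ form a *kinetic spectrum*: instead of one rate per
experiment, the method reports how strongly each rate band contributes.
The non-cooperative contrast model, $A\,(1 - e^{-k t})$, has its maximum
rate at $t = 0$ and no growth phase; it is fitted alongside
(`langmuir_fit()`) to document what the spectral model adds. A sinusoidal
(discrete-Fourier) expansion of the record would instead describe it in
terms of oscillatory components; the sigmoid bank is used precisely because
adsorption processes are monotone with saturation, which sinusoids do not
capture term by term.

## Preprocessing

The reduction from raw multi-overtone records to analysis-ready curves
follows standard QCM-D practice:

* **Dissipation quality filter.** A run is kept when the maximum excursion
  of every overtone's dissipation from its initial value stays strictly
  below `0.5e-6` (natural, dimensionless scale). A wandering dissipation
  indicates instrumental drift or a soft film for which the rigid-film
  reading of $\Delta f$ fails. "Steady dissipation" is operationalized as
  this single excursion bound: one number, testable, and subsuming
  "steady" for any reasonable reading. Runs without dissipation data
  cannot be vetted and are excluded with a warning.
* **Overtone averaging.** The 5th, 7th and 9th overtone shifts are averaged
  pointwise after dividing each by its overtone index (the usual
  normalization that puts harmonics on a common scale; raw averaging is
  available via `normalize_by_overtone = FALSE`), negated so adsorption
  rises, and baseline-zeroed at the first sample (an explicit injection
  baseline can be imposed upstream by trimming).
* **Representative replicate.** For each concentration the replicate with
  the smallest root-mean-square deviation from the pointwise mean curve is
  selected; ties break lexicographically by run id. Replicates on
  different clocks are linearly resampled to the coarsest common grid
  first — instrument clocks drift, and linear interpolation at
  $\sim$1 s spacing introduces errors far below the sensor noise.

## Fitting: rough scaling, bounded refinement, pruning

The fit is deliberately two-stage.

**Stage 1 (rough).** Rates are fixed to the grid (default 50 components,
user definable; default limits $1/(10\,t_{\mathrm{span}})$ to
$10/\Delta t_{\mathrm{sample}}$, the window of rates the record can
resolve). Inflection times start at each component's characteristic time
$1/k_{\mathrm{obs},i}$, plus a global delay offset found by a coarse scan
(25 candidates over the first third of the record, evaluated by nonnegative
least squares on a thinned copy of the curve). The offset matters: a
delayed process initialized without it leaves the optimizer at a saddle,
because a component with zero amplitude has zero gradient in its misplaced
inflection time. Amplitudes are then scaled by nonnegative least squares
of the fixed-shape sigmoid bank against the curve. Three numerical details:

* the basis carries one extra nonnegative *global-offset* column, because
  every sigmoid is strictly positive at $t = 0$ while the curve is zeroed
  there; the fitted offset seeds the vertical shifts, apportioned across
  components in proportion to amplitude;
* a small ridge penalty (`1e-8` relative to the largest basis column norm)
  stabilizes the near-collinear bank — neighboring grid sigmoids are
  almost parallel;
* the ridge bias is then removed by an exact least-squares polish on the
  NNLS-selected support, kept only when it stays feasible. On noise-free
  on-grid inputs this makes the rough fit exact to machine precision.

**Stage 2 (refine).** Amplitudes, inflection times and vertical shifts are
refined jointly by Levenberg–Marquardt least squares with an analytic
Jacobian under box bounds — amplitudes in $[0,\, 2\max|y|]$, inflection
times within the record (the lower bound is configurable to negative values
for processes already mid-flight at injection), vertical shifts in the
amplitude box. Rates stay pinned to the grid: freeing them would destroy
the spectral reading of the amplitudes. Because each vertical shift enters
the prediction only through the model-wide sum, the objective has flat
directions along which step-based stopping criteria never fire; refinement
therefore runs in rounds of 25 iterations and stops when the relative RMSD
improvement per round falls below `stall_tol` (default `1e-4`), or at
`maxiter` (default 200) with a warning. The refined RMSD never exceeds the
initial RMSD.

**Stage 3 (prune).** Components whose amplitude falls strictly below
`prune_eps` (default `1e-3`) times the largest amplitude are switched off
exactly — the rough scaling acting as a logical switch. Their vertical
shifts are transferred to the largest surviving component (the sum is all
that the prediction sees), so pruning changes the prediction by at most the
pruned amplitude total and leaves the asymptote untouched.

The pipeline is deterministic: no randomness enters the fit, and re-running
with the same curve and configuration reproduces the model bit for bit.

## Peak deconvolution

The kinetic spectrum is itself a curve — weight versus
$\log_{10} k_{\mathrm{obs}}$ — whose overlapping, asymmetric humps mix
distinct assembly events. `deconvolve()` fits it as a sum of Gaussians in
log-rate space plus an optional flat or linear background, by bounded least
squares. With `n_peaks = "auto"`, peaks are added greedily at the largest
positive residual until the Bayesian information criterion stops improving,
which makes "add components until the deconvolution is optimal"
reproducible. Gaussians in $\log_{10} k$ are the simplest symmetric shape;
an asymmetric band simply resolves into more than one Gaussian. The
XPS-specific Tougaard background of electron spectroscopy software has no
physical meaning for kinetic spectra and is deliberately not offered; the
default background is none. `regime_fractions()` reports the slow/fast
weight split at a user-chosen rate threshold (default: the geometric
midpoint of the grid) — a reporting device, not a fitted quantity.

## Cooperativity and thermodynamics

Equilibrium responses $\Delta f_{\mathrm{eq}}(C)$ across concentrations are
summarized by the Hill isotherm. With occupancy
$\theta = \Delta f_{\mathrm{eq}} / f_{\max}$, ordinary least squares on the
linearization

$$
\ln\!\frac{\theta}{1-\theta} \;=\; n \ln C + \ln K'
$$

gives the cooperativity constant $n$ as the slope ($n<1$: negative
cooperativity — bound peptides slow further binding; $n>1$: positive;
$n=1$: the Langmuir limit) and the equilibrium constant as
$K_{\mathrm{eq}} = (K')^{1/n}$ in M$^{-1}$ (concentrations are converted to
molar before any logarithm). Points with $\theta$ outside $(0,1)$ are
excluded with a warning; fewer than three usable points is an error. When
$f_{\max}$ is not known it is profiled: a 1-D search maximizes the linear
fit's $R^2$ — on noise-free Hill data this recovers the generating
$f_{\max}$ because only the true value linearizes the plot exactly. The
binding free energy is $\Delta G = -RT\ln K_{\mathrm{eq}}$ with
$R = 1.987\times 10^{-3}$ kcal mol$^{-1}$ K$^{-1}$ and a default
$T = 298.15$ K, always reported with the temperature used. Equilibrium
plateaus are read as the mean over the final 10 % of samples, flagged "not
converged" when the tail slope exceeds 1 % of the response range per 100 s.

The peptide identity check, `peptide_average_mass()`, sums standard average
residue masses plus one water — the quantity ESI-MS reports for an
unmodified linear peptide; AuBP1 evaluates to 1454.75 g/mol.

## The synthetic-data generator

Every quantitative claim in the test suite is made against data with known
ground truth from `simulate_run()` and
`simulate_concentration_series()`. A simulated run stores, per overtone
$n$, $\Delta f_n(t) = -s_n \cdot \mathrm{truth}(t) + \varepsilon(t)$ with
the raw negative-going sign convention, $s_n$ defaulting to the overtone
index (so overtone-normalized averaging recovers the truth exactly), and
$\varepsilon$ iid Gaussian noise (optionally AR(1)-correlated with the
marginal standard deviation preserved); dissipation is a linear drift plus
noise. Concentration series scale a base component set so total amplitude
follows a Hill isotherm, and return the exact occupancies used.

What the generator emulates: the multi-overtone record structure, additive
sensor noise, dissipation drift, sigmoidal multi-process kinetics, and
Hill-structured equilibria. What it does not: viscoelastic coupling between
film and dissipation, solution-phase aggregation and depletion, flow and
injection transients, temperature drifts of the resonance. Passing
closed-loop tests therefore demonstrates that the estimator recovers the
model class it assumes under realistic noise — not that real peptide data
obey that class; on instrument data the spectrum is a description, and its
peaks hypotheses.

Default study conditions in the tests and acceptance script mirror the
measurement design the package targets: records of about an hour sampled
once per second ($t_{\mathrm{span}} = 3600$ s, $\Delta t = 1$ s), a
50-component grid spanning $3\times10^{-5}$–$1$ s$^{-1}$, sensor noise
$\sigma = 0.1$ Hz, component amplitudes of 8–25 Hz ($\ge 20\sigma$),
ground-truth inflection times at each component's characteristic time
$1/k_{\mathrm{obs}}$, eight concentrations spanning 0.05–0.75 µM, and 2 %
multiplicative noise on equilibrium occupancies with 100 replicates for
the Hill recovery study. Unit tests use shorter records (1201 samples, 30
components on $10^{-3}$–$1$ s$^{-1}$), which resolve the same contracts at
a fraction of the cost.

## Numerical choices and degenerate inputs

* Logistic evaluation goes through `plogis`, which saturates cleanly far
  from the inflection; components remain finite for any finite time.
* A zero curve yields an all-zero model (NNLS of a zero target), a zero
  spectrum refuses deconvolution, and a zero total weight refuses regime
  fractions — each with a specific error.
* Records shorter than two samples per component proceed with a warning:
  the ridge keeps the rough system well-posed, but the result is
  underdetermined.
* The baseline-zeroed observable cannot distinguish the pre-zeroing level:
  fits are compared against the *zeroed* truth asymptote
  (truth limit minus truth at $t=0$), which is what the data contain.
* Run files are written at 15 significant digits (round-trip error below
  $10^{-12}$ relative); model JSON uses 17 significant digits, which
  round-trips doubles exactly.
* Ties: representative selection breaks RMSD ties lexicographically by run
  id; spectral plateaus report their left-most index as the peak.

## Limitations

The spectral reading is only as fine as the grid, and neighboring sigmoids
are nearly collinear: weight localizes to within about one grid step, not
better, and a non-sigmoidal process (e.g., a pure Langmuir record, whose
maximum rate is at $t=0$) is represented as a band of components around
its rate rather than a single line. Amplitude uncertainty is not
quantified — a bootstrap over replicates would be the natural extension.
The Hill analysis uses equilibrium plateaus; if a record has not converged
the plateau estimate flags it, but the fit does not model the approach to
equilibrium. Conversion of frequency shifts to adsorbed mass (Sauerbrey or
viscoelastic) is out of scope.
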