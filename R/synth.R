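#' Specification for a synthetic QCM-D run
#'
#' Defines the ground truth and noise model for one simulated sensor run:
#' a set of sigmoidal kinetic components, the recorded overtones and their
#' raw-signal scaling, additive Gaussian (optionally AR(1)-correlated)
#' frequency noise, and a linear dissipation drift. The raw frequency shift
#' is stored negative-going (adsorption lowers resonance frequency), so the
#' preprocessing negation recovers a rising curve.
#'
#' @param components list of [sigmoid_component()] ground-truth processes.
#' @param overtones odd overtone indices recorded (default 5, 7, 9).
#' @param overtone_scale per-overtone multiplier on the raw shift; default
#'   the overtone index itself (raw shifts grow with harmonic number, so
#'   overtone-normalized averaging recovers the truth exactly).
#' @param noise_sd frequency-noise standard deviation (Hz).
#' @param ar1 AR(1) coefficient of the frequency noise in `[0, 1)`; 0 gives
#'   iid noise. The marginal standard deviation stays `noise_sd`.
#' @param diss_drift linear dissipation drift slope (1/s, natural scale).
#' @param diss_noise_sd dissipation noise standard deviation (natural
#'   scale).
#' @param t_span record length (s).
#' @param dt sampling interval (s).
#' @param concentration micromolar label, or `NA`.
#' @param run_id character label.
#' @param seed integer seed; the same spec and seed reproduce the run
#'   bit-identically.
#' @return Object of class `synth_spec`.
#' @export
synth_spec <- function(components, overtones = c(5, 7, 9),
                       overtone_scale = NULL, noise_sd = 0, ar1 = 0,
                       diss_drift = 0, diss_noise_sd = 0,
                       t_span = 3600, dt = 1,
                       concentration = NA_real_, run_id = "synth",
                       seed = NULL) {
  stopifnot(noise_sd >= 0, diss_noise_sd >= 0, dt > 0, t_span > 0,
            ar1 >= 0, ar1 < 1)
  if (inherits(components, "sigmoid_component")) {
    components <- list(components)
  }
  stopifnot(all(vapply(components, inherits, logical(1),
                       "sigmoid_component")))
  if (is.null(overtone_scale)) overtone_scale <- as.numeric(overtones)
  stopifnot(length(overtone_scale) == length(overtones))
  structure(list(components = components,
                 overtones = as.integer(overtones),
                 overtone_scale = as.numeric(overtone_scale),
                 noise_sd = noise_sd, ar1 = ar1,
                 diss_drift = diss_drift, diss_noise_sd = diss_noise_sd,
                 t_span = t_span, dt = dt,
                 concentration = as.numeric(concentration),
                 run_id = run_id, seed = seed),
            class = "synth_spec")
}

.truth_value <- function(components, t) {
  out <- numeric(length(t))
  for (cmp in components) out <- out + sigmoid_value(cmp, t)
  out
}

.noise_series <- function(n, sd, ar1) {
  if (sd == 0) return(numeric(n))
  w <- stats::rnorm(n, sd = sd)
  if (ar1 == 0) return(w)
  as.numeric(stats::filter(w * sqrt(1 - ar1^2), ar1,
                           method = "recursive"))
}

#' Simulate one multi-overtone QCM-D run
#'
#' Raw per-overtone shifts are
#' `delta f_n(t) = -scale_n * truth(t) + noise`, dissipation is
#' `delta D_n(t) = drift * t + noise_D`. Deterministic for a given spec and
#' seed. The noise-free ground-truth curve is attached as attribute
#' `"truth"`.
#'
#' @param spec a [synth_spec()].
#' @return An [adsorption_run()].
#' @export
simulate_run <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  t <- seq(0, spec$t_span, by = spec$dt)
  truth <- .truth_value(spec$components, t)
  freq <- list()
  diss <- list()
  for (i in seq_along(spec$overtones)) {
    key <- as.character(spec$overtones[i])
    freq[[key]] <- -spec$overtone_scale[i] * truth +
      .noise_series(length(t), spec$noise_sd, spec$ar1)
    diss[[key]] <- spec$diss_drift * t +
      .noise_series(length(t), spec$diss_noise_sd, 0)
  }
  run <- adsorption_run(run_id = spec$run_id, time = t, freq_shift = freq,
                        dissipation = diss,
                        concentration = spec$concentration)
  attr(run, "truth") <- truth
  run
}

#' Simulate a concentration series with Hill-structured equilibria
#'
#' Scales a base set of ground-truth components per concentration so that
#' the total amplitude follows a Hill isotherm,
#' `sum(amplitudes) = f_max * theta(C)` with
#' `theta = C^n / (K_d^n + C^n)`, then simulates one run per concentration.
#' Returns both the runs and the exact occupancies used, enabling
#' closed-loop recovery tests of the Hill analysis.
#'
#' @param base_components list of [sigmoid_component()]; relative amplitudes
#'   and time structure shared by all concentrations.
#' @param concentrations micromolar concentrations (one run each).
#' @param hill list with `n` (cooperativity), `K_d` (half-saturation
#'   concentration in molar) and `f_max` (saturation response, Hz).
#' @param seed integer seed; run `i` uses `seed + i`.
#' @param ... further arguments passed to [synth_spec()] (noise, sampling,
#'   overtones, ...).
#' @return List with `runs` (named by concentration label) and
#'   `equilibrium`, a data frame of `concentration` (micromolar), `theta`
#'   (exact occupancy) and `response` (`f_max * theta`, Hz).
#' @export
simulate_concentration_series <- function(base_components, concentrations,
                                          hill, seed = 1, ...) {
  stopifnot(all(c("n", "K_d", "f_max") %in% names(hill)),
            hill$n > 0, hill$K_d > 0, hill$f_max > 0,
            all(concentrations > 0))
  base_amp <- sum(vapply(base_components, `[[`, numeric(1), "amplitude"))
  stopifnot(base_amp > 0)
  C_M <- concentrations * 1e-6
  theta <- C_M^hill$n / (hill$K_d^hill$n + C_M^hill$n)
  runs <- list()
  for (i in seq_along(concentrations)) {
    s <- hill$f_max * theta[i] / base_amp
    comps <- lapply(base_components, function(cmp) {
      sigmoid_component(cmp$amplitude * s, cmp$k_obs, cmp$t_shift,
                        cmp$v_shift * s)
    })
    id <- sprintf("conc_%g", concentrations[i])
    spec <- synth_spec(comps, concentration = concentrations[i],
                       run_id = id, seed = seed + i, ...)
    runs[[id]] <- simulate_run(spec)
  }
  list(runs = runs,
       equilibrium = data.frame(concentration = concentrations,
                                theta = theta,
                                response = hill$f_max * theta))
}

#' Simulate a run with a prescribed dissipation drift
#'
#' Convenience fixture for the dissipation quality filter: identical to
#' [simulate_run()] but with the dissipation drift slope overridden.
#'
#' @param spec a [synth_spec()].
#' @param drift dissipation drift slope (1/s, natural scale).
#' @return An [adsorption_run()].
#' @export
make_drifting_run <- function(spec, drift) {
  spec$diss_drift <- drift
  simulate_run(spec)
}
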