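#' Single cooperative sigmoidal kinetic component
#'
#' One adsorption/assembly process modeled as a logistic curve in time:
#' `amplitude / (1 + exp(-k_obs * (t - t_shift))) - v_shift`. The inflection
#' sits at `t = t_shift`, where the process runs at maximum rate and has
#' accumulated half of its final shift; `v_shift` moves the curve below the
#' horizontal axis (deflection-onset offset).
#'
#' @param amplitude final frequency-shift contribution of the process (Hz,
#'   >= 0).
#' @param k_obs apparent first-order rate constant (s^-1, > 0).
#' @param t_shift inflection time (s).
#' @param v_shift vertical offset below the axis (Hz, >= 0).
#' @return Object of class `sigmoid_component`.
#' @export
sigmoid_component <- function(amplitude, k_obs, t_shift = 0, v_shift = 0) {
  stopifnot(amplitude >= 0, k_obs > 0, v_shift >= 0)
  structure(list(amplitude = as.numeric(amplitude),
                 k_obs = as.numeric(k_obs),
                 t_shift = as.numeric(t_shift),
                 v_shift = as.numeric(v_shift)),
            class = "sigmoid_component")
}

# overflow-safe logistic; plogis saturates cleanly for |z| > ~745
.logistic <- function(z) stats::plogis(z)

#' Evaluate a sigmoidal component
#'
#' @param component a [sigmoid_component()].
#' @param t time(s), numeric vector (s).
#' @return Frequency-shift contribution in Hz, finite for all finite `t`.
#' @export
sigmoid_value <- function(component, t) {
  component$amplitude *
    .logistic(component$k_obs * (t - component$t_shift)) -
    component$v_shift
}

#' Log-spaced grid of apparent rate constants
#'
#' The spectral support of the model: `n` rate constants spaced uniformly in
#' log space, inclusive of both endpoints.
#'
#' @param k_min,k_max grid limits (s^-1), `0 < k_min < k_max`.
#' @param n number of grid points (default 50).
#' @return Object of class `kobs_grid` with fields `k_min`, `k_max`, `n`,
#'   `values`.
#' @export
make_grid <- function(k_min, k_max, n = 50) {
  if (!(is.numeric(k_min) && is.numeric(k_max) && k_min > 0 &&
        k_max > k_min)) {
    stop("require 0 < k_min < k_max")
  }
  if (n < 2) stop("grid needs at least 2 components")
  values <- exp(seq(log(k_min), log(k_max), length.out = n))
  values[1] <- k_min
  values[n] <- k_max
  structure(list(k_min = as.numeric(k_min), k_max = as.numeric(k_max),
                 n = as.integer(n), values = values),
            class = "kobs_grid")
}

#' Default rate-constant grid for a record
#'
#' The resolvable-rate window of a sampled record: processes slower than
#' about a tenth of the reciprocal record span or faster than about ten times
#' the sampling rate leave no usable signature, so the default grid spans
#' `1/(10 * t_span)` to `10 / dt`.
#'
#' @param curve an [adsorption_curve()].
#' @param n number of components (default 50).
#' @return A [make_grid()] result.
#' @export
default_grid <- function(curve, n = 50) {
  t_span <- diff(range(curve$time))
  dt <- stats::median(diff(curve$time))
  make_grid(1 / (10 * t_span), 10 / dt, n = n)
}

#' Frequency Response Cooperativity model
#'
#' An ordered bank of sigmoidal components, one per grid rate constant; the
#' per-component amplitudes over `log10(k_obs)` are the kinetic spectrum.
#' Component rate constants are pinned to the grid values.
#'
#' @param grid a [make_grid()] result.
#' @param amplitude,t_shift,v_shift numeric vectors of length `grid$n`.
#' @param diagnostics optional list (rmsd, iterations, converged, ...).
#' @return Object of class `frc_model`.
#' @export
frc_model <- function(grid, amplitude, t_shift, v_shift,
                      diagnostics = list()) {
  stopifnot(inherits(grid, "kobs_grid"),
            length(amplitude) == grid$n,
            length(t_shift) == grid$n,
            length(v_shift) == grid$n)
  if (any(amplitude < 0) || any(v_shift < 0)) {
    stop("amplitudes and vertical shifts must be non-negative")
  }
  structure(list(grid = grid,
                 amplitude = as.numeric(amplitude),
                 t_shift = as.numeric(t_shift),
                 v_shift = as.numeric(v_shift),
                 diagnostics = diagnostics),
            class = "frc_model")
}

#' @export
print.frc_model <- function(x, ...) {
  act <- sum(x$amplitude > 0)
  cat("<frc_model> ", x$grid$n, " components on k_obs in [",
      format(x$grid$k_min), ", ", format(x$grid$k_max), "] s^-1\n", sep = "")
  cat("  active components: ", act, "\n", sep = "")
  s <- model_summary(x)
  cat("  asymptote: ", format(s$asymptote), " Hz\n", sep = "")
  if (!is.null(x$diagnostics$rmsd)) {
    cat("  fit RMSD: ", format(x$diagnostics$rmsd), " Hz (converged: ",
        isTRUE(x$diagnostics$converged), ")\n", sep = "")
  }
  invisible(x)
}

#' Components of an FRC model
#'
#' @param model an [frc_model()].
#' @return List of [sigmoid_component()] objects, one per grid point.
#' @export
frc_components <- function(model) {
  lapply(seq_len(model$grid$n), function(i) {
    sigmoid_component(model$amplitude[i], model$grid$values[i],
                      model$t_shift[i], model$v_shift[i])
  })
}

#' Evaluate an FRC model
#'
#' Sum of all component sigmoids at the requested times.
#'
#' @param model an [frc_model()].
#' @param t numeric vector of times (s).
#' @return Modeled frequency shift (Hz), same length as `t`.
#' @export
frc_value <- function(model, t) {
  out <- numeric(length(t))
  for (i in seq_len(model$grid$n)) {
    a <- model$amplitude[i]
    v <- model$v_shift[i]
    if (a == 0 && v == 0) next
    out <- out + a * .logistic(model$grid$values[i] * (t - model$t_shift[i])) - v
  }
  out
}

#' Langmuir (non-cooperative) adsorption parameters
#'
#' @param amplitude saturation response A (Hz, >= 0).
#' @param k_obs apparent rate constant (s^-1, > 0).
#' @return Object of class `langmuir_params`.
#' @export
langmuir_params <- function(amplitude, k_obs) {
  stopifnot(amplitude >= 0, k_obs > 0)
  structure(list(amplitude = as.numeric(amplitude),
                 k_obs = as.numeric(k_obs)),
            class = "langmuir_params")
}

#' Evaluate the Langmuir adsorption observable
#'
#' Single-site, non-cooperative uptake `A * (1 - exp(-k_obs * t))`: maximum
#' rate at t = 0, pure convergence, no growth (lag) phase. Serves as the
#' contrast model for the cooperative sigmoids.
#'
#' @param params a [langmuir_params()].
#' @param t numeric vector of times (s).
#' @return Modeled response (Hz).
#' @export
langmuir_value <- function(params, t) {
  params$amplitude * (1 - exp(-params$k_obs * t))
}

#' Totals of an FRC model
#'
#' @param model an [frc_model()].
#' @return List with `total_amplitude`, `total_v_shift`, `asymptote`
#'   (total amplitude minus total vertical shift, the t -> Inf response) and
#'   `n_active` (components with nonzero amplitude).
#' @export
model_summary <- function(model) {
  list(total_amplitude = sum(model$amplitude),
       total_v_shift = sum(model$v_shift),
       asymptote = sum(model$amplitude) - sum(model$v_shift),
       n_active = sum(model$amplitude > 0))
}

#' Serialize an FRC model to JSON
#'
#' Full-precision serialization; [read_model()] reproduces the model exactly.
#'
#' @param model an [frc_model()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  obj <- list(grid = list(k_min = model$grid$k_min,
                          k_max = model$grid$k_max,
                          n = model$grid$n),
              amplitude = model$amplitude,
              t_shift = model$t_shift,
              v_shift = model$v_shift,
              diagnostics = model$diagnostics)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE)
  invisible(path)
}

#' Read an FRC model from JSON
#'
#' @param path file written by [write_model()].
#' @return An [frc_model()].
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  grid <- make_grid(obj$grid$k_min, obj$grid$k_max, obj$grid$n)
  frc_model(grid, obj$amplitude, obj$t_shift, obj$v_shift,
            diagnostics = as.list(obj$diagnostics))
}
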