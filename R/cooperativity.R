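#' Gas constant in kcal/(mol K)
#' @keywords internal
.R_KCAL <- 1.987e-3

#' Estimate the equilibrium plateau of an adsorption curve
#'
#' Mean response over the final fraction of samples, with a convergence
#' check: the tail is flagged "not converged" when its fitted slope exceeds
#' 1 percent of the response range per 100 s.
#'
#' @param curve an [adsorption_curve()].
#' @param tail_fraction fraction of trailing samples averaged (default 0.1).
#' @return List of class `plateau_estimate`: `value` (Hz), `converged`
#'   (logical), `tail_slope` (Hz/s).
#' @export
plateau_estimate <- function(curve, tail_fraction = 0.1) {
  stopifnot(tail_fraction > 0, tail_fraction <= 1)
  n <- length(curve$time)
  i0 <- max(1L, n - max(2L, ceiling(tail_fraction * n)) + 1L)
  tt <- curve$time[i0:n]
  yy <- curve$response[i0:n]
  value <- mean(yy)
  rng <- diff(range(curve$response))
  slope <- if (length(unique(tt)) > 1) {
    unname(stats::coef(stats::lm(yy ~ tt))[2])
  } else 0
  converged <- rng == 0 || abs(slope) * 100 <= 0.01 * rng
  structure(list(value = value, converged = converged, tail_slope = slope),
            class = "plateau_estimate")
}

#' @export
print.plateau_estimate <- function(x, ...) {
  cat("<plateau_estimate> ", format(x$value), " Hz",
      if (!x$converged) "  [not converged]", "\n", sep = "")
  invisible(x)
}

#' Binding free energy from an equilibrium constant
#'
#' `delta G = -R T ln(K_eq)` with R = 1.987e-3 kcal/(mol K).
#'
#' @param K_eq equilibrium binding constant (M^-1), > 0.
#' @param T temperature (K), default 298.15.
#' @return Free energy in kcal/mol.
#' @export
delta_g <- function(K_eq, T = 298.15) {
  if (any(K_eq <= 0)) stop("K_eq must be positive")
  -.R_KCAL * T * log(K_eq)
}

.hill_ols <- function(lnC, lnOdds) {
  fit <- stats::lm(lnOdds ~ lnC)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = summary(fit)$r.squared)
}

#' Hill-equation fit of concentration-dependent equilibrium responses
#'
#' Linearizes the Hill isotherm: with fractional occupancy
#' `theta = response / f_max`, ordinary least squares of
#' `ln(theta / (1 - theta))` against `ln C` (C in molar) gives the
#' cooperativity constant `n` as the slope and an intercept `ln K'` from
#' which the equilibrium constant is recovered as `K_eq = K'^(1/n)` (M^-1).
#' `n > 1` indicates positive, `n < 1` negative cooperativity, `n = 1` the
#' non-cooperative (Langmuir) limit. Binding free energy follows via
#' [delta_g()].
#'
#' When `f_max = "fit"`, the saturation response is profiled: a 1-D search
#' over `f_max` maximizes the linear-fit R-squared.
#'
#' @param points data frame with columns `concentration` (micromolar) and
#'   `response` (equilibrium frequency shift, Hz).
#' @param f_max saturation response in Hz, or `"fit"`.
#' @param T temperature (K) for the free-energy conversion.
#' @return Object of class `hill_fit`: `n`, `K_eq` (M^-1), `f_max`,
#'   `delta_G` (kcal/mol), `T`, `slope`, `intercept`, `r_squared`,
#'   `points_used`, `excluded` (row indices dropped for theta outside (0,1)).
#' @export
hill_fit <- function(points, f_max = "fit", T = 298.15) {
  stopifnot(is.data.frame(points),
            all(c("concentration", "response") %in% names(points)))
  if (any(points$concentration <= 0)) {
    stop("concentrations must be positive (micromolar)")
  }
  if (anyDuplicated(points$concentration)) {
    # replicate concentrations are fine for OLS; no action needed
  }
  C_M <- points$concentration * 1e-6

  fit_at <- function(fmax) {
    theta <- points$response / fmax
    ok <- is.finite(theta) & theta > 0 & theta < 1
    if (sum(ok) < 3) return(NULL)
    ols <- .hill_ols(log(C_M[ok]), log(theta[ok] / (1 - theta[ok])))
    c(ols, list(ok = ok, f_max = fmax))
  }

  if (identical(f_max, "fit")) {
    lo <- max(points$response) * (1 + 1e-4)
    hi <- max(points$response) * 100
    obj <- function(fmax) {
      f <- fit_at(fmax)
      if (is.null(f)) return(1e6)
      -f$r_squared
    }
    opt <- stats::optimize(obj, interval = c(lo, hi), tol = 1e-10)
    f_max <- opt$minimum
  }
  stopifnot(is.numeric(f_max), f_max > 0)
  res <- fit_at(f_max)
  if (is.null(res)) {
    stop("fewer than 3 points with occupancy strictly inside (0,1); ",
         "cannot fit the Hill linearization")
  }
  if (any(!res$ok)) {
    warning(sum(!res$ok), " point(s) excluded: occupancy outside (0,1)")
  }
  n <- res$slope
  if (n <= 0) warning("non-positive Hill slope; K_eq is not interpretable")
  K_eq <- exp(res$intercept / n)   # (K')^(1/n), K' = exp(intercept)
  structure(list(n = n, K_eq = K_eq, f_max = f_max,
                 delta_G = if (K_eq > 0 && is.finite(K_eq))
                   delta_g(K_eq, T) else NA_real_,
                 T = T,
                 slope = res$slope, intercept = res$intercept,
                 r_squared = res$r_squared,
                 points_used = sum(res$ok),
                 excluded = which(!res$ok)),
            class = "hill_fit")
}

#' @export
print.hill_fit <- function(x, ...) {
  cat("<hill_fit>\n")
  cat(sprintf("  n (cooperativity): %.4g\n", x$n))
  cat(sprintf("  K_eq:              %.4g M^-1\n", x$K_eq))
  cat(sprintf("  delta G (%g K):    %.4g kcal/mol\n", x$T, x$delta_G))
  cat(sprintf("  f_max:             %.4g Hz\n", x$f_max))
  cat(sprintf("  linear fit R^2:    %.6f  (%d points used)\n",
              x$r_squared, x$points_used))
  invisible(x)
}

#' Fit the Langmuir observable to an adsorption curve
#'
#' Least-squares fit of `A * (1 - exp(-k t))`, the non-cooperative
#' single-site contrast model. It captures convergence but has no growth
#' phase, so sigmoidal (cooperative) curves fit poorly by construction.
#'
#' @param curve a baseline-zeroed rising [adsorption_curve()].
#' @return A [langmuir_params()] with attributes `rmsd` and `degenerate`.
#' @export
langmuir_fit <- function(curve) {
  t <- curve$time
  y <- curve$response
  A0 <- max(y)
  if (A0 <= 0) {
    out <- langmuir_params(0, 1e-12)
    attr(out, "rmsd") <- sqrt(mean(y^2))
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  half <- t[which(y >= A0 / 2)[1]]
  k0 <- if (is.na(half) || half <= 0) 1 / max(t) else log(2) / half
  fit <- minpack.lm::nls.lm(
    par = c(A = A0, k = k0),
    lower = c(0, 1e-12), upper = c(Inf, Inf),
    fn = function(p) p[1] * (1 - exp(-p[2] * t)) - y,
    control = minpack.lm::nls.lm.control(ftol = 1e-14, ptol = 1e-14,
                                         maxiter = 500))
  out <- langmuir_params(fit$par[1], fit$par[2])
  attr(out, "rmsd") <- sqrt(mean((langmuir_value(out, t) - y)^2))
  attr(out, "degenerate") <- FALSE
  out
}

# Standard average residue masses (g/mol): monomer mass minus one water,
# 2-decimal values from the conventional average-isotopic table.
.AA_RESIDUE_MASS <- c(
  A = 71.08,  R = 156.19, N = 114.10, D = 115.09, C = 103.14,
  E = 129.12, Q = 128.13, G = 57.05,  H = 137.14, I = 113.16,
  L = 113.16, K = 128.17, M = 131.19, F = 147.18, P = 97.12,
  S = 87.08,  T = 101.10, W = 186.21, Y = 163.18, V = 99.13)

.WATER_MASS <- 18.02

#' Average molar mass of a peptide
#'
#' Sum of standard average residue masses plus one water (18.02 g/mol), the
#' quantity reported by ESI-MS for an unmodified linear peptide. Used as an
#' identity check, e.g. the gold-binding peptide AuBP1 (WAGAKRLVLRRE) has an
#' average molar mass of 1454.7 g/mol.
#'
#' @param sequence one-letter amino-acid string (standard 20 letters).
#' @return Average molar mass in g/mol (unrounded).
#' @export
peptide_average_mass <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  if (nchar(sequence) == 0L) stop("empty peptide sequence")
  letters <- strsplit(toupper(sequence), "")[[1]]
  bad <- which(!letters %in% names(.AA_RESIDUE_MASS))
  if (length(bad)) {
    stop("unknown amino-acid letter '", letters[bad[1]], "' at position ",
         bad[1])
  }
  sum(.AA_RESIDUE_MASS[letters]) + .WATER_MASS
}
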