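#' Kinetic spectrum container
#'
#' Component weights (fitted sigmoid amplitudes, Hz) over `log10` of the
#' apparent rate constant.
#'
#' @param log_k_obs strictly increasing numeric vector.
#' @param curve_weight nonnegative numeric vector, same length.
#' @param concentration optional micromolar label.
#' @return Object of class `kinetic_spectrum`.
#' @export
kinetic_spectrum <- function(log_k_obs, curve_weight,
                             concentration = NA_real_) {
  log_k_obs <- as.numeric(log_k_obs)
  curve_weight <- as.numeric(curve_weight)
  if (length(log_k_obs) != length(curve_weight)) {
    stop("log_k_obs and curve_weight must have equal length")
  }
  if (is.unsorted(log_k_obs, strictly = TRUE)) {
    stop("log_k_obs must be strictly increasing")
  }
  if (any(curve_weight < 0)) stop("curve_weight must be non-negative")
  structure(list(log_k_obs = log_k_obs, curve_weight = curve_weight,
                 concentration = as.numeric(concentration)),
            class = "kinetic_spectrum")
}

#' @export
print.kinetic_spectrum <- function(x, ...) {
  cat("<kinetic_spectrum> ", length(x$log_k_obs), " components, log10(k) in [",
      format(min(x$log_k_obs)), ", ", format(max(x$log_k_obs)), "]\n",
      sep = "")
  cat("  total weight: ", format(sum(x$curve_weight)), " Hz; nonzero: ",
      sum(x$curve_weight > 0), "\n", sep = "")
  invisible(x)
}

#' Extract the kinetic spectrum from a fitted FRC model
#'
#' The spectrally distributed rate estimate: fitted component amplitudes
#' plotted against `log10(k_obs)`. Pruned components are kept as exact
#' zeros, so total spectral weight equals total fitted amplitude.
#'
#' @param model a fitted [frc_model()].
#' @param concentration optional micromolar label carried on the spectrum.
#' @return A [kinetic_spectrum()].
#' @export
extract_spectrum <- function(model, concentration = NA_real_) {
  kinetic_spectrum(log_k_obs = log10(model$grid$values),
                   curve_weight = model$amplitude,
                   concentration = concentration)
}

# mixture model: background + sum of area-parameterized Gaussians
.mixture_value <- function(x, centers, widths, areas, bg) {
  out <- rep(bg[1], length(x))
  if (length(bg) > 1) out <- out + bg[2] * x
  for (j in seq_along(centers)) {
    out <- out + areas[j] * stats::dnorm(x, centers[j], widths[j])
  }
  out
}

.mixture_fit <- function(x, y, centers, widths, areas, nbg, ftol = 1e-12) {
  np <- length(centers)
  dx <- min(diff(x))
  span <- diff(range(x))
  p0 <- c(centers, widths, areas, numeric(nbg))
  lower <- c(rep(min(x), np), rep(dx / 4, np), rep(0, np),
             rep(-Inf, nbg))
  upper <- c(rep(max(x), np), rep(span, np), rep(Inf, np), rep(Inf, nbg))
  resid_fn <- function(p) {
    ce <- p[seq_len(np)]
    wi <- p[np + seq_len(np)]
    ar <- p[2 * np + seq_len(np)]
    bg <- if (nbg > 0) p[3 * np + seq_len(nbg)] else 0
    .mixture_value(x, ce, wi, ar, bg) - y
  }
  fit <- minpack.lm::nls.lm(
    par = p0, lower = lower, upper = upper, fn = resid_fn,
    control = minpack.lm::nls.lm.control(ftol = ftol, ptol = ftol,
                                         maxiter = 500))
  p <- fit$par
  list(centers = p[seq_len(np)],
       widths = p[np + seq_len(np)],
       areas = p[2 * np + seq_len(np)],
       background = if (nbg > 0) p[3 * np + seq_len(nbg)] else numeric(),
       rss = sum(resid_fn(p)^2),
       n_par = length(p0))
}

#' Deconvolve a kinetic spectrum into Gaussian peaks
#'
#' Fits the spectrum (weight vs `log10 k_obs`) as a sum of Gaussian peaks
#' plus an optional flat or linear background by bounded least squares.
#' With `n_peaks = "auto"`, peaks are added greedily at the largest
#' positive residual until the Bayesian information criterion stops
#' improving; with a fixed count, exactly that many peaks are fitted (same
#' greedy initialization). Peaks are returned sorted by center.
#'
#' @param spectrum a [kinetic_spectrum()] with at least one nonzero weight.
#' @param n_peaks `"auto"` (default) or a positive integer not exceeding
#'   the number of nonzero spectrum points.
#' @param background `"none"` (default), `"constant"`, or `"linear"`.
#' @param max_peaks cap on the greedy search (default 8).
#' @return Object of class `deconvolution_result`: `peaks` (data frame with
#'   `center`, `width`, `area`, `height`, `shape`), `background`
#'   coefficients, `residual_rmsd`, and `fitted` values on the grid.
#' @export
deconvolve <- function(spectrum, n_peaks = "auto",
                       background = c("none", "constant", "linear"),
                       max_peaks = 8) {
  background <- match.arg(background)
  x <- spectrum$log_k_obs
  y <- spectrum$curve_weight
  nonzero <- sum(y > 0)
  if (nonzero == 0) stop("nothing to deconvolve: spectrum is all zero")
  nbg <- switch(background, none = 0L, constant = 1L, linear = 2L)
  auto <- identical(n_peaks, "auto")
  if (!auto) {
    n_peaks <- as.integer(n_peaks)
    if (n_peaks < 1) stop("n_peaks must be >= 1")
    if (n_peaks > nonzero) {
      stop("n_peaks (", n_peaks, ") exceeds the ", nonzero,
           " nonzero spectrum points")
    }
    max_peaks <- n_peaks
  }
  dx <- min(diff(x))
  n <- length(x)

  centers <- numeric(0); widths <- numeric(0); areas <- numeric(0)
  best <- NULL
  best_bic <- Inf
  fit <- NULL
  repeat {
    resid <- if (is.null(fit)) y else y - .mixture_value(
      x, fit$centers, fit$widths, fit$areas,
      if (nbg > 0) fit$background else 0)
    j <- which.max(resid)
    if (resid[j] <= 0) break
    centers <- c(if (is.null(fit)) NULL else fit$centers, x[j])
    widths <- c(if (is.null(fit)) NULL else fit$widths, 2 * dx)
    areas <- c(if (is.null(fit)) NULL else fit$areas,
               max(resid[j], .Machine$double.eps) * 2 * dx * sqrt(2 * pi))
    fit <- .mixture_fit(x, y, centers, widths, areas, nbg)
    k_par <- fit$n_par
    bic <- n * log(max(fit$rss / n, .Machine$double.xmin)) +
      k_par * log(n)
    if (auto) {
      if (bic < best_bic - 1e-9) {
        best <- fit; best_bic <- bic
      } else {
        break
      }
      # residual at numerical floor: further peaks would fit roundoff
      if (sqrt(fit$rss / n) <= 1e-10 * max(y)) break
      if (length(centers) >= min(max_peaks, nonzero)) break
    } else {
      best <- fit
      if (length(centers) >= n_peaks) break
    }
  }
  if (is.null(best)) stop("deconvolution failed to place any peak")

  ord <- order(best$centers)
  peaks <- data.frame(center = best$centers[ord],
                      width = best$widths[ord],
                      area = best$areas[ord],
                      height = best$areas[ord] /
                        (best$widths[ord] * sqrt(2 * pi)),
                      shape = "gaussian")
  fitted <- .mixture_value(x, best$centers, best$widths, best$areas,
                           if (nbg > 0) best$background else 0)
  structure(list(peaks = peaks,
                 background = best$background,
                 background_type = background,
                 residual_rmsd = sqrt(best$rss / n),
                 fitted = fitted,
                 log_k_obs = x),
            class = "deconvolution_result")
}

#' @export
print.deconvolution_result <- function(x, ...) {
  cat("<deconvolution_result> ", nrow(x$peaks), " Gaussian peak(s), ",
      "background: ", x$background_type, "\n", sep = "")
  print(x$peaks, row.names = FALSE)
  cat("  residual RMSD: ", format(x$residual_rmsd), " Hz\n", sep = "")
  invisible(x)
}

#' Slow/fast kinetic-regime weight fractions
#'
#' Splits total spectral weight at a rate threshold: "slow" is the weight
#' fraction strictly below `k_split`, "fast" the fraction at or above it.
#' The default split is the geometric midpoint of the grid; the regime
#' boundary is a reporting device, not a fitted quantity.
#'
#' @param spectrum a [kinetic_spectrum()] with nonzero total weight.
#' @param k_split rate threshold (s^-1); default geometric midpoint.
#' @return Named list `slow`, `fast` (fractions summing to 1) plus the
#'   `k_split` used.
#' @export
regime_fractions <- function(spectrum, k_split = NULL) {
  total <- sum(spectrum$curve_weight)
  if (total <= 0) stop("zero total spectral weight")
  if (is.null(k_split)) {
    k_split <- 10^mean(range(spectrum$log_k_obs))
  }
  slow <- sum(spectrum$curve_weight[spectrum$log_k_obs < log10(k_split)]) /
    total
  list(slow = slow, fast = 1 - slow, k_split = k_split)
}

#' Local maxima of a kinetic spectrum
#'
#' Grid indices whose weight is positive and not exceeded by either
#' neighbor (ties flatten to the left-most index of a plateau).
#'
#' @param spectrum a [kinetic_spectrum()].
#' @return Integer vector of grid indices.
#' @export
spectrum_peaks <- function(spectrum) {
  w <- spectrum$curve_weight
  n <- length(w)
  if (n == 0) return(integer())
  left <- c(-Inf, w[-n])
  right <- c(w[-1], -Inf)
  which(w > 0 & w > left & w >= right)
}
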