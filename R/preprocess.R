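#' Dissipation-based quality filter
#'
#' QCM-D runs whose dissipation wanders are dominated by instrumental drift
#' or viscoelastic artifacts rather than rigid-film mass uptake. A run is
#' kept when its maximum dissipation excursion from the initial value,
#' taken over all overtones and all samples, stays strictly below the
#' threshold (default 0.5e-6 on the natural dimensionless scale). Runs
#' without dissipation data cannot be vetted and are excluded
#' ("unfilterable") with a warning.
#'
#' @param runs list of [adsorption_run()] objects.
#' @param threshold dimensionless excursion bound (natural scale).
#' @return List with elements `kept` (the surviving runs) and `report`, a
#'   data frame with one row per input run: `run_id`,
#'   `max_dissipation_excursion`, `kept`, `unfilterable`, `threshold_used`.
#' @export
dissipation_filter <- function(runs, threshold = 0.5e-6) {
  stopifnot(threshold > 0)
  rows <- lapply(runs, function(r) {
    if (is.null(r$dissipation) || length(r$dissipation) == 0L) {
      warning("run '", r$run_id,
              "' has no dissipation data; marked unfilterable and excluded")
      return(data.frame(run_id = r$run_id,
                        max_dissipation_excursion = NA_real_,
                        kept = FALSE, unfilterable = TRUE,
                        threshold_used = threshold))
    }
    exc <- max(vapply(r$dissipation,
                      function(d) max(abs(d - d[1])), numeric(1)))
    data.frame(run_id = r$run_id, max_dissipation_excursion = exc,
               kept = exc < threshold, unfilterable = FALSE,
               threshold_used = threshold)
  })
  report <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  kept <- runs[report$kept]
  list(kept = kept, report = report)
}

#' Average overtone frequency shifts into one adsorption curve
#'
#' Builds the analysis observable from a raw run: the selected overtone
#' frequency-shift series (optionally divided by their overtone index, the
#' usual convention for putting harmonics on a common scale) are averaged
#' pointwise, negated so adsorption gives a rising curve, and baseline-zeroed
#' at the first sample.
#'
#' @param run an [adsorption_run()].
#' @param overtones overtone indices to average (default 5, 7, 9).
#' @param normalize_by_overtone divide each shift by its overtone index
#'   before averaging (default TRUE).
#' @param baseline_zero shift the response so it is 0 at the first sample
#'   (default TRUE).
#' @return An [adsorption_curve()].
#' @export
average_overtones <- function(run, overtones = c(5, 7, 9),
                              normalize_by_overtone = TRUE,
                              baseline_zero = TRUE) {
  keys <- as.character(overtones)
  missing <- setdiff(keys, names(run$freq_shift))
  if (length(missing)) {
    stop("overtone(s) ", paste(missing, collapse = ", "),
         " not present in run '", run$run_id, "'; available: ",
         paste(names(run$freq_shift), collapse = ", "))
  }
  mat <- vapply(keys, function(k) {
    v <- run$freq_shift[[k]]
    if (normalize_by_overtone) v / as.numeric(k) else v
  }, numeric(length(run$time)))
  if (is.null(dim(mat))) mat <- matrix(mat, nrow = length(run$time))
  response <- -rowMeans(mat)
  if (baseline_zero) response <- response - response[1]
  adsorption_curve(run_id = run$run_id, time = run$time,
                   response = response,
                   concentration = run$concentration,
                   overtones_used = as.integer(overtones),
                   normalized_by_overtone = normalize_by_overtone)
}

#' Resample a curve onto a target time grid
#'
#' Linear interpolation within the observed time span; requests outside the
#' span are an error (no extrapolation).
#'
#' @param curve an [adsorption_curve()].
#' @param target_times new sample times (s), strictly increasing, within the
#'   span of `curve$time`.
#' @return An [adsorption_curve()] on the target grid.
#' @export
resample_to_grid <- function(curve, target_times) {
  target_times <- as.numeric(target_times)
  if (min(target_times) < min(curve$time) ||
      max(target_times) > max(curve$time)) {
    stop("target times extend outside the observed span [",
         min(curve$time), ", ", max(curve$time), "] s; extrapolation refused")
  }
  y <- stats::approx(curve$time, curve$response, xout = target_times,
                     method = "linear", ties = "ordered")$y
  adsorption_curve(run_id = curve$run_id, time = target_times, response = y,
                   concentration = curve$concentration,
                   overtones_used = curve$overtones_used,
                   normalized_by_overtone = curve$normalized_by_overtone)
}

# Common grid for a set of curves: the time base of the coarsest curve
# (largest median sampling interval), restricted to the overlapping span.
.common_grid <- function(curves) {
  med_dt <- vapply(curves, function(cv) stats::median(diff(cv$time)),
                   numeric(1))
  base <- curves[[which.max(med_dt)]]$time
  lo <- max(vapply(curves, function(cv) min(cv$time), numeric(1)))
  hi <- min(vapply(curves, function(cv) max(cv$time), numeric(1)))
  if (lo > hi) stop("curves have no overlapping time span")
  base[base >= lo & base <= hi]
}

#' Pointwise mean of adsorption curves
#'
#' @param curves list of [adsorption_curve()] objects at one concentration.
#' @param resample allow linear resampling to a common grid (the coarsest
#'   curve's time base over the overlapping span) when time grids differ;
#'   if `FALSE` (default), differing grids are an error.
#' @return An [adsorption_curve()] with run_id `"mean"`.
#' @export
mean_curve <- function(curves, resample = FALSE) {
  stopifnot(length(curves) >= 1L)
  t0 <- curves[[1]]$time
  same <- all(vapply(curves, function(cv) {
    length(cv$time) == length(t0) && all(cv$time == t0)
  }, logical(1)))
  if (!same) {
    if (!resample) {
      stop("curves are on different time grids; call with resample = TRUE")
    }
    grid <- .common_grid(curves)
    curves <- lapply(curves, resample_to_grid, target_times = grid)
    t0 <- grid
  }
  resp <- rowMeans(vapply(curves, `[[`, numeric(length(t0)), "response"))
  adsorption_curve(run_id = "mean", time = t0, response = resp,
                   concentration = curves[[1]]$concentration,
                   overtones_used = curves[[1]]$overtones_used,
                   normalized_by_overtone =
                     curves[[1]]$normalized_by_overtone)
}

#' Select the representative replicate by minimum RMSD
#'
#' Computes each replicate's root-mean-square deviation from the pointwise
#' mean curve of the set and selects the replicate with the smallest RMSD;
#' ties are broken lexicographically by run id.
#'
#' @param curves list of [adsorption_curve()] replicates at one
#'   concentration.
#' @param resample passed to [mean_curve()].
#' @return List with `concentration`, `rmsd_by_run` (named numeric),
#'   `chosen_run_id`, and `chosen` (the selected curve), of class
#'   `representative_selection`.
#' @export
select_representative <- function(curves, resample = FALSE) {
  stopifnot(length(curves) >= 1L)
  m <- mean_curve(curves, resample = resample)
  aligned <- lapply(curves, function(cv) {
    if (length(cv$time) == length(m$time) && all(cv$time == m$time)) cv
    else resample_to_grid(cv, m$time)
  })
  ids <- vapply(curves, `[[`, character(1), "run_id")
  rmsd <- vapply(aligned, function(cv) {
    sqrt(mean((cv$response - m$response)^2))
  }, numeric(1))
  names(rmsd) <- ids
  ord <- order(rmsd, ids)   # lexicographic tie-break on run_id
  chosen_id <- ids[ord[1]]
  structure(list(concentration = curves[[1]]$concentration,
                 rmsd_by_run = rmsd,
                 chosen_run_id = chosen_id,
                 chosen = curves[[which(ids == chosen_id)[1]]]),
            class = "representative_selection")
}

#' @export
print.representative_selection <- function(x, ...) {
  cat("<representative_selection>",
      if (!is.na(x$concentration)) sprintf(" %g uM", x$concentration),
      "\n", sep = "")
  for (id in names(x$rmsd_by_run)) {
    cat(sprintf("  %-12s RMSD %.4g Hz%s\n", id, x$rmsd_by_run[[id]],
                if (id == x$chosen_run_id) "  <- chosen" else ""))
  }
  invisible(x)
}
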