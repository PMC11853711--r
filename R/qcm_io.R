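#' Column dialect for delimited QCM-D exports
#'
#' Instrument software exports multi-overtone frequency/dissipation tables in
#' a variety of delimited-text layouts. A dialect maps table columns onto the
#' fields of an [adsorption_run()]: a time column, per-overtone frequency-shift
#' columns (`f5`, `f7`, ...), optional per-overtone dissipation columns
#' (`D5`, `D7`, ...), and optional run-id / concentration columns so that
#' several runs can share one file.
#'
#' @param sep field separator (default tab).
#' @param time regex matching the time column.
#' @param freq regex with one capture group giving the overtone index of a
#'   frequency-shift column.
#' @param diss regex with one capture group giving the overtone index of a
#'   dissipation column.
#' @param run regex matching the run-id column (optional in files).
#' @param conc regex matching the concentration column, in micromolar.
#' @param time_scale multiplier converting file time units to seconds
#'   (e.g. 60 for minutes).
#' @param diss_scale multiplier converting file dissipation units to the
#'   natural (dimensionless) scale; use `1e-6` when the file stores
#'   dissipation in units of 1e-6.
#' @param fundamental_hz sensor fundamental frequency assigned to runs (Hz).
#' @return A list of class `qcm_dialect`.
#' @export
qcm_dialect <- function(sep = "\t",
                        time = "^time",
                        freq = "^[fF](\\d+)$",
                        diss = "^[dD](\\d+)$",
                        run = "^run_id$",
                        conc = "^conc",
                        time_scale = 1,
                        diss_scale = 1,
                        fundamental_hz = 5e6) {
  structure(list(sep = sep, time = time, freq = freq, diss = diss,
                 run = run, conc = conc, time_scale = time_scale,
                 diss_scale = diss_scale, fundamental_hz = fundamental_hz),
            class = "qcm_dialect")
}

#' Raw multi-overtone QCM-D run
#'
#' Container for one sensor run at one solution concentration: sample times,
#' per-overtone frequency shifts and (optionally) per-overtone dissipation
#' shifts. Series are re-ordered so that time is strictly increasing;
#' duplicate timestamps are an error.
#'
#' @param run_id character label.
#' @param time sample times (s).
#' @param freq_shift named list of numeric vectors, one per overtone; names
#'   are odd positive integers ("5", "7", ...). Values in Hz (raw sign:
#'   adsorption makes them negative).
#' @param dissipation optional named list of numeric vectors on the natural
#'   dimensionless scale (order 1e-6), same overtone naming.
#' @param concentration solution concentration in micromolar, or `NA` for a
#'   blank run.
#' @param fundamental_hz sensor fundamental frequency (Hz).
#' @return Object of class `adsorption_run`.
#' @export
adsorption_run <- function(run_id, time, freq_shift, dissipation = NULL,
                           concentration = NA_real_, fundamental_hz = 5e6) {
  stopifnot(is.character(run_id), length(run_id) == 1L)
  time <- as.numeric(time)
  if (anyNA(time)) stop("time contains missing values")
  if (!is.list(freq_shift) || is.null(names(freq_shift)) ||
      any(names(freq_shift) == "")) {
    stop("freq_shift must be a named list keyed by overtone index")
  }
  ot <- as.integer(names(freq_shift))
  if (anyNA(ot) || any(ot <= 0L) || any(ot %% 2L == 0L)) {
    stop("overtone indices must be positive odd integers, got: ",
         paste(names(freq_shift), collapse = ", "))
  }
  lens <- vapply(freq_shift, length, integer(1))
  if (any(lens != length(time))) {
    stop("all frequency series must have the same length as time")
  }
  if (!is.null(dissipation)) {
    dl <- vapply(dissipation, length, integer(1))
    if (any(dl != length(time))) {
      stop("all dissipation series must have the same length as time")
    }
  }
  if (anyDuplicated(time)) {
    stop("duplicate timestamps in run '", run_id, "'")
  }
  if (is.unsorted(time)) {
    o <- order(time)
    time <- time[o]
    freq_shift <- lapply(freq_shift, function(x) as.numeric(x)[o])
    if (!is.null(dissipation)) {
      dissipation <- lapply(dissipation, function(x) as.numeric(x)[o])
    }
  } else {
    freq_shift <- lapply(freq_shift, as.numeric)
    if (!is.null(dissipation)) dissipation <- lapply(dissipation, as.numeric)
  }
  if (!is.na(concentration) && concentration <= 0) {
    stop("concentration must be > 0 (micromolar) when provided")
  }
  structure(list(run_id = run_id,
                 concentration = as.numeric(concentration),
                 time = time,
                 freq_shift = freq_shift,
                 dissipation = dissipation,
                 fundamental_hz = fundamental_hz),
            class = "adsorption_run")
}

#' @export
print.adsorption_run <- function(x, ...) {
  cat("<adsorption_run> ", x$run_id,
      if (!is.na(x$concentration)) sprintf(" (%g uM)", x$concentration),
      "\n", sep = "")
  cat("  samples:   ", length(x$time), " over ",
      format(diff(range(x$time))), " s\n", sep = "")
  cat("  overtones: ", paste(names(x$freq_shift), collapse = ", "), "\n",
      sep = "")
  cat("  dissipation: ", if (is.null(x$dissipation)) "absent" else "present",
      "\n", sep = "")
  invisible(x)
}

#' Reduced single-channel adsorption curve
#'
#' The analysis-ready observable: minus the overtone-averaged frequency shift
#' as a function of time (a rising curve for adsorption), baseline-zeroed at
#' its first sample unless constructed otherwise.
#'
#' @param run_id character label.
#' @param time sample times (s), strictly increasing.
#' @param response -(averaged frequency shift) in Hz.
#' @param concentration micromolar, or `NA`.
#' @param overtones_used integer vector of the overtone indices averaged.
#' @param normalized_by_overtone logical; were overtone shifts divided by
#'   their index before averaging.
#' @return Object of class `adsorption_curve`.
#' @export
adsorption_curve <- function(run_id, time, response,
                             concentration = NA_real_,
                             overtones_used = integer(),
                             normalized_by_overtone = FALSE) {
  time <- as.numeric(time)
  response <- as.numeric(response)
  if (length(time) != length(response)) {
    stop("time and response must have equal length")
  }
  if (is.unsorted(time, strictly = TRUE)) {
    stop("time must be strictly increasing")
  }
  structure(list(run_id = as.character(run_id),
                 concentration = as.numeric(concentration),
                 time = time,
                 response = response,
                 overtones_used = as.integer(overtones_used),
                 normalized_by_overtone = isTRUE(normalized_by_overtone)),
            class = "adsorption_curve")
}

#' @export
print.adsorption_curve <- function(x, ...) {
  cat("<adsorption_curve> ", x$run_id,
      if (!is.na(x$concentration)) sprintf(" (%g uM)", x$concentration),
      "\n", sep = "")
  cat("  samples: ", length(x$time), ", response range [",
      format(min(x$response)), ", ", format(max(x$response)), "] Hz\n",
      sep = "")
  if (length(x$overtones_used)) {
    cat("  overtones averaged: ", paste(x$overtones_used, collapse = ", "),
        if (x$normalized_by_overtone) " (overtone-normalized)", "\n",
        sep = "")
  }
  invisible(x)
}

# numeric conversion with a parse error naming the offending cell
.parse_numeric_col <- function(x, colname) {
  out <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(out) & !is.na(x) & trimws(x) != "" &
                 toupper(trimws(x)) != "NA")
  if (length(bad)) {
    stop("non-numeric value '", x[bad[1]], "' in column '", colname,
         "', data row ", bad[1])
  }
  out
}

#' Read QCM-D runs from a delimited text file
#'
#' Parses a headered delimited table into a collection of
#' [adsorption_run()] objects. Columns are resolved through the regexes in
#' `dialect`; a `run_id` column splits the file into several runs. Unmapped
#' columns are ignored with a warning. Time is converted to seconds and
#' dissipation to the natural scale per the dialect.
#'
#' @param path file path.
#' @param dialect a [qcm_dialect()].
#' @return Named list of `adsorption_run` objects.
#' @export
read_runs <- function(path, dialect = qcm_dialect()) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = dialect$sep,
                          check.names = FALSE, colClasses = "character",
                          stringsAsFactors = FALSE)
  nm <- names(df)
  time_col <- grep(dialect$time, nm, value = TRUE)
  if (length(time_col) == 0L) {
    stop("format error: no column matching time pattern '", dialect$time, "'")
  }
  time_col <- time_col[1]
  if (nrow(df) == 0L) return(list())
  fm <- regmatches(nm, regexec(dialect$freq, nm))
  freq_cols <- nm[lengths(fm) == 2L]
  freq_ot <- vapply(fm[lengths(fm) == 2L], function(m) m[2], character(1))
  dm <- regmatches(nm, regexec(dialect$diss, nm))
  diss_cols <- nm[lengths(dm) == 2L]
  diss_ot <- vapply(dm[lengths(dm) == 2L], function(m) m[2], character(1))
  run_col <- grep(dialect$run, nm, value = TRUE)[1]
  conc_col <- grep(dialect$conc, nm, value = TRUE)[1]
  if (length(freq_cols) == 0L) {
    stop("format error: no frequency-shift columns matching '",
         dialect$freq, "'")
  }
  mapped <- c(time_col, freq_cols, diss_cols,
              if (!is.na(run_col)) run_col, if (!is.na(conc_col)) conc_col)
  unmapped <- setdiff(nm, mapped)
  if (length(unmapped)) {
    warning("ignoring unmapped column(s): ", paste(unmapped, collapse = ", "))
  }
  if (nrow(df) == 0L) return(list())

  groups <- if (!is.na(run_col)) split(df, df[[run_col]]) else list(run1 = df)
  runs <- lapply(names(groups), function(id) {
    g <- groups[[id]]
    tt <- .parse_numeric_col(g[[time_col]], time_col) * dialect$time_scale
    fs <- stats::setNames(
      lapply(freq_cols, function(cn) .parse_numeric_col(g[[cn]], cn)),
      freq_ot)
    fs <- fs[!vapply(fs, function(x) all(is.na(x)), logical(1))]
    ds <- NULL
    if (length(diss_cols)) {
      ds <- stats::setNames(
        lapply(diss_cols, function(cn)
          .parse_numeric_col(g[[cn]], cn) * dialect$diss_scale),
        diss_ot)
      ds <- ds[!vapply(ds, function(x) all(is.na(x)), logical(1))]
      if (length(ds) == 0L) ds <- NULL
    }
    conc <- NA_real_
    if (!is.na(conc_col)) {
      cv <- unique(.parse_numeric_col(g[[conc_col]], conc_col))
      cv <- cv[!is.na(cv)]
      if (length(cv) > 1L) stop("run '", id, "' has multiple concentrations")
      if (length(cv)) conc <- cv
    }
    adsorption_run(run_id = id, time = tt, freq_shift = fs, dissipation = ds,
                   concentration = conc,
                   fundamental_hz = dialect$fundamental_hz)
  })
  stats::setNames(runs, vapply(runs, `[[`, character(1), "run_id"))
}

.fmt_num <- function(x) {
  out <- sprintf("%.15g", x)
  out[is.na(x)] <- ""
  out
}

#' Write QCM-D runs to a delimited text file
#'
#' Inverse of [read_runs()]: numeric fields are written at 15 significant
#' digits so that a write/read round trip preserves values to better than
#' 1e-12 relative error.
#'
#' @param runs list of [adsorption_run()] objects (possibly empty).
#' @param path output file path.
#' @param dialect a [qcm_dialect()]; time and dissipation are converted back
#'   to the dialect's file units.
#' @return `path`, invisibly.
#' @export
write_runs <- function(runs, path, dialect = qcm_dialect()) {
  if (length(runs) == 0L) {
    writeLines(paste("run_id", "time_s", sep = dialect$sep), path)
    return(invisible(path))
  }
  all_ot <- sort(unique(as.integer(unlist(
    lapply(runs, function(r) names(r$freq_shift))))))
  has_diss <- any(!vapply(runs, function(r) is.null(r$dissipation),
                          logical(1)))
  diss_ot <- if (has_diss) {
    sort(unique(as.integer(unlist(
      lapply(runs, function(r) names(r$dissipation))))))
  } else integer()
  has_conc <- any(!is.na(vapply(runs, `[[`, numeric(1), "concentration")))

  header <- c("run_id", if (has_conc) "concentration_uM", "time_s",
              paste0("f", all_ot), if (has_diss) paste0("D", diss_ot))
  lines <- paste(header, collapse = dialect$sep)
  for (r in runs) {
    n <- length(r$time)
    cols <- list(rep(r$run_id, n))
    if (has_conc) cols <- c(cols, list(.fmt_num(rep(r$concentration, n))))
    cols <- c(cols, list(.fmt_num(r$time / dialect$time_scale)))
    for (ot in all_ot) {
      v <- r$freq_shift[[as.character(ot)]]
      cols <- c(cols, list(if (is.null(v)) rep("", n) else .fmt_num(v)))
    }
    for (ot in diss_ot) {
      v <- r$dissipation[[as.character(ot)]]
      cols <- c(cols, list(if (is.null(v)) rep("", n)
                           else .fmt_num(v / dialect$diss_scale)))
    }
    lines <- c(lines, do.call(paste, c(cols, sep = dialect$sep)))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write a kinetic spectrum as a two-column text file
#'
#' Exports the spectrum in the conventional X/Y layout used to hand kinetic
#' spectra to peak-fitting software: X = log10 of the apparent rate constant,
#' Y = component weight, with the exact header
#' `log_k_obs<TAB>curve_weight`.
#'
#' @param spectrum a [kinetic_spectrum()] (or any list with `log_k_obs` and
#'   `curve_weight` of equal length).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_spectrum_xy <- function(spectrum, path) {
  x <- spectrum$log_k_obs
  y <- spectrum$curve_weight
  if (length(x) != length(y)) {
    stop("log_k_obs and curve_weight must have equal length")
  }
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    stop("spectrum values must be finite")
  }
  lines <- c("log_k_obs\tcurve_weight",
             paste(.fmt_num(x), .fmt_num(y), sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Read a two-column kinetic spectrum file
#'
#' @param path file written by [write_spectrum_xy()].
#' @return A [kinetic_spectrum()].
#' @export
read_spectrum_xy <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  if (!all(c("log_k_obs", "curve_weight") %in% names(df))) {
    stop("not a spectrum file (expected columns log_k_obs, curve_weight)")
  }
  kinetic_spectrum(log_k_obs = df$log_k_obs, curve_weight = df$curve_weight)
}
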