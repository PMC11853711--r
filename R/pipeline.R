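#' Run the full FRC analysis workflow
#'
#' Chains the analysis stages over a runs file: dissipation quality filter,
#' overtone averaging and representative-replicate selection per
#' concentration, FRC spectral fitting, spectrum export and Gaussian peak
#' deconvolution, and (when at least three concentrations survive) the Hill
#' cooperativity fit on the equilibrium plateaus. All outputs land under
#' `out_dir` together with a JSON manifest recording the configuration,
#' input hashes, package version and per-stage diagnostics; identical
#' inputs and configuration reproduce identical numerical outputs.
#'
#' @param input path to a delimited runs file readable by [read_runs()].
#' @param out_dir output directory (created if absent).
#' @param config list of options: `overtones` (default `c(5, 7, 9)`),
#'   `normalize_by_overtone` (default TRUE), `diss_threshold` (default
#'   0.5e-6), `fit` (a [fit_config()]), `n_peaks` (default `"auto"`),
#'   `background` (default `"none"`), `f_max` (default `"fit"`),
#'   `temperature` (default 298.15), `tail_fraction` (default 0.1).
#' @param dialect a [qcm_dialect()] for reading `input`.
#' @return The manifest, invisibly (also written to
#'   `out_dir/manifest.json`).
#' @export
run_pipeline <- function(input, out_dir, config = list(),
                         dialect = qcm_dialect()) {
  cfg <- utils::modifyList(
    list(overtones = c(5, 7, 9), normalize_by_overtone = TRUE,
         diss_threshold = 0.5e-6, fit = fit_config(), n_peaks = "auto",
         background = "none", f_max = "fit", temperature = 298.15,
         tail_fraction = 0.1),
    config)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  stages <- list()

  runs <- read_runs(input, dialect)
  if (length(runs) == 0L) stop("no runs in input file: ", input)

  ## stage 1: dissipation filter
  filt <- dissipation_filter(runs, threshold = cfg$diss_threshold)
  utils::write.table(filt$report,
                     file.path(out_dir, "filter_report.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  stages$dissipation_filter <- list(n_in = length(runs),
                                    n_kept = length(filt$kept))
  if (length(filt$kept) == 0L) stop("no runs survive the dissipation filter")

  ## stage 2: overtone averaging + representative selection
  curves <- lapply(filt$kept, average_overtones,
                   overtones = cfg$overtones,
                   normalize_by_overtone = cfg$normalize_by_overtone)
  conc <- vapply(curves, `[[`, numeric(1), "concentration")
  groups <- split(curves, conc)
  reps <- lapply(groups, function(g) {
    select_representative(unname(g), resample = TRUE)
  })
  sel_df <- do.call(rbind, lapply(reps, function(s) {
    data.frame(concentration = s$concentration,
               chosen_run_id = s$chosen_run_id,
               rmsd = s$rmsd_by_run[[s$chosen_run_id]])
  }))
  utils::write.table(sel_df, file.path(out_dir, "representatives.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  stages$representative_selection <- list(n_concentrations = length(reps))

  ## stage 3: FRC fit per representative curve
  fits <- list()
  spectra <- list()
  fit_rows <- list()
  for (key in names(reps)) {
    cv <- reps[[key]]$chosen
    m <- fit_frc(cv, cfg$fit)
    fits[[key]] <- m
    sp <- extract_spectrum(m, concentration = cv$concentration)
    spectra[[key]] <- sp
    tag <- gsub("[^0-9A-Za-z.]+", "_", key)
    write_model(m, file.path(out_dir, paste0("model_", tag, ".json")))
    write_spectrum_xy(sp, file.path(out_dir,
                                    paste0("spectrum_", tag, ".tsv")))
    fit_rows[[key]] <- data.frame(
      concentration = cv$concentration,
      rmsd = m$diagnostics$rmsd,
      n_active = model_summary(m)$n_active,
      asymptote = model_summary(m)$asymptote)
  }
  utils::write.table(do.call(rbind, fit_rows),
                     file.path(out_dir, "fit_summary.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  stages$frc_fit <- list(n_fits = length(fits))

  ## stage 4: peak deconvolution
  decon <- lapply(spectra, function(sp) {
    if (sum(sp$curve_weight) == 0) return(NULL)
    d <- deconvolve(sp, n_peaks = cfg$n_peaks, background = cfg$background)
    list(concentration = sp$concentration, peaks = d$peaks,
         residual_rmsd = d$residual_rmsd)
  })
  jsonlite::write_json(decon[!vapply(decon, is.null, logical(1))],
                       file.path(out_dir, "deconvolution.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  stages$deconvolution <- list(
    n_spectra = sum(!vapply(decon, is.null, logical(1))))

  ## stage 5: Hill analysis on equilibrium plateaus
  plateaus <- do.call(rbind, lapply(reps, function(s) {
    p <- plateau_estimate(s$chosen, tail_fraction = cfg$tail_fraction)
    data.frame(concentration = s$concentration, response = p$value,
               converged = p$converged)
  }))
  if (nrow(plateaus) >= 3) {
    hf <- hill_fit(plateaus[, c("concentration", "response")],
                   f_max = cfg$f_max, T = cfg$temperature)
    jsonlite::write_json(
      list(n = hf$n, K_eq = hf$K_eq, delta_G = hf$delta_G,
           f_max = hf$f_max, temperature = hf$T,
           r_squared = hf$r_squared, points_used = hf$points_used),
      file.path(out_dir, "hill.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
    stages$hill <- list(n = hf$n, K_eq = hf$K_eq, delta_G = hf$delta_G)
  } else {
    stages$hill <- list(skipped = "fewer than 3 concentrations")
  }

  manifest <- list(package_version =
                     as.character(utils::packageVersion("frckit")),
                   input = normalizePath(input),
                   input_md5 = unname(tools::md5sum(input)),
                   config = list(overtones = cfg$overtones,
                                 normalize_by_overtone =
                                   cfg$normalize_by_overtone,
                                 diss_threshold = cfg$diss_threshold,
                                 n_peaks = cfg$n_peaks,
                                 background = cfg$background,
                                 f_max = cfg$f_max,
                                 temperature = cfg$temperature,
                                 tail_fraction = cfg$tail_fraction,
                                 fit = unclass(cfg$fit)),
                   stages = stages)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(manifest)
}
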