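#' Configuration for the synthetic fingerprint generator
#'
#' The generator emulates a calibrated MALDI-TOF collagen fingerprint: the
#' marker peaks of one panel taxon plus a rich collagen "background" of
#' non-diagnostic peptide peaks, with configurable mass error, calibration
#' drift, intensity decay with m/z, and (in profile mode) Gaussian peak
#' shapes over a uniform grid with additive baseline noise.
#'
#' Background peaks are drawn uniformly over `mz_range` but excluded from
#' +/-2 Da around every reference mass of every panel taxon (and the
#' conserved vertebrate counterpart), so ground-truth labels stay
#' unambiguous; set `adversarial = TRUE` to lift the exclusion and place
#' near-marker decoys for stress testing.
#'
#' @param taxon A panel taxon name, or `"background-only"`.
#' @param markers_present `"all"` or an integer vector of slot indices to
#'   include.
#' @param background_peaks Number of background collagen peaks (default 40,
#'   emulating the ~60-80 peptides of a typical partial collagen
#'   fingerprint).
#' @param mass_error_sd Gaussian mass error SD in Da applied to every peak.
#' @param calibration_drift Length-2 numeric `c(slope, intercept)`: observed
#'   m/z = slope * true m/z + intercept (identity `c(1, 0)` by default).
#' @param peak_fwhm Peak full width at half maximum in Da at m/z 2000;
#'   scales linearly with m/z (constant resolving power).
#' @param snr_range Interval from which per-peak S/N is drawn log-uniformly
#'   before the m/z decay is applied.
#' @param noise_sd Baseline noise SD in intensity units (profile mode); also
#'   the reference level converting S/N to amplitude.
#' @param baseline_level Constant baseline offset (intensity units) under a
#'   profile trace, keeping the detector-positive trace from clipping the
#'   noise distribution.
#' @param decay_scale e-folding scale (Da) of the intensity decay with m/z.
#' @param mz_range Acquisition range in Da.
#' @param grid_step Profile grid spacing in Da.
#' @param adversarial Lift the background exclusion zones.
#' @param seed Optional integer seed; fixed seed implies identical output.
#' @return A `sim_config` list.
#' @export
sim_config <- function(taxon = "background-only", markers_present = "all",
                       background_peaks = 40, mass_error_sd = 0.05,
                       calibration_drift = c(1, 0), peak_fwhm = 0.25,
                       snr_range = c(5, 50), noise_sd = 1,
                       baseline_level = 10, decay_scale = 2700,
                       mz_range = c(800, 3500), grid_step = 0.05,
                       adversarial = FALSE, seed = NULL) {
  stopifnot(
    background_peaks >= 0, mass_error_sd >= 0, length(calibration_drift) == 2,
    peak_fwhm > 0, length(snr_range) == 2, all(snr_range > 0),
    snr_range[2] >= snr_range[1], noise_sd >= 0, baseline_level >= 0,
    decay_scale > 0,
    length(mz_range) == 2, mz_range[2] > mz_range[1], grid_step > 0
  )
  structure(
    list(taxon = taxon, markers_present = markers_present,
         background_peaks = background_peaks, mass_error_sd = mass_error_sd,
         calibration_drift = calibration_drift, peak_fwhm = peak_fwhm,
         snr_range = snr_range, noise_sd = noise_sd,
         baseline_level = baseline_level,
         decay_scale = decay_scale, mz_range = mz_range,
         grid_step = grid_step, adversarial = adversarial, seed = seed),
    class = "sim_config"
  )
}

with_optional_seed <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(seed, code)
}

#' Simulate one labelled MALDI fingerprint
#'
#' @param config A [sim_config()].
#' @param panel A [marker_panel()] supplying marker masses and exclusion
#'   zones.
#' @param mode `"centroid"` or `"profile"`.
#' @param spectrum_id Identifier for the generated spectrum.
#' @return A list with elements `spectrum` (a `maldi_spectrum`), `taxon`
#'   (the ground-truth label) and `truth` (tibble of true peaks: `type`,
#'   `slot`, `true_mz`, `observed_mz`, `amplitude`, `snr`).
#' @export
simulate_spectrum <- function(config, panel = default_panel(),
                              mode = c("centroid", "profile"),
                              spectrum_id = "simulated") {
  stopifnot(inherits(config, "sim_config"))
  mode <- match.arg(mode)
  known <- c("background-only", panel$taxa$taxon)
  if (!config$taxon %in% known) {
    abort(sprintf("unknown taxon '%s'; panel taxa are: %s", config$taxon,
                  paste(panel$taxa$taxon, collapse = ", ")))
  }
  with_optional_seed(config$seed, {
    truth <- sim_true_peaks(config, panel)
    spectrum <- render_spectrum(truth, config, mode, spectrum_id)
    list(spectrum = spectrum, taxon = config$taxon, truth = truth)
  })
}

sim_true_peaks <- function(config, panel) {
  long <- panel_long(panel)
  marker <- tibble(type = character(), slot = integer(), true_mz = numeric())
  if (config$taxon != "background-only") {
    rows <- long[long$taxon == config$taxon, ]
    if (!identical(config$markers_present, "all")) {
      rows <- rows[rows$slot %in% config$markers_present, ]
    }
    marker <- tibble(type = "marker", slot = rows$slot,
                     true_mz = rows$reference_mz)
  }
  bg <- numeric(0)
  if (config$background_peaks > 0) {
    excl <- if (config$adversarial) numeric(0) else panel_masses(panel)
    bg <- draw_excluded_uniform(config$background_peaks, config$mz_range,
                                excl, halfwidth = 2)
  }
  truth <- dplyr::bind_rows(
    marker,
    tibble(type = rep("background", length(bg)), slot = NA_integer_,
           true_mz = bg)
  )
  drift <- config$calibration_drift
  truth$observed_mz <- drift[[1]] * truth$true_mz + drift[[2]] +
    rnorm(nrow(truth), 0, config$mass_error_sd)
  decay <- exp(-(truth$true_mz - config$mz_range[[1]]) / config$decay_scale)
  log_snr <- runif(nrow(truth), log(config$snr_range[[1]]),
                   log(config$snr_range[[2]]))
  truth$snr <- exp(log_snr) * decay
  noise_ref <- if (config$noise_sd > 0) config$noise_sd else 1
  truth$amplitude <- truth$snr * noise_ref
  dplyr::arrange(truth, .data$observed_mz)
}

draw_excluded_uniform <- function(n, range, excluded, halfwidth) {
  out <- numeric(0)
  guard <- 0
  while (length(out) < n && guard < 1000) {
    guard <- guard + 1
    x <- runif(n - length(out), range[[1]], range[[2]])
    if (length(excluded) > 0) {
      keep <- vapply(x, function(xi) all(abs(xi - excluded) > halfwidth),
                     logical(1))
      x <- x[keep]
    }
    out <- c(out, x)
  }
  if (length(out) < n) abort("could not draw background peaks outside the exclusion zones")
  out
}

render_spectrum <- function(truth, config, mode, spectrum_id) {
  meta <- list(simulated = TRUE, taxon = config$taxon)
  if (mode == "centroid") {
    pts <- tibble(mz = truth$observed_mz, intensity = truth$amplitude,
                  snr = truth$snr)
    return(new_spectrum(pts, mode = "centroid", spectrum_id = spectrum_id,
                        metadata = meta))
  }
  pad <- 20
  grid <- seq(config$mz_range[[1]] - pad, config$mz_range[[2]] + pad,
              by = config$grid_step)
  signal <- rep(config$baseline_level, length(grid))
  for (i in seq_len(nrow(truth))) {
    mu <- truth$observed_mz[[i]]
    sigma <- (config$peak_fwhm * mu / 2000) / 2.35482
    lo <- findInterval(mu - 6 * sigma, grid)
    hi <- findInterval(mu + 6 * sigma, grid) + 1L
    idx <- max(1L, lo):min(length(grid), hi)
    signal[idx] <- signal[idx] +
      truth$amplitude[[i]] * exp(-(grid[idx] - mu)^2 / (2 * sigma^2))
  }
  if (config$noise_sd > 0) {
    signal <- signal + rnorm(length(grid), 0, config$noise_sd)
  }
  signal[signal < 0] <- 0
  new_spectrum(tibble(mz = grid, intensity = signal), mode = "profile",
               spectrum_id = spectrum_id, metadata = meta)
}

#' Simulate a calibrant-spot spectrum
#'
#' Renders the calibrant panel peptides as a centroid spectrum under the same
#' drift/error model as [simulate_spectrum()], for exercising external
#' calibration end to end.
#'
#' @param config A [sim_config()] (its `calibration_drift` and
#'   `mass_error_sd` apply; the taxon and background settings are ignored).
#' @param calibrants A [calibrant_panel()].
#' @return A centroid `maldi_spectrum`.
#' @export
simulate_calibrant_spectrum <- function(config, calibrants = calibrant_panel()) {
  stopifnot(inherits(config, "sim_config"))
  with_optional_seed(config$seed, {
    drift <- config$calibration_drift
    mz <- drift[[1]] * calibrants$reference_mz + drift[[2]] +
      rnorm(nrow(calibrants), 0, config$mass_error_sd)
    new_spectrum(
      tibble(mz = mz, intensity = 100, snr = 100),
      mode = "centroid", spectrum_id = "calibrant-spot",
      metadata = list(simulated = TRUE, calibrants = TRUE)
    )
  })
}

#' Simulate a labelled batch of fingerprints on disk
#'
#' Writes `n_per_taxon` spectra for each requested taxon as peak-list (or
#' mzML) files plus a batch manifest and a ground-truth table, ready for
#' [screen_batch()].
#'
#' @param n_per_taxon Spectra per taxon (>= 1).
#' @param out_dir Output directory (created if needed).
#' @param config A [sim_config()] template; per-spectrum seeds are derived
#'   from `seed`.
#' @param panel A [marker_panel()].
#' @param taxa Taxa to simulate (default: all panel taxa).
#' @param format `"peaklist"` or `"mzml"`.
#' @param mode `"centroid"` or `"profile"`.
#' @param seed Integer seed making the whole batch reproducible.
#' @param overwrite Overwrite existing files in `out_dir`?
#' @return A list with `manifest` (tibble, also written to
#'   `manifest.csv`), `truth` (tibble, also written to `truth.csv`) and
#'   `dir`.
#' @export
simulate_batch <- function(n_per_taxon, out_dir, config = sim_config(),
                           panel = default_panel(), taxa = panel$taxa$taxon,
                           format = c("peaklist", "mzml"),
                           mode = c("centroid", "profile"),
                           seed = 1, overwrite = FALSE) {
  stopifnot(n_per_taxon >= 1)
  format <- match.arg(format)
  mode <- match.arg(mode)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ext <- if (format == "peaklist") "txt" else "mzML"
  grid <- tidyr::expand_grid(taxon = taxa, rep = seq_len(n_per_taxon))
  grid$spectrum_id <- sprintf("%s_%03d", gsub("[^A-Za-z0-9]+", "_", grid$taxon),
                              grid$rep)
  grid$file <- file.path(out_dir, paste0(grid$spectrum_id, ".", ext))
  clash <- file.exists(grid$file)
  if (any(clash) && !overwrite) {
    abort(sprintf("output file '%s' already exists (use overwrite = TRUE)",
                  grid$file[clash][[1]]))
  }
  rank_of <- setNames(panel$taxa$rank, panel$taxa$taxon)
  withr::with_seed(seed, {
    for (i in seq_len(nrow(grid))) {
      cfg <- config
      cfg$taxon <- grid$taxon[[i]]
      cfg$seed <- NULL  # one sequential stream governed by `seed`
      sim <- simulate_spectrum(cfg, panel, mode = mode,
                               spectrum_id = grid$spectrum_id[[i]])
      sp <- sim$spectrum
      if (format == "peaklist") {
        if (spectrum_mode(sp) == "profile") {
          abort("profile spectra must be written as mzML, not peak lists")
        }
        write_peaklist(sp, grid$file[[i]])
      } else {
        write_mzml(sp, grid$file[[i]])
      }
    }
  })
  truth <- tibble(
    spectrum_id = grid$spectrum_id,
    taxon = grid$taxon,
    resolution = dplyr::if_else(grid$taxon %in% names(rank_of),
                                unname(rank_of[grid$taxon]), "none"),
    file = grid$file
  )
  manifest <- tibble(spectrum_id = grid$spectrum_id, path = grid$file,
                     accession = grid$spectrum_id)
  readr::write_csv(truth, file.path(out_dir, "truth.csv"))
  readr::write_csv(manifest, file.path(out_dir, "manifest.csv"))
  list(manifest = manifest, truth = truth, dir = out_dir)
}
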