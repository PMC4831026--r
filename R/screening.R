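#' Batch-screen a set of spectra
#'
#' Runs the full pipeline over a batch manifest: read each spectrum, pick
#' peaks if it is a profile trace, optionally apply an external calibration
#' fit, apply the quality gate, and classify the survivors against the
#' marker panel. Every manifest row is accounted for exactly once as a
#' quality pass, a quality fail, or a read error; unreadable files never
#' abort the batch.
#'
#' @param manifest A manifest tibble (columns `spectrum_id`, `path`,
#'   `accession`) or the path to a manifest CSV (see [read_manifest()]).
#' @param panel A [marker_panel()].
#' @param criterion A [quality_criterion()].
#' @param calibration Optional `calibration_fit` from [recalibrate()] on a
#'   calibrant-spot spectrum, applied to every sample spectrum before
#'   gating. `NULL` skips calibration.
#' @param tolerance Marker-match tolerance in Da.
#' @param min_markers,margin Classifier thresholds, see [classify()].
#' @param min_snr,window Peak-picking settings for profile spectra.
#' @param verbose Emit one message per spectrum.
#' @return An object of class `screen_report`: a list with `results` (one
#'   row per input spectrum) and `summary` (totals and per-taxon counts).
#'   [tidy()] returns the per-spectrum rows, [glance()] the summary.
#' @export
screen_batch <- function(manifest, panel = default_panel(),
                         criterion = quality_criterion(),
                         calibration = NULL, tolerance = 0.5,
                         min_markers = 4, margin = 1, min_snr = 3,
                         window = 100, verbose = FALSE) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  manifest <- as_tibble(manifest)
  need <- c("spectrum_id", "path", "accession")
  missing <- setdiff(need, names(manifest))
  if (length(missing) > 0) {
    abort(paste0("manifest is missing column(s): ", paste(missing, collapse = ", ")))
  }
  results <- purrr::map_dfr(seq_len(nrow(manifest)), function(i) {
    row <- manifest[i, ]
    base <- tibble(
      spectrum_id = row$spectrum_id, accession = row$accession,
      status = "ok", quality_pass = NA, n_qualifying = NA_integer_,
      label = NA_character_, resolution = NA_character_,
      score = NA_integer_, murine_candidate = NA,
      matched_slots = NA_character_, error = NA_character_
    )
    out <- tryCatch({
      sp <- read_any_spectrum(row$path)
      if (spectrum_mode(sp) == "profile") {
        sp <- pick_peaks(sp, min_snr = min_snr, window = window)
      }
      if (!is.null(calibration)) sp <- apply_calibration(sp, calibration)
      qc <- passes_quality(sp, criterion)
      base$quality_pass <- qc$pass
      base$n_qualifying <- qc$n_qualifying
      base$status <- if (qc$pass) "pass" else "fail"
      if (qc$pass) {
        asg <- classify(sp, panel, tolerance = tolerance,
                        min_markers = min_markers, margin = margin)
        base$label <- asg$label
        base$resolution <- asg$resolution
        base$score <- asg$score
        base$murine_candidate <- asg$murine_candidate
        base$matched_slots <- paste(sort(asg$matched$slot), collapse = ";")
      }
      base
    }, error = function(e) {
      base$status <- "read_error"
      base$error <- conditionMessage(e)
      base
    })
    if (verbose) {
      message(sprintf("[%d/%d] %s: %s%s", i, nrow(manifest), row$spectrum_id,
                      out$status,
                      if (!is.na(out$label)) paste0(" -> ", out$label) else ""))
    }
    out
  })
  if (nrow(results) == 0) {
    results <- tibble(
      spectrum_id = character(), accession = character(), status = character(),
      quality_pass = logical(), n_qualifying = integer(), label = character(),
      resolution = character(), score = integer(), murine_candidate = logical(),
      matched_slots = character(), error = character()
    )
  }
  positives <- results[!is.na(results$label) &
                         results$label != "indeterminate", ]
  counts <- if (nrow(positives) > 0) {
    dplyr::count(positives, .data$label, .data$resolution, name = "n")
  } else {
    tibble(label = character(), resolution = character(), n = integer())
  }
  summary <- list(
    n_input = nrow(manifest),
    n_read_error = sum(results$status == "read_error"),
    n_good_quality = sum(results$status == "pass"),
    n_fail_quality = sum(results$status == "fail"),
    n_murine_candidate = sum(results$murine_candidate %in% TRUE),
    taxon_counts = counts
  )
  structure(list(results = results, summary = summary),
            class = "screen_report")
}

# Dispatch on file extension; mzML files may hold several scans but a
# screening manifest points at single-spectrum acquisitions, so take scan 1.
read_any_spectrum <- function(path) {
  if (grepl("\\.mzml$", path, ignore.case = TRUE)) {
    read_mzml(path)[[1]]
  } else {
    read_peaklist(path)
  }
}

#' @export
print.screen_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "<screen_report> %d spectra: %d good quality, %d failed gate, %d read errors\n",
    s$n_input, s$n_good_quality, s$n_fail_quality, s$n_read_error))
  if (nrow(s$taxon_counts) > 0) {
    print(s$taxon_counts)
  } else {
    cat("no taxa assigned\n")
  }
  invisible(x)
}

#' @rdname screen_batch
#' @param x A `screen_report`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.screen_report <- function(x, ...) x$results

#' @rdname screen_batch
#' @exportS3Method generics::glance
glance.screen_report <- function(x, ...) {
  s <- x$summary
  tibble(
    n_input = s$n_input, n_read_error = s$n_read_error,
    n_good_quality = s$n_good_quality, n_fail_quality = s$n_fail_quality,
    n_murine_candidate = s$n_murine_candidate,
    n_assigned = sum(s$taxon_counts$n)
  )
}

#' Write a screen report to disk
#'
#' @param report A `screen_report`.
#' @param dir Output directory; writes `report.csv` (per-spectrum rows) and
#'   `summary.json`.
#' @return `dir`, invisibly.
#' @export
write_screen_report <- function(report, dir) {
  stopifnot(inherits(report, "screen_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(report$results, file.path(dir, "report.csv"), na = "")
  s <- report$summary
  s$taxon_counts <- as.data.frame(s$taxon_counts)
  jsonlite::write_json(s, file.path(dir, "summary.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a specimen metadata table
#'
#' Specimen records carry the accession code, the original morphological
#' identification, and the excavation-grid find location: westing and
#' northing (grid units) and depth, which is either centimetres below the
#' site datum or a named stratum such as `"flowstone"`.
#'
#' @param path Path to a CSV with columns `accession`, `morphological_id`,
#'   `westing`, `northing`, `depth`.
#' @return A tibble with those columns (depth kept as character) plus
#'   `depth_cm`, the numeric depth (NA for named strata).
#' @export
read_specimens <- function(path) {
  sp <- readr::read_csv(path, show_col_types = FALSE,
                        col_types = readr::cols(.default = readr::col_character()))
  need <- c("accession", "morphological_id", "westing", "northing", "depth")
  missing <- setdiff(need, names(sp))
  if (length(missing) > 0) {
    abort(paste0("specimen table is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  if (anyDuplicated(sp$accession)) {
    abort(sprintf("duplicate accession in specimen table: '%s'",
                  sp$accession[duplicated(sp$accession)][[1]]))
  }
  sp$westing <- as.numeric(sp$westing)
  sp$northing <- as.numeric(sp$northing)
  sp$depth_cm <- suppressWarnings(as.numeric(sp$depth))
  sp[c(need, "depth_cm")]
}

#' The bundled Pin Hole Cave specimen table
#'
#' Accession codes, original morphological identifications and excavation
#' find locations of the 24 myomorph-positive Pin Hole Cave specimens, used
#' as a worked example for the spatial join.
#'
#' @return A specimen tibble, see [read_specimens()].
#' @export
pinhole_specimens <- function() {
  read_specimens(system.file("extdata", "pinhole_specimens.csv",
                             package = "zoomscreen", mustWork = TRUE))
}

#' Join screening positives to specimen find locations
#'
#' @param report A `screen_report`.
#' @param specimens A specimen tibble from [read_specimens()].
#' @return An object of class `spatial_summary`: a list with `positives`
#'   (one row per positively assigned spectrum with westing/northing/depth)
#'   and `unmatched` (accessions of positives absent from the specimen
#'   table).
#' @export
spatial_summary <- function(report, specimens) {
  stopifnot(inherits(report, "screen_report"))
  specimens <- as_tibble(specimens)
  pos <- report$results[!is.na(report$results$label) &
                          report$results$label != "indeterminate", ]
  pos <- pos[c("spectrum_id", "accession", "label", "resolution", "score")]
  matched <- dplyr::inner_join(pos, specimens, by = "accession")
  unmatched <- pos[!pos$accession %in% specimens$accession, ]
  structure(list(positives = matched, unmatched = unmatched),
            class = "spatial_summary")
}

#' @export
print.spatial_summary <- function(x, ...) {
  cat(sprintf("<spatial_summary> %d located positive(s), %d unmatched accession(s)\n",
              nrow(x$positives), nrow(x$unmatched)))
  if (nrow(x$positives) > 0) print(x$positives)
  invisible(x)
}

#' Plot located positive finds on the excavation grid
#'
#' One point per located positive, on westing/northing axes, coloured by
#' numeric depth where available (named strata are shown as unfilled
#' points).
#'
#' @param object A `spatial_summary`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.spatial_summary <- function(object, ...) {
  df <- object$positives
  ggplot2::ggplot(df, ggplot2::aes(x = .data$westing, y = .data$northing)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$depth_cm), size = 3) +
    ggplot2::scale_colour_viridis_c(na.value = "grey40",
                                    name = "depth (cm)") +
    ggplot2::labs(x = "westing", y = "northing",
                  title = "Positive finds on the excavation grid") +
    ggplot2::theme_minimal()
}
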