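#' Construct a MALDI spectrum
#'
#' A spectrum is a tibble of points with package metadata attached: `mz` and
#' `intensity` columns for a profile trace, plus an `snr` column for a
#' centroided peak list (NA allowed until noise has been estimated). Rows are
#' kept strictly ascending in m/z; duplicate m/z values are merged by summing
#' intensity.
#'
#' @param points A data frame with columns `mz`, `intensity` and optionally
#'   `snr`.
#' @param mode `"centroid"` or `"profile"`.
#' @param spectrum_id Identifier string.
#' @param metadata Named list of acquisition metadata (accession code, plate
#'   well, notes ...).
#' @return A tibble of class `maldi_spectrum`.
#' @examples
#' s <- new_spectrum(data.frame(mz = c(1443.7, 1203.7), intensity = c(10, 5)),
#'                   mode = "centroid", spectrum_id = "demo")
#' spectrum_mode(s)
#' @export
new_spectrum <- function(points, mode = c("centroid", "profile"),
                         spectrum_id = "spectrum", metadata = list()) {
  mode <- match.arg(mode)
  points <- as_tibble(points)
  if (!all(c("mz", "intensity") %in% names(points))) {
    abort("`points` must have columns `mz` and `intensity`")
  }
  if (nrow(points) == 0) abort("a spectrum must contain at least one point")
  if (!is.numeric(points$mz) || !is.numeric(points$intensity)) {
    abort("`mz` and `intensity` must be numeric")
  }
  if (any(!is.finite(points$mz)) || any(points$mz <= 0)) {
    abort("all m/z values must be finite and > 0")
  }
  if (any(!is.finite(points$intensity)) || any(points$intensity < 0)) {
    abort("all intensities must be finite and >= 0")
  }
  if (mode == "centroid" && !"snr" %in% names(points)) {
    points$snr <- NA_real_
  }
  if ("snr" %in% names(points) && any(points$snr < 0, na.rm = TRUE)) {
    abort("`snr` must be >= 0")
  }
  points <- dplyr::arrange(points, .data$mz)
  if (anyDuplicated(points$mz)) {
    points <- dplyr::summarise(
      dplyr::group_by(points, .data$mz),
      intensity = sum(.data$intensity),
      dplyr::across(dplyr::any_of("snr"), max),
      .groups = "drop"
    )
  }
  cols <- intersect(c("mz", "intensity", "snr"), names(points))
  points <- points[cols]
  structure(
    points,
    class = c("maldi_spectrum", class(tibble())),
    mode = mode,
    spectrum_id = spectrum_id,
    metadata = metadata
  )
}

#' @rdname new_spectrum
#' @param x A `maldi_spectrum`.
#' @export
spectrum_mode <- function(x) attr(x, "mode")

#' @rdname new_spectrum
#' @export
spectrum_id <- function(x) attr(x, "spectrum_id")

#' @rdname new_spectrum
#' @export
spectrum_metadata <- function(x) attr(x, "metadata")

is_spectrum <- function(x) inherits(x, "maldi_spectrum")

assert_spectrum <- function(x, mode = NULL) {
  if (!is_spectrum(x)) abort("expected a `maldi_spectrum` object")
  if (!is.null(mode) && spectrum_mode(x) != mode) {
    abort(sprintf("expected a %s spectrum but got %s", mode, spectrum_mode(x)))
  }
  invisible(x)
}

# Rebuild a spectrum from transformed points, keeping identity metadata.
replace_points <- function(spectrum, points, mode = spectrum_mode(spectrum)) {
  new_spectrum(points, mode = mode, spectrum_id = spectrum_id(spectrum),
               metadata = spectrum_metadata(spectrum))
}

#' @export
print.maldi_spectrum <- function(x, ...) {
  cat(sprintf("<maldi_spectrum '%s'> %s, %d %s, m/z %.1f..%.1f\n",
              spectrum_id(x), spectrum_mode(x), nrow(x),
              if (spectrum_mode(x) == "centroid") "peaks" else "points",
              min(x$mz), max(x$mz)))
  NextMethod()
}

#' Plot a spectrum
#'
#' Profile spectra are drawn as a continuous trace, centroid spectra as
#' vertical sticks.
#'
#' @param object A `maldi_spectrum`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.maldi_spectrum <- function(object, ...) {
  df <- as_tibble(as.data.frame(object))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$mz, y = .data$intensity))
  if (spectrum_mode(object) == "profile") {
    p <- p + ggplot2::geom_line(linewidth = 0.3)
  } else {
    p <- p + ggplot2::geom_segment(
      ggplot2::aes(xend = .data$mz, yend = 0), linewidth = 0.4
    )
  }
  p + ggplot2::labs(x = "m/z", y = "intensity", title = spectrum_id(object)) +
    ggplot2::theme_minimal()
}
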