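#' Spectral quality criterion for collagen fingerprints
#'
#' A fingerprint is considered good enough for taxonomic investigation when
#' it shows *more than* `min_peak_count` peaks above `mz_floor` with
#' signal-to-noise *greater than* `min_snr`. Both inequalities are strict:
#' with the defaults, exactly 10 qualifying peaks fails and 11 passes, and a
#' peak at S/N exactly 3 does not qualify.
#'
#' @param min_peak_count Count threshold (default 10; strict greater-than).
#' @param mz_floor m/z floor in Da (default 2000; strict greater-than).
#' @param min_snr S/N threshold (default 3; strict greater-than).
#' @return An object of class `quality_criterion`.
#' @export
quality_criterion <- function(min_peak_count = 10, mz_floor = 2000,
                              min_snr = 3) {
  if (min_peak_count <= 0 || mz_floor <= 0 || min_snr <= 0) {
    abort("all quality thresholds must be strictly positive")
  }
  structure(
    list(min_peak_count = min_peak_count, mz_floor = mz_floor,
         min_snr = min_snr),
    class = "quality_criterion"
  )
}

#' @export
print.quality_criterion <- function(x, ...) {
  cat(sprintf("<quality_criterion> > %d peaks with m/z > %g and S/N > %g\n",
              x$min_peak_count, x$mz_floor, x$min_snr))
  invisible(x)
}

#' Apply the quality gate to a centroided spectrum
#'
#' @param spectrum A centroid `maldi_spectrum` with `snr` populated on every
#'   peak (pick peaks first, or supply three-column peak lists).
#' @param criterion A [quality_criterion()].
#' @return A one-row tibble with columns `pass` (logical) and `n_qualifying`
#'   (count of peaks clearing both the m/z floor and the S/N threshold).
#' @examples
#' s <- new_spectrum(data.frame(mz = 2000 + 1:11, intensity = 1, snr = 4),
#'                   mode = "centroid")
#' passes_quality(s)
#' @export
passes_quality <- function(spectrum, criterion = quality_criterion()) {
  assert_spectrum(spectrum, mode = "centroid")
  stopifnot(inherits(criterion, "quality_criterion"))
  if (nrow(spectrum) > 0 && any(is.na(spectrum$snr))) {
    abort(paste0(
      "spectrum '", spectrum_id(spectrum), "' has peaks without S/N; ",
      "run pick_peaks() or supply a three-column peak list"
    ))
  }
  n_qual <- sum(spectrum$mz > criterion$mz_floor &
                  spectrum$snr > criterion$min_snr)
  tibble(pass = n_qual > criterion$min_peak_count, n_qualifying = n_qual)
}
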