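## Shared baseline/noise machinery for profile traces.
##
## Baseline: running median over `baseline_k` points (wide relative to any
## peak, so peaks are treated as outliers). Noise: per m/z window, the
## MAD (x1.4826) of the baseline-subtracted residuals -- robust to the
## presence of peaks as long as they occupy a minority of points per window.

profile_baseline <- function(spectrum, baseline_k = 151) {
  n <- nrow(spectrum)
  k <- min(baseline_k, if (n %% 2 == 1) n else n - 1)
  if (k %% 2 == 0) k <- k - 1
  if (k < 3) return(rep(stats::median(spectrum$intensity), n))
  as.numeric(runmed(spectrum$intensity, k, endrule = "median"))
}

#' Estimate the noise level of a profile spectrum
#'
#' Noise is estimated per m/z window as 1.4826 times the median absolute
#' deviation of the intensities after removal of a running-median baseline,
#' giving a piecewise-constant noise function of m/z that is robust to the
#' peaks themselves.
#'
#' @param spectrum A profile `maldi_spectrum` with at least 50 points.
#' @param window Window width in Da (default 100). If the spectrum spans less
#'   than one window a single global estimate is returned.
#' @param baseline_k Running-median width in points for baseline removal.
#' @return An object of class `noise_profile`: a tibble with columns
#'   `mz_lo`, `mz_hi`, `noise`. Evaluate it at arbitrary m/z with
#'   [noise_at()].
#' @export
estimate_noise <- function(spectrum, window = 100, baseline_k = 151) {
  assert_spectrum(spectrum, mode = "profile")
  if (nrow(spectrum) < 50) {
    abort("noise estimation needs a profile trace of at least 50 points")
  }
  if (window <= 0) abort("`window` must be positive")
  resid <- spectrum$intensity - profile_baseline(spectrum, baseline_k)
  span <- range(spectrum$mz)
  breaks <- seq(span[1], span[2], by = window)
  if (length(breaks) < 2 || max(breaks) < span[2]) {
    breaks <- c(breaks, span[2])
  }
  idx <- findInterval(spectrum$mz, breaks, rightmost.closed = TRUE)
  global <- mad(resid)
  out <- purrr::map_dfr(seq_len(length(breaks) - 1), function(i) {
    in_win <- idx == i
    tibble(
      mz_lo = breaks[i], mz_hi = breaks[i + 1],
      noise = if (sum(in_win) >= 10) mad(resid[in_win]) else global
    )
  })
  structure(out, class = c("noise_profile", class(tibble())), global = global)
}

#' Evaluate a noise profile at given m/z values
#'
#' @param noise A `noise_profile` from [estimate_noise()].
#' @param mz Numeric vector of m/z values.
#' @return Numeric vector of noise levels (piecewise constant; values outside
#'   the estimated range take the nearest window's level).
#' @export
noise_at <- function(noise, mz) {
  stopifnot(inherits(noise, "noise_profile"))
  i <- findInterval(mz, noise$mz_lo)
  i[i < 1] <- 1L
  i[i > nrow(noise)] <- nrow(noise)
  noise$noise[i]
}

#' Pick centroided peaks from a profile spectrum
#'
#' Detects local maxima of the baseline-subtracted signal that exceed
#' `min_snr` times the local noise level, then centroids each peak as the
#' intensity-weighted mean m/z over the contiguous region above half of the
#' apex signal. The reported peak intensity is the apex signal and its S/N is
#' apex signal divided by local noise. The whole procedure is invariant to
#' rescaling the trace by a positive constant.
#'
#' A candidate peak must additionally keep at least `min_width` consecutive
#' samples above half-maximum: single-sample noise excursions have no peak
#' shape and are discarded, which keeps the false-positive rate at S/N > 3
#' far below the Gaussian point-wise exceedance rate. This presumes the
#' profile is sampled with at least `min_width` points across a peak's FWHM.
#'
#' @param spectrum A profile `maldi_spectrum`.
#' @param min_snr Minimum signal-to-noise ratio (default 3).
#' @param window Noise-window width in Da, passed to [estimate_noise()].
#' @param baseline_k Running-median width for baseline removal.
#' @param min_width Minimum number of samples above half-maximum (default 3).
#' @return A centroid `maldi_spectrum` with `snr` populated. An all-noise
#'   trace yields a zero-peak centroid spectrum.
#' @export
pick_peaks <- function(spectrum, min_snr = 3, window = 100, baseline_k = 151,
                       min_width = 3) {
  assert_spectrum(spectrum, mode = "profile")
  y <- spectrum$intensity - profile_baseline(spectrum, baseline_k)
  y[y < 0] <- 0
  np <- estimate_noise(spectrum, window = window, baseline_k = baseline_k)
  n <- length(y)
  left <- c(-Inf, y[-n])
  right <- c(y[-1], -Inf)
  is_max <- y > left & y >= right & y > 0
  noise <- noise_at(np, spectrum$mz)
  snr <- ifelse(noise > 0, y / noise, ifelse(y > 0, Inf, 0))
  apex <- which(is_max & snr > min_snr)
  peaks <- purrr::map_dfr(apex, function(i) {
    half <- y[i] / 2
    lo <- i
    while (lo > 1 && y[lo - 1] >= half) lo <- lo - 1
    hi <- i
    while (hi < n && y[hi + 1] >= half) hi <- hi + 1
    if (hi - lo + 1 < min_width) return(tibble())
    reg <- lo:hi
    tibble(
      mz = sum(spectrum$mz[reg] * y[reg]) / sum(y[reg]),
      intensity = y[i],
      snr = snr[i]
    )
  })
  if (nrow(peaks) == 0) {
    return(empty_centroid(spectrum_id(spectrum), spectrum_metadata(spectrum)))
  }
  # adjacent apexes sharing a half-max region centroid to the same m/z;
  # merging by intensity sum keeps the peak list strictly ascending
  replace_points(spectrum, peaks, mode = "centroid")
}

# Zero-peak centroid spectrum: the one sanctioned exception to non-emptiness,
# used when peak picking finds nothing above threshold.
empty_centroid <- function(spectrum_id = "empty", metadata = list()) {
  pts <- tibble(mz = numeric(), intensity = numeric(), snr = numeric())
  structure(pts, class = c("maldi_spectrum", class(tibble())),
            mode = "centroid", spectrum_id = spectrum_id, metadata = metadata)
}

#' The five-peptide MALDI calibrant panel
#'
#' The standard external calibration mixture spanning the collagen
#' fingerprint mass range: angiotensin II, bradykinin fragment 1-7, P14R,
#' ACTH fragment 18-39 and (oxidised) insulin chain B. Reference \[M+H\]+
#' values are computed from the peptide sequences by [peptide_mh()], with the
#' two cysteic-acid residues of oxidised insulin chain B carried as a fixed
#' mass offset.
#'
#' @param masses A [mass_table()].
#' @return A tibble of class `calibrant_panel` with columns `name`,
#'   `sequence`, `fixed_delta`, `reference_mz`, sorted ascending in
#'   `reference_mz`.
#' @examples
#' calibrant_panel()
#' @export
calibrant_panel <- function(masses = mass_table()) {
  cysteic_acid <- 2 * 47.9847  # SO3H oxidation of the two Cys in chain B
  p <- tibble(
    name = c("Bradykinin fragment 1-7", "Angiotensin II", "P14R",
             "ACTH fragment 18-39", "Insulin chain B (oxidised)"),
    sequence = c("RPPGFSP", "DRVYIHPF", paste0(strrep("P", 14), "R"),
                 "RPVKVYPNGAEDESAEAFPLEF",
                 "FVNQHLCGSHLVEALYLVCGERGFFYTPKA"),
    fixed_delta = c(0, 0, 0, 0, cysteic_acid)
  )
  p$reference_mz <- peptide_mh(p$sequence, masses = masses) + p$fixed_delta
  p <- dplyr::arrange(p, .data$reference_mz)
  validate_calibrant_panel(p)
}

validate_calibrant_panel <- function(p) {
  p <- as_tibble(p)
  if (!all(c("name", "reference_mz") %in% names(p))) {
    abort("a calibrant panel needs columns `name` and `reference_mz`")
  }
  if (nrow(p) < 2) abort("a calibrant panel needs at least 2 entries")
  if (is.unsorted(p$reference_mz, strictly = TRUE)) {
    abort("calibrant reference m/z values must be strictly ascending")
  }
  structure(p, class = c("calibrant_panel", class(tibble())))
}

#' Recalibrate a centroid spectrum against a calibrant panel
#'
#' Matches each calibrant to the nearest observed peak within
#' `match_tolerance`, fits a least-squares observed-to-reference model
#' (linear, or quadratic in m/z), and applies the correction to every peak.
#' This is external calibration: fit on a calibrant-spot spectrum, then apply
#' the returned fit to sample spectra with [apply_calibration()].
#'
#' With fewer matched calibrants than the model needs (2 for linear, 3 for
#' quadratic) the fit is refused: the spectrum is returned unchanged and the
#' fit object carries `applied = FALSE`.
#'
#' @param spectrum A centroid `maldi_spectrum`.
#' @param panel A [calibrant_panel()].
#' @param match_tolerance Maximum |observed - reference| in Da for a
#'   calibrant to count as matched (default 0.5).
#' @param model `"linear"` or `"quadratic"`.
#' @return A list with elements `spectrum` (corrected, or unchanged when the
#'   fit was refused) and `fit` (a `calibration_fit`; see [tidy()] and
#'   [glance()] methods).
#' @export
recalibrate <- function(spectrum, panel = calibrant_panel(),
                        match_tolerance = 0.5,
                        model = c("linear", "quadratic")) {
  assert_spectrum(spectrum, mode = "centroid")
  model <- match.arg(model)
  panel <- validate_calibrant_panel(panel)
  need <- if (model == "linear") 2L else 3L
  matches <- purrr::map_dfr(seq_len(nrow(panel)), function(i) {
    ref <- panel$reference_mz[[i]]
    if (nrow(spectrum) == 0) return(tibble())
    d <- abs(spectrum$mz - ref)
    j <- which.min(d)
    if (d[j] > match_tolerance) return(tibble())
    tibble(name = panel$name[[i]], reference_mz = ref,
           observed_mz = spectrum$mz[[j]])
  })
  if (nrow(matches) < need) {
    fit <- new_calibration_fit(model, coefficients = NULL, matches = matches,
                               applied = FALSE)
    return(list(spectrum = spectrum, fit = fit))
  }
  fml <- if (model == "linear") {
    reference_mz ~ observed_mz
  } else {
    reference_mz ~ observed_mz + I(observed_mz^2)
  }
  lmfit <- lm(fml, data = matches)
  matches$residual <- matches$reference_mz -
    as.numeric(predict(lmfit, matches))
  corrected <- as.numeric(predict(lmfit, tibble(observed_mz = spectrum$mz)))
  pts <- as_tibble(as.data.frame(spectrum))
  pts$mz <- corrected
  fit <- new_calibration_fit(model, coefficients = coef(lmfit),
                             matches = matches, applied = TRUE)
  list(spectrum = replace_points(spectrum, pts), fit = fit)
}

new_calibration_fit <- function(model, coefficients, matches, applied) {
  structure(
    list(model = model, coefficients = coefficients, matches = matches,
         n_matched = nrow(matches), applied = applied),
    class = "calibration_fit"
  )
}

#' Apply a fitted calibration to another spectrum
#'
#' @param spectrum A centroid `maldi_spectrum`.
#' @param fit A `calibration_fit` from [recalibrate()].
#' @return The spectrum with corrected m/z values (unchanged if the fit was
#'   refused).
#' @export
apply_calibration <- function(spectrum, fit) {
  assert_spectrum(spectrum, mode = "centroid")
  stopifnot(inherits(fit, "calibration_fit"))
  if (!fit$applied || nrow(spectrum) == 0) return(spectrum)
  co <- fit$coefficients
  mz <- spectrum$mz
  corrected <- co[[1]] + co[[2]] * mz +
    if (fit$model == "quadratic") co[[3]] * mz^2 else 0
  pts <- as_tibble(as.data.frame(spectrum))
  pts$mz <- corrected
  replace_points(spectrum, pts)
}

#' @export
print.calibration_fit <- function(x, ...) {
  if (x$applied) {
    cat(sprintf("<calibration_fit> %s, %d calibrants matched, max |residual| %.2g Da\n",
                x$model, x$n_matched, max(abs(x$matches$residual))))
  } else {
    cat(sprintf("<calibration_fit> refused: %d calibrant(s) matched, %s model needs %d\n",
                x$n_matched, x$model, if (x$model == "linear") 2 else 3))
  }
  invisible(x)
}

#' @rdname recalibrate
#' @param x A `calibration_fit`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.calibration_fit <- function(x, ...) x$matches

#' @rdname recalibrate
#' @exportS3Method generics::glance
glance.calibration_fit <- function(x, ...) {
  tibble(
    model = x$model,
    applied = x$applied,
    n_matched = x$n_matched,
    intercept = if (x$applied) x$coefficients[[1]] else NA_real_,
    slope = if (x$applied) x$coefficients[[2]] else NA_real_,
    quad = if (x$applied && x$model == "quadratic") x$coefficients[[3]] else NA_real_,
    max_abs_residual = if (x$applied) max(abs(x$matches$residual)) else NA_real_
  )
}
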