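test_that("a constant trace has zero noise everywhere", {
  s <- new_spectrum(data.frame(mz = seq(1000, 1300, by = 0.5), intensity = 7),
                    mode = "profile")
  np <- estimate_noise(s)
  expect_true(all(np$noise == 0))
})

test_that("the MAD estimator recovers Gaussian noise sigma", {
  withr::with_seed(11, {
    s <- new_spectrum(
      data.frame(mz = seq(1000, 1999.9, by = 0.1),
                 intensity = 100 + rnorm(10000, 0, 1)),
      mode = "profile"
    )
  })
  np <- estimate_noise(s)
  expect_true(all(np$noise > 0.9 & np$noise < 1.1))
})

test_that("noise estimation is robust to a dominating peak", {
  withr::with_seed(12, base_int <- 100 + rnorm(10000, 0, 1))
  mz <- seq(1000, 1999.9, by = 0.1)
  flat <- new_spectrum(data.frame(mz = mz, intensity = base_int),
                       mode = "profile")
  spiked_int <- base_int + 5000 * exp(-(mz - 1500)^2 / (2 * 0.15^2))
  spiked <- new_spectrum(data.frame(mz = mz, intensity = spiked_int),
                         mode = "profile")
  n1 <- noise_at(estimate_noise(flat), 1500)
  n2 <- noise_at(estimate_noise(spiked), 1500)
  expect_lt(abs(n2 - n1) / n1, 0.05)
})

test_that("a clean Gaussian peak is centroided to within 0.01 Da", {
  withr::with_seed(13, {
    s <- gaussian_profile(1500, 500, fwhm = 0.3, mz_range = c(1400, 1600),
                          noise_sd = 0.5)
  })
  pk <- pick_peaks(s)
  expect_identical(nrow(pk), 1L)
  expect_lt(abs(pk$mz - 1500), 0.01)
  expect_gt(pk$snr, 100)
})

test_that("well-separated peaks are resolved individually", {
  withr::with_seed(14, {
    s <- gaussian_profile(c(1500, 1510), c(300, 400), fwhm = 0.3,
                          mz_range = c(1450, 1560), noise_sd = 0.5)
  })
  pk <- pick_peaks(s)
  expect_identical(nrow(pk), 2L)
  expect_equal(pk$mz, c(1500, 1510), tolerance = 0.01)
})

test_that("an all-noise trace yields almost no peaks at S/N > 3", {
  withr::with_seed(15, {
    s <- new_spectrum(
      data.frame(mz = seq(1000, 1999.9, by = 0.1),
                 intensity = 100 + rnorm(10000, 0, 1)),
      mode = "profile"
    )
  })
  pk <- pick_peaks(s, min_snr = 3)
  expect_lte(nrow(pk), 15)  # ~0.1% of points clear 3 sigma by chance
  expect_identical(nrow(pick_peaks(s, min_snr = 6)), 0L)
  expect_identical(spectrum_mode(pick_peaks(s, min_snr = 6)), "centroid")
})

test_that("peak picking is invariant to intensity rescaling", {
  withr::with_seed(16, {
    s <- gaussian_profile(c(1500, 1620.4), c(200, 90), fwhm = 0.3,
                          mz_range = c(1450, 1700), noise_sd = 1)
  })
  pts <- as.data.frame(s)
  pts$intensity <- pts$intensity * 7.3
  s_scaled <- new_spectrum(pts, mode = "profile")
  a <- pick_peaks(s)
  b <- pick_peaks(s_scaled)
  expect_equal(b$mz, a$mz, tolerance = 1e-9)
  expect_equal(b$snr, a$snr, tolerance = 1e-9)
})

test_that("the calibrant panel is computed from sequences, in ascending order", {
  cp <- calibrant_panel()
  expect_identical(nrow(cp), 5L)
  expect_false(is.unsorted(cp$reference_mz, strictly = TRUE))
  # frozen independent values for the standard peptide calibration mixture
  expect_equal(cp$reference_mz,
               c(757.3992, 1046.5418, 1533.8576, 2465.1983, 3494.6508),
               tolerance = 2e-3)
})

test_that("peaks already at reference masses give an identity fit", {
  cp <- calibrant_panel()
  s <- make_peaks(cp$reference_mz, intensity = 100, snr = 50)
  out <- recalibrate(s, cp)
  expect_true(out$fit$applied)
  expect_identical(out$fit$n_matched, 5L)
  expect_equal(max(abs(out$fit$matches$residual)), 0, tolerance = 1e-9)
  expect_equal(out$spectrum$mz, s$mz, tolerance = 1e-9)
})

test_that("an injected affine distortion is recovered exactly", {
  cp <- calibrant_panel()
  distorted <- make_peaks(1.0002 * cp$reference_mz + 0.05,
                          intensity = 100, snr = 50)
  out <- recalibrate(distorted, cp, match_tolerance = 1)
  co <- out$fit$coefficients
  # reference = (observed - 0.05) / 1.0002
  expect_equal(unname(co[[2]]), 1 / 1.0002, tolerance = 1e-6)
  expect_equal(unname(co[[1]]), -0.05 / 1.0002, tolerance = 1e-6)
  expect_lt(max(abs(out$fit$matches$residual)), 1e-6)
  expect_equal(out$spectrum$mz, cp$reference_mz, tolerance = 1e-6)
})

test_that("calibration proceeds with a missing calibrant and refuses below minimum", {
  cp <- calibrant_panel()
  four <- make_peaks(cp$reference_mz[-3], intensity = 100, snr = 50)
  out <- recalibrate(four, cp)
  expect_true(out$fit$applied)
  expect_identical(out$fit$n_matched, 4L)

  one <- make_peaks(cp$reference_mz[2], intensity = 100, snr = 50)
  ref <- recalibrate(one, cp)
  expect_false(ref$fit$applied)
  expect_equal(ref$spectrum$mz, one$mz)
  # quadratic needs three matched calibrants
  two <- make_peaks(cp$reference_mz[1:2], intensity = 100, snr = 50)
  expect_false(recalibrate(two, cp, model = "quadratic")$fit$applied)
  expect_true(recalibrate(two, cp, model = "linear")$fit$applied)
})

test_that("recalibration is idempotent and preserves m/z ordering", {
  cp <- calibrant_panel()
  withr::with_seed(17, extra <- sort(runif(30, 800, 3400)))
  s <- make_peaks(sort(c(1.0003 * cp$reference_mz - 0.1, extra)),
                  intensity = 100, snr = 50)
  once <- recalibrate(s, cp, match_tolerance = 1.5)
  twice <- recalibrate(once$spectrum, cp, match_tolerance = 1.5)
  expect_equal(unname(twice$fit$coefficients), c(0, 1), tolerance = 1e-9)
  expect_false(is.unsorted(once$spectrum$mz, strictly = TRUE))
})

test_that("a fitted calibration transfers to sample spectra", {
  cp <- calibrant_panel()
  cal_spot <- make_peaks(1.0002 * cp$reference_mz + 0.05,
                         intensity = 100, snr = 50)
  fit <- recalibrate(cal_spot, cp, match_tolerance = 1)$fit
  sample <- make_peaks(1.0002 * c(1443.7, 2695.4) + 0.05)
  corrected <- apply_calibration(sample, fit)
  expect_equal(corrected$mz, c(1443.7, 2695.4), tolerance = 1e-6)
})
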