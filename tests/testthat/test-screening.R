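panel <- default_panel()

test_that("good fingerprints and noise-only traces are triaged correctly", {
  dir <- withr::local_tempdir()
  good <- simulate_batch(10, file.path(dir, "good"), panel = panel,
                         taxa = "Apodemus", seed = 51)
  # noise-only profile traces: no peptide peaks at all, written as mzML
  noise <- simulate_batch(
    5, file.path(dir, "noise"), panel = panel, taxa = "background-only",
    config = sim_config(background_peaks = 0, noise_sd = 1),
    format = "mzml", mode = "profile", seed = 52
  )
  manifest <- rbind(good$manifest, noise$manifest)
  rep <- screen_batch(manifest, panel)
  g <- glance(rep)
  expect_identical(g$n_input, 15L)
  expect_identical(g$n_good_quality, 10L)
  expect_identical(g$n_fail_quality, 5L)
  counts <- rep$summary$taxon_counts
  expect_identical(counts$label, "Apodemus")
  expect_identical(counts$n, 10L)
})

test_that("an empty manifest yields an empty report with zero counts", {
  manifest <- tibble::tibble(spectrum_id = character(), path = character(),
                             accession = character())
  rep <- screen_batch(manifest, panel)
  expect_identical(glance(rep)$n_input, 0L)
  expect_identical(nrow(tidy(rep)), 0L)
  expect_identical(nrow(rep$summary$taxon_counts), 0L)
})

test_that("a corrupt file becomes a read-error row and the batch continues", {
  dir <- withr::local_tempdir()
  b <- simulate_batch(2, file.path(dir, "ok"), panel = panel,
                      taxa = "Micromys", seed = 53)
  bad <- file.path(dir, "corrupt.txt")
  writeLines(c("not a peak list", "at all"), bad)
  manifest <- rbind(
    b$manifest,
    tibble::tibble(spectrum_id = "bad1", path = bad, accession = "PHX")
  )
  rep <- screen_batch(manifest, panel)
  res <- tidy(rep)
  expect_identical(sum(res$status == "read_error"), 1L)
  expect_identical(res$spectrum_id[res$status == "read_error"], "bad1")
  expect_identical(sum(res$status == "pass"), 2L)
})

test_that("every manifest row is accounted for exactly once", {
  dir <- withr::local_tempdir()
  b <- simulate_batch(4, file.path(dir, "mix"), panel = panel,
                      taxa = c("Mus", "R. rattus"), seed = 54)
  manifest <- b$manifest
  # induce two read errors: one missing file, one garbage file
  manifest$path[2] <- file.path(dir, "missing.txt")
  garb <- file.path(dir, "garbage.txt")
  writeLines("x y z", garb)
  manifest$path[5] <- garb
  rep <- screen_batch(manifest, panel)
  res <- tidy(rep)
  expect_identical(nrow(res), nrow(manifest))
  expect_identical(
    sum(res$status == "pass") + sum(res$status == "fail") +
      sum(res$status == "read_error"),
    nrow(manifest)
  )
  expect_identical(sum(res$status == "read_error"), 2L)
})

test_that("screening applies an external calibration fit before matching", {
  dir <- withr::local_tempdir()
  drift <- c(1.0003, 0.1)
  cfg <- sim_config(taxon = "Mus", mass_error_sd = 0.01,
                    calibration_drift = drift)
  b <- simulate_batch(3, file.path(dir, "drifted"), panel = panel,
                      taxa = "Mus", config = cfg, seed = 55)
  cal_spot <- simulate_calibrant_spectrum(
    sim_config(mass_error_sd = 0.01, calibration_drift = drift, seed = 56)
  )
  fit <- recalibrate(cal_spot, match_tolerance = 2)$fit
  rep_cal <- screen_batch(b$manifest, panel, calibration = fit)
  expect_identical(rep_cal$summary$taxon_counts$label, "Mus")
  expect_identical(rep_cal$summary$taxon_counts$n, 3L)
  # without correction the high-mass markers drift out of the 0.5 Da window
  rep_raw <- screen_batch(b$manifest, panel)
  raw_scores <- tidy(rep_raw)$score
  expect_true(all(tidy(rep_cal)$score > raw_scores))
})

test_that("reports round-trip to disk", {
  dir <- withr::local_tempdir()
  b <- simulate_batch(2, file.path(dir, "b"), panel = panel,
                      taxa = "Apodemus", seed = 57)
  rep <- screen_batch(b$manifest, panel)
  out <- file.path(dir, "report")
  write_screen_report(rep, out)
  back <- readr::read_csv(file.path(out, "report.csv"),
                          show_col_types = FALSE)
  expect_identical(nrow(back), 2L)
  js <- jsonlite::read_json(file.path(out, "summary.json"))
  expect_identical(js$n_good_quality, 2L)
})

test_that("positives join to their excavation find locations", {
  dir <- withr::local_tempdir()
  b <- simulate_batch(1, file.path(dir, "b"), panel = panel,
                      taxa = "Apodemus", seed = 58)
  manifest <- b$manifest
  manifest$accession <- "PH6368"
  rep <- screen_batch(manifest, panel)
  ss <- spatial_summary(rep, pinhole_specimens())
  expect_identical(nrow(ss$positives), 1L)
  expect_identical(ss$positives$label, "Apodemus")
  expect_equal(ss$positives$westing, 8)
  expect_equal(ss$positives$northing, 1)
  expect_identical(ss$positives$depth, "flowstone")
  expect_identical(nrow(ss$unmatched), 0L)
})

test_that("unknown accessions are reported separately, empty reports join empty", {
  dir <- withr::local_tempdir()
  b <- simulate_batch(1, file.path(dir, "b"), panel = panel,
                      taxa = "Mus", seed = 59)
  manifest <- b$manifest
  manifest$accession <- "PH-unknown"
  rep <- screen_batch(manifest, panel)
  ss <- spatial_summary(rep, pinhole_specimens())
  expect_identical(nrow(ss$positives), 0L)
  expect_identical(ss$unmatched$accession, "PH-unknown")

  noise <- simulate_batch(
    1, file.path(dir, "n"), panel = panel, taxa = "background-only",
    seed = 60
  )
  rep0 <- screen_batch(noise$manifest, panel)
  ss0 <- spatial_summary(rep0, pinhole_specimens())
  expect_identical(nrow(ss0$positives), 0L)
  expect_identical(nrow(ss0$unmatched), 0L)
})

test_that("the bundled specimen table validates and parses depths", {
  sp <- pinhole_specimens()
  expect_identical(nrow(sp), 24L)
  expect_true(all(!is.na(sp$westing)))
  expect_true(is.na(sp$depth_cm[sp$accession == "PH6368"]))
  expect_equal(sp$depth_cm[sp$accession == "PH9232"], 115)
})
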