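panel <- default_panel()

test_that("the bundled panel carries the published marker values", {
  rn <- unlist(panel$taxa[panel$taxa$taxon == "R. norvegicus",
                          paste0("slot", 1:9)])
  expect_equal(unname(rn), c(1203.7, 1443.7, 1451.7, 1453.7, 2143.1,
                             2695.4, 2899.5, 2987.5, 3003.5))
  expect_equal(panel$taxa$slot3[panel$taxa$taxon == "Micromys"], 1465.7)
  expect_identical(nrow(panel$taxa), 5L)
  # slot structure: 2/4/6 conserved, 8 species-diagnostic
  expect_identical(panel$slots$resolution[c(2, 4, 6)], rep("conserved", 3))
  expect_identical(panel$slots$resolution[[8]], "species")
  expect_identical(panel$slots$legacy[[8]], "G")
})

test_that("invalid panels are rejected with the problem named", {
  taxa <- panel$taxa
  taxa$taxon[2] <- taxa$taxon[1]
  expect_error(marker_panel(taxa), "duplicate taxon")
  taxa <- panel$taxa
  taxa$slot5[taxa$taxon == "Micromys"] <- NA
  expect_error(marker_panel(taxa), "Micromys.*slot5")
  # identical congeneric species must be collapsed to a genus row
  taxa <- panel$taxa
  taxa$slot8[taxa$taxon == "R. rattus"] <- 2987.5
  expect_error(marker_panel(taxa), "collapse")
})

test_that("a perfect R. rattus fingerprint matches 9/9 vs 8/9 for R. norvegicus", {
  s <- row_spectrum(panel, "R. rattus")
  mm <- match_markers(s, panel, tolerance = 0.5)
  counts <- tapply(mm$matched, mm$taxon, sum)
  expect_identical(unname(counts[["R. rattus"]]), 9L)
  expect_identical(unname(counts[["R. norvegicus"]]), 8L)
  # the missing slot is the species-diagnostic one, 30 Da away
  miss <- mm[mm$taxon == "R. norvegicus" & !mm$matched, ]
  expect_identical(miss$slot, 8L)
  expect_equal(miss$reference_mz, 2987.5)
})

test_that("degenerate spectra match as expected", {
  empty <- zoomscreen:::empty_centroid()
  mm <- match_markers(empty, panel)
  expect_false(any(mm$matched))
  one <- make_peaks(1443.7)
  mm1 <- match_markers(one, panel)
  hit <- mm1[mm1$matched, ]
  expect_identical(sort(unique(hit$taxon)), sort(panel$taxa$taxon))
  expect_true(all(hit$slot == 2))
})

test_that("each panel taxon is recovered at its achievable resolution", {
  expected <- tibble::tribble(
    ~taxon,          ~label,          ~resolution,
    "R. norvegicus", "R. norvegicus", "species",
    "R. rattus",     "R. rattus",     "species",
    "Apodemus",      "Apodemus",      "genus",
    "Micromys",      "Micromys",      "genus",
    "Mus",           "Mus",           "species"
  )
  for (i in seq_len(nrow(expected))) {
    a <- classify(row_spectrum(panel, expected$taxon[[i]]), panel)
    expect_identical(a$label, expected$label[[i]])
    expect_identical(a$resolution, expected$resolution[[i]])
    expect_identical(a$score, 9L)
    expect_true(a$murine_candidate)
  }
})

test_that("conserved slots alone give a murine-positive but indeterminate call", {
  s <- make_peaks(c(1443.7, 1453.7, 2143.1, 2695.4, 3003.5))
  a <- classify(s, panel, tolerance = 0.5)
  expect_identical(a$label, "indeterminate")
  expect_identical(a$resolution, "none")
  expect_true(a$murine_candidate)
  expect_gt(length(a$ambiguity), 1)
})

test_that("the murine flag requires absence of the vertebrate counterpart", {
  with_counterpart <- make_peaks(c(1443.7, 1459.7, 1453.7, 2143.1, 2695.4))
  expect_false(classify(with_counterpart, panel)$murine_candidate)
  vertebrate_only <- make_peaks(c(1459.7, 2705.4))
  expect_false(classify(vertebrate_only, panel)$murine_candidate)
})

test_that("species calls without the diagnostic slot degrade to genus", {
  vals <- unlist(panel$taxa[panel$taxa$taxon == "R. norvegicus",
                            paste0("slot", c(1:7, 9))])
  a <- classify(make_peaks(unname(vals)), panel)
  expect_identical(a$label, "Rattus")
  expect_identical(a$resolution, "genus")
  expect_identical(sort(a$ambiguity), c("R. norvegicus", "R. rattus"))
})

test_that("classification is invariant under peak-list permutation", {
  withr::with_seed(31, {
    mzs <- c(unname(unlist(panel$taxa[3, paste0("slot", 1:9)])),
             runif(20, 800, 3500))
    perm <- sample(seq_along(mzs))
  })
  a <- classify(make_peaks(mzs), panel)
  b <- classify(make_peaks(mzs[perm]), panel)
  expect_identical(glance(a), glance(b))
})

test_that("match counts never decrease as tolerance grows", {
  withr::with_seed(32, {
    for (i in 1:10) {
      s <- make_peaks(sort(runif(sample(5:30, 1), 800, 3500)))
      prev <- rep(-1L, nrow(panel$taxa))
      for (tol in c(0.1, 0.2, 0.5, 1.0)) {
        mm <- match_markers(s, panel, tolerance = tol)
        counts <- tapply(mm$matched, mm$taxon, sum)[panel$taxa$taxon]
        expect_true(all(counts >= prev))
        prev <- counts
      }
    }
  })
})

test_that("match counts equal the exhaustive all-pairs oracle", {
  withr::with_seed(33, {
    for (i in 1:100) {
      mzs <- sort(runif(sample(1:30, 1), 800, 3500))
      mm <- match_markers(make_peaks(mzs), panel, tolerance = 0.5)
      counts <- tapply(mm$matched, mm$taxon, sum)[panel$taxa$taxon]
      oracle <- oracle_match_counts(mzs, panel, tolerance = 0.5)
      expect_identical(unname(as.integer(counts)),
                       unname(as.integer(oracle[panel$taxa$taxon])))
    }
  })
})

test_that("one peak never satisfies two slots of the same taxon", {
  # 1452.7 sits within 1.2 Da of both slot 3 (1451.7) and slot 4 (1453.7)
  s <- make_peaks(1452.7)
  mm <- match_markers(s, panel, tolerance = 1.2)
  per_taxon <- tapply(mm$matched, mm$taxon, sum)
  expect_true(all(per_taxon <= 1))
})

test_that("assignment objects tidy and glance cleanly", {
  a <- classify(row_spectrum(panel, "Mus"), panel)
  td <- tidy(a)
  expect_identical(nrow(td), 9L)
  expect_true(all(td$matched))
  g <- glance(a)
  expect_identical(g$label, "Mus")
  expect_identical(g$score, 9L)
})
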