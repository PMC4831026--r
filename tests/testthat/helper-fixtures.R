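# Shared fixtures and independent oracles, built in code at test time.

# centroid spectrum from bare m/z values
make_peaks <- function(mz, intensity = 10, snr = 20, id = "test") {
  new_spectrum(data.frame(mz = mz, intensity = intensity, snr = snr),
               mode = "centroid", spectrum_id = id)
}

# a panel taxon rendered as a perfect peak list
row_spectrum <- function(panel, taxon) {
  slot_cols <- grep("^slot", names(panel$taxa), value = TRUE)
  vals <- unlist(panel$taxa[panel$taxa$taxon == taxon, slot_cols])
  make_peaks(unname(vals), id = taxon)
}

# profile trace: sum of Gaussians on a constant baseline plus optional noise
gaussian_profile <- function(centers, amplitudes, fwhm = 0.3,
                             mz_range = range(centers) + c(-30, 30),
                             step = 0.01, noise_sd = 0, baseline = 10,
                             id = "profile") {
  grid <- seq(mz_range[1], mz_range[2], by = step)
  sigma <- fwhm / 2.35482
  y <- rep(baseline, length(grid))
  for (i in seq_along(centers)) {
    y <- y + amplitudes[i] * exp(-(grid - centers[i])^2 / (2 * sigma^2))
  }
  if (noise_sd > 0) y <- y + rnorm(length(grid), 0, noise_sd)
  y[y < 0] <- 0
  new_spectrum(data.frame(mz = grid, intensity = y), mode = "profile",
               spectrum_id = id)
}

# brute-force tryptic digest oracle: enumerate all boundary pairs directly
oracle_digest <- function(sequence, missed_cleavages) {
  chars <- strsplit(sequence, "")[[1]]
  n <- length(chars)
  sites <- integer()
  for (i in seq_len(n)) {
    if (chars[i] %in% c("K", "R") && (i == n || chars[i + 1] != "P")) {
      sites <- c(sites, i)
    }
  }
  bounds <- sort(unique(c(0L, sites, n)))
  frags <- character()
  for (a in seq_len(length(bounds) - 1)) {
    for (b in (a + 1):length(bounds)) {
      internal <- b - a - 1
      if (internal <= missed_cleavages) {
        frags <- c(frags, substr(sequence, bounds[a] + 1, bounds[b]))
      }
    }
  }
  frags
}

# all-pairs marker-match oracle: a slot counts as matched when any observed
# peak lies within tolerance of its reference value
oracle_match_counts <- function(mz_values, panel, tolerance) {
  slot_cols <- grep("^slot", names(panel$taxa), value = TRUE)
  sapply(seq_len(nrow(panel$taxa)), function(i) {
    refs <- unlist(panel$taxa[i, slot_cols])
    sum(vapply(refs, function(r) any(abs(mz_values - r) <= tolerance),
               logical(1)))
  }) |> stats::setNames(panel$taxa$taxon)
}

random_peptide <- function(len) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], len,
               replace = TRUE), collapse = "")
}
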