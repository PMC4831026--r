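#' Read a centroided peak list from delimited text
#'
#' Accepts whitespace- or comma-delimited text with columns m/z and intensity
#' and, in the three-column dialect, signal-to-noise. A header line is
#' detected and skipped automatically. Duplicate m/z rows are merged by
#' summing intensity; rows are sorted ascending in m/z.
#'
#' @param path Path to the peak-list file.
#' @param dialect `"auto"` (default), `"two-column"` or `"three-column"`.
#' @param spectrum_id Identifier; defaults to the file name.
#' @param metadata Named list carried on the spectrum.
#' @return A centroid `maldi_spectrum`.
#' @export
read_peaklist <- function(path, dialect = c("auto", "two-column", "three-column"),
                          spectrum_id = NULL, metadata = list()) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort(sprintf("file not found: '%s'", path))
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  keep <- nzchar(lines) & !startsWith(lines, "#")
  line_no <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0) abort(sprintf("empty peak list: '%s'", path))
  fields <- strsplit(lines, "[,\t ]+")
  # header detection: first line whose first field is not numeric
  first_num <- suppressWarnings(as.numeric(fields[[1]][[1]]))
  if (is.na(first_num)) {
    fields <- fields[-1]
    line_no <- line_no[-1]
    if (length(fields) == 0) abort(sprintf("no data rows in '%s'", path))
  }
  ncol <- lengths(fields)
  want <- switch(dialect, auto = max(ncol), `two-column` = 2L, `three-column` = 3L)
  bad <- which(ncol < min(want, 2L))
  if (length(bad) > 0) {
    abort(sprintf("line %d of '%s' has %d column(s), expected at least %d",
                  line_no[bad[[1]]], path, ncol[bad[[1]]], min(want, 2L)))
  }
  parse_col <- function(k, name) {
    vals <- suppressWarnings(as.numeric(vapply(fields, function(f) {
      if (length(f) >= k) f[[k]] else NA_character_
    }, character(1))))
    nn <- which(is.na(vals) & vapply(fields, length, 1L) >= k)
    if (length(nn) > 0) {
      abort(sprintf("non-numeric %s value on line %d of '%s'",
                    name, line_no[nn[[1]]], path))
    }
    vals
  }
  pts <- tibble(mz = parse_col(1, "m/z"), intensity = parse_col(2, "intensity"))
  if (want >= 3 && any(ncol >= 3)) pts$snr <- parse_col(3, "S/N")
  new_spectrum(pts, mode = "centroid",
               spectrum_id = spectrum_id %||% basename(path),
               metadata = metadata)
}

#' Write a centroided peak list as three-column text
#'
#' Writes tab-separated `mz`, `intensity`, `snr` with a header line.
#' `read_peaklist()` of the result reproduces the peaks to within 1e-6.
#'
#' @param spectrum A centroid `maldi_spectrum`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_peaklist <- function(spectrum, path) {
  assert_spectrum(spectrum, mode = "centroid")
  df <- as.data.frame(spectrum)[c("mz", "intensity", "snr")]
  header <- "mz\tintensity\tsnr"
  body <- sprintf("%.6f\t%.6f\t%s", df$mz, df$intensity,
                  ifelse(is.na(df$snr), "NA", sprintf("%.6f", df$snr)))
  writeLines(c(header, body), path)
  invisible(path)
}

## --- minimal mzML subset (MS1, 64-bit float, no compression) ---

ms_cv <- function(node, accession, name, value = "") {
  xml2::xml_add_child(node, "cvParam", cvRef = "MS", accession = accession,
                      name = name, value = value)
}

#' Write spectra to a minimal mzML file
#'
#' Emits the MS1 subset of mzML 1.1.0 (64-bit little-endian floats, no
#' compression) that mainstream readers, including `mzR`, accept. Centroid
#' and profile spectra are flagged with the corresponding CV terms.
#'
#' @param spectra A `maldi_spectrum` or list of them.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mzml <- function(spectra, path) {
  if (is_spectrum(spectra)) spectra <- list(spectra)
  if (length(spectra) == 0) abort("no spectra to write")
  purrr::walk(spectra, assert_spectrum)
  enc64 <- function(x) {
    # base64_enc line-wraps long input; mzML readers need one unbroken token
    gsub("[\r\n]", "",
         jsonlite::base64_enc(writeBin(as.double(x), raw(), size = 8,
                                       endian = "little")))
  }
  doc <- xml2::xml_new_root("mzML", xmlns = "http://psi.hupo.org/ms/mzml",
                            version = "1.1.0")
  cvl <- xml2::xml_add_child(doc, "cvList", count = "1")
  xml2::xml_add_child(cvl, "cv", id = "MS", fullName = "PSI-MS",
                      URI = "https://raw.githubusercontent.com/HUPO-PSI/psi-ms-CV/master/psi-ms.obo")
  fdl <- xml2::xml_add_child(doc, "fileDescription")
  ms_cv(xml2::xml_add_child(fdl, "fileContent"), "MS:1000579", "MS1 spectrum")
  sfl <- xml2::xml_add_child(doc, "softwareList", count = "1")
  xml2::xml_add_child(sfl, "software", id = "zoomscreen",
                      version = as.character(utils::packageVersion("zoomscreen")))
  icl <- xml2::xml_add_child(doc, "instrumentConfigurationList", count = "1")
  xml2::xml_add_child(icl, "instrumentConfiguration", id = "IC1")
  dpl <- xml2::xml_add_child(doc, "dataProcessingList", count = "1")
  dp <- xml2::xml_add_child(dpl, "dataProcessing", id = "DP1")
  pm <- xml2::xml_add_child(dp, "processingMethod", order = "1",
                            softwareRef = "zoomscreen")
  ms_cv(pm, "MS:1000544", "Conversion to mzML")
  run <- xml2::xml_add_child(doc, "run", id = "run1",
                             defaultInstrumentConfigurationRef = "IC1")
  sl <- xml2::xml_add_child(run, "spectrumList",
                            count = as.character(length(spectra)),
                            defaultDataProcessingRef = "DP1")
  for (i in seq_along(spectra)) {
    sp <- spectra[[i]]
    s <- xml2::xml_add_child(
      sl, "spectrum", index = as.character(i - 1),
      id = sprintf("scan=%d", i),
      defaultArrayLength = as.character(nrow(sp))
    )
    ms_cv(s, "MS:1000511", "ms level", "1")
    ms_cv(s, "MS:1000579", "MS1 spectrum")
    if (spectrum_mode(sp) == "centroid") {
      ms_cv(s, "MS:1000127", "centroid spectrum")
    } else {
      ms_cv(s, "MS:1000128", "profile spectrum")
    }
    bal <- xml2::xml_add_child(s, "binaryDataArrayList", count = "2")
    for (col in c("mz", "intensity")) {
      b64 <- enc64(sp[[col]])
      ba <- xml2::xml_add_child(bal, "binaryDataArray",
                                encodedLength = as.character(nchar(b64)))
      ms_cv(ba, "MS:1000523", "64-bit float")
      ms_cv(ba, "MS:1000576", "no compression")
      if (col == "mz") {
        ms_cv(ba, "MS:1000514", "m/z array")
      } else {
        ms_cv(ba, "MS:1000515", "intensity array")
      }
      xml2::xml_add_child(ba, "binary", b64)
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Read MS1 spectra from an mzML file
#'
#' Uses the `mzR` (proteowizard) backend. Each scan becomes one
#' `maldi_spectrum`; profile/centroid mode is taken from the file's spectrum
#' type flag, defaulting to profile with a warning when the flag is absent.
#'
#' @param path Path to an mzML file.
#' @return A list of `maldi_spectrum` objects.
#' @export
read_mzml <- function(path) {
  if (!requireNamespace("mzR", quietly = TRUE)) {
    abort("read_mzml() requires the mzR package")
  }
  if (!file.exists(path)) abort(sprintf("file not found: '%s'", path))
  handle <- mzR::openMSfile(path)
  on.exit(mzR::close(handle), add = TRUE)
  hdr <- mzR::header(handle)
  purrr::map(seq_len(nrow(hdr)), function(i) {
    pk <- mzR::peaks(handle, i)
    centroided <- hdr$centroided[[i]]
    if (is.na(centroided)) {
      warn(sprintf("scan %d of '%s' has no centroid/profile flag; assuming profile",
                   i, path))
      centroided <- FALSE
    }
    new_spectrum(
      tibble(mz = pk[, 1], intensity = pk[, 2]),
      mode = if (centroided) "centroid" else "profile",
      spectrum_id = sprintf("%s#%d", basename(path), i),
      metadata = list(source = path, scan = i)
    )
  })
}

#' Read a spectra batch manifest
#'
#' A manifest maps spectrum identifiers to files and specimen accessions:
#' a CSV with columns `spectrum_id`, `path`, `accession`. Relative paths are
#' resolved against the manifest's directory.
#'
#' @param path Path to a manifest CSV.
#' @return A tibble with columns `spectrum_id`, `path`, `accession`.
#' @export
read_manifest <- function(path) {
  m <- readr::read_csv(path, show_col_types = FALSE,
                       col_types = readr::cols(.default = readr::col_character()))
  need <- c("spectrum_id", "path", "accession")
  missing <- setdiff(need, names(m))
  if (length(missing) > 0) {
    abort(paste0("manifest is missing column(s): ", paste(missing, collapse = ", ")))
  }
  rel <- !grepl("^(/|[A-Za-z]:)", m$path) & !file.exists(m$path)
  m$path[rel] <- file.path(dirname(path), m$path[rel])
  m[need]
}
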