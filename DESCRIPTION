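Package: zoomscreen
Title: High-Throughput Collagen Peptide Mass Fingerprint Screening of
    Murine Rodents
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for Zooarchaeology by Mass Spectrometry (ZooMS) screening
    of skeletal remains using collagen peptide mass fingerprints. Computes
    theoretical monoisotopic peptide masses with collagen post-translational
    modifications (hydroxylation, deamidation), performs in-silico tryptic
    digestion, reads and writes MALDI-TOF spectra (text peak lists and a
    minimal mzML subset), estimates noise and picks centroided peaks from
    profile traces, recalibrates m/z against a peptide calibrant panel,
    applies a signal-to-noise quality gate, and assigns rodent taxa by
    matching peaks against a taxon-by-marker reference panel. A synthetic
    spectrum generator with known ground truth supports end-to-end testing
    of the batch screening pipeline at scale.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    mzR,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    xml2
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
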