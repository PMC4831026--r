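#' Monoisotopic mass table for peptide m/z computation
#'
#' The mass scale underlying every theoretical m/z in the package: the 20
#' standard amino-acid residue masses, the mass of water (added once per
#' peptide for the terminal H/OH), the proton mass (for the singly protonated
#' \[M+H\]+ ion), and the mass shifts of the two post-translational
#' modifications that dominate collagen chemistry -- hydroxylation of proline
#' and lysine (+15.9949 Da) and deamidation of asparagine and glutamine
#' (+0.9840 Da). All values are monoisotopic, in daltons.
#'
#' @param residue_masses Named numeric vector of residue masses to override
#'   or extend the built-in table (names are one-letter amino-acid codes).
#' @return An object of class `mass_table`: a list with elements
#'   `residue_masses`, `water_mass`, `proton_mass` and `mod_deltas`.
#' @examples
#' mt <- mass_table()
#' mt$residue_masses[["G"]]
#' mt$mod_deltas[["hydroxylation"]]
#' @export
mass_table <- function(residue_masses = NULL) {
  rm <- c(
    G = 57.0214637, A = 71.0371138, S = 87.0320284, P = 97.0527638,
    V = 99.0684139, T = 101.0476785, C = 103.0091848, L = 113.0840640,
    I = 113.0840640, N = 114.0429274, D = 115.0269430, Q = 128.0585775,
    K = 128.0949630, E = 129.0425931, M = 131.0404849, H = 137.0589119,
    F = 147.0684139, R = 156.1011110, Y = 163.0633285, W = 186.0793129
  )
  if (!is.null(residue_masses)) {
    if (is.null(names(residue_masses)) || any(!nzchar(names(residue_masses)))) {
      abort("`residue_masses` overrides must be a named numeric vector.")
    }
    rm[names(residue_masses)] <- residue_masses
  }
  out <- structure(
    list(
      residue_masses = rm,
      water_mass = 18.0105646837,
      proton_mass = 1.00727646677,
      mod_deltas = c(hydroxylation = 15.9949146196, deamidation = 0.9840155827)
    ),
    class = "mass_table"
  )
  validate_mass_table(out)
  out
}

validate_mass_table <- function(x) {
  std <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  missing <- setdiff(std, names(x$residue_masses))
  if (length(missing) > 0) {
    abort(paste0("mass table is missing residues: ", paste(missing, collapse = ", ")))
  }
  if (any(x$residue_masses <= 0)) abort("residue masses must be positive")
  if (x$water_mass < 18.0105 || x$water_mass > 18.0106) {
    abort("water mass outside the monoisotopic range [18.0105, 18.0106]")
  }
  if (x$proton_mass < 1.00727 || x$proton_mass > 1.00729) {
    abort("proton mass outside the monoisotopic range [1.00727, 1.00729]")
  }
  invisible(x)
}

#' @export
print.mass_table <- function(x, ...) {
  cat("<mass_table>: ", length(x$residue_masses), " residues, water ",
      format(x$water_mass), " Da, proton ", format(x$proton_mass), " Da\n",
      "modifications: ",
      paste(names(x$mod_deltas), sprintf("%+.4f", x$mod_deltas), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

# Checks a peptide sequence against the residue alphabet; names the first
# offending character in the error.
check_sequence <- function(sequence, masses, arg = "sequence") {
  if (!is.character(sequence) || length(sequence) != 1 || is.na(sequence) ||
      !nzchar(sequence)) {
    abort(sprintf("`%s` must be a single non-empty string.", arg))
  }
  chars <- strsplit(sequence, "")[[1]]
  bad <- setdiff(unique(chars), names(masses$residue_masses))
  if (length(bad) > 0) {
    abort(sprintf("unknown residue '%s' in %s \"%s\"", bad[[1]], arg, sequence))
  }
  chars
}
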